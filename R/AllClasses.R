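#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats median plogis quantile runif setNames
#' @importFrom utils read.table write.table
NULL

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_EXTENDED  <- c(AA_CANONICAL, "X")

#' Proteome: a validated set of amino-acid sequences
#'
#' Extends [Biostrings::AAStringSet] with validity constraints suited to
#' whole-proteome motif scanning: unique non-empty identifiers, non-empty
#' sequences, and an alphabet restricted to the 20 canonical residues plus
#' `X` for unknowns.
#'
#' @slot .Data inherited `AAStringSet` payload.
#' @seealso [readProteome()], [Proteome()]
#' @export
setClass("Proteome", contains = "AAStringSet")

setValidity("Proteome", function(object) {
  ids <- names(object)
  if (length(object) == 0L)
    return("proteome must contain at least one sequence")
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    return("all sequences must carry a non-empty id")
  if (anyDuplicated(ids))
    return(sprintf("duplicate id %s", ids[duplicated(ids)][1L]))
  if (any(Biostrings::width(object) == 0L))
    return("sequences must be non-empty")
  letters_used <- Biostrings::uniqueLetters(object)
  bad <- setdiff(letters_used, AA_EXTENDED)
  if (length(bad))
    return(sprintf("sequence alphabet restricted to ACDEFGHIKLMNPQRSTVWYX; found: %s",
                   paste(bad, collapse = "")))
  TRUE
})

#' Weighted undirected protein-association network
#'
#' Stores confidence-weighted undirected edges (STRING-style, confidences in
#' \[0,1\]), optional self-loops, and a cached node strength
#' \eqn{S(v) = \sum_x C(v,x)} (self-loop counted once). The strength cache
#' feeds the hub penalty of the association score.
#'
#' @slot nodes character vector of protein ids.
#' @slot edges data.frame with columns `a`, `b`, `weight`; `a < b`
#'   lexicographically for proper edges, `a == b` for self-loops.
#' @slot adjacency named list: for each node, a named numeric vector of
#'   neighbor confidences (self excluded).
#' @slot strength named numeric, cached \eqn{S(v)}.
#' @slot selfLoop named numeric, \eqn{C(v,v)} (0 when absent).
#' @seealso [readNetworkTsv()], [ContextNetwork()], [stepFactor()]
#' @export
setClass("ContextNetwork",
  representation(nodes = "character", edges = "data.frame",
                 adjacency = "list", strength = "numeric",
                 selfLoop = "numeric"))

setValidity("ContextNetwork", function(object) {
  e <- object@edges
  if (!all(c("a", "b", "weight") %in% names(e)))
    return("edges must have columns a, b, weight")
  if (nrow(e) && (any(e$weight < 0) || any(e$weight > 1)))
    return("edge confidences must lie in [0, 1]")
  s <- vapply(object@nodes, function(v) {
    sum(object@adjacency[[v]]) + object@selfLoop[[v]]
  }, numeric(1))
  if (!isTRUE(all.equal(unname(s), unname(object@strength[object@nodes]),
                        tolerance = 1e-9)))
    return("cached node strengths disagree with recomputation")
  TRUE
})

#' Compiled motif regular expression (restricted dialect)
#'
#' The dialect allows one-letter residue codes, `.` for any residue,
#' `[...]` residue classes, the quantifiers `*`, `+`, `{m}`, `{m,n}`, the
#' anchors `^` and `$`, and at most one capture group `(...)` marking the
#' modified/anchor residue. Anything else (alternation, escapes,
#' lookaround, nesting) is rejected at compile time.
#'
#' @slot patternText the pattern as supplied.
#' @slot compiled normalized PCRE pattern actually used for matching.
#' @slot anchoredCterm `TRUE` when the pattern ends in `$` (matches must
#'   terminate at the C-terminus).
#' @slot anchorGroup index of the capture group marking the anchor residue,
#'   or `NA_integer_` when the pattern has no group.
#' @seealso [compileMotifRegex()], [scanMotif()]
#' @export
setClass("RegexMotif",
  representation(patternText = "character", compiled = "character",
                 anchoredCterm = "logical", anchorGroup = "integer"))

#' Position-specific scoring matrix with background correction
#'
#' Log-odds (base 2) of the position-wise residue distribution of a set of
#' aligned binding peptides against the overall residue distribution of the
#' proteome, with background-proportional pseudocounts.
#'
#' @slot logOdds numeric matrix, 20 canonical residues (rows) by motif
#'   positions (columns); `-Inf` permitted when `pseudocountTotal == 0`.
#' @slot background named numeric(20), residue frequencies summing to 1,
#'   all strictly positive.
#' @slot pseudocountTotal total pseudocount mass distributed proportionally
#'   to the background.
#' @slot nPeptides number of training peptides.
#' @seealso [buildPSSM()], [scanMotif()]
#' @export
setClass("PSSM",
  representation(logOdds = "matrix", background = "numeric",
                 pseudocountTotal = "numeric", nPeptides = "integer"))

setValidity("PSSM", function(object) {
  if (!identical(rownames(object@logOdds), AA_CANONICAL))
    return("logOdds rows must be the 20 canonical residues")
  bg <- object@background
  if (!identical(names(bg), AA_CANONICAL) || any(bg <= 0))
    return("background must be strictly positive over the 20 canonical residues")
  if (abs(sum(bg) - 1) > 1e-9)
    return("background frequencies must sum to 1")
  if (any(is.nan(object@logOdds)) || any(object@logOdds == Inf))
    return("logOdds must be finite or -Inf")
  if (object@pseudocountTotal < 0)
    return("pseudocountTotal must be non-negative")
  TRUE
})

setMethod("show", "Proteome", function(object) {
  cat(sprintf("Proteome of %d sequences (total %d residues)\n",
              length(object), sum(Biostrings::width(object))))
  callNextMethod()
})

setMethod("show", "ContextNetwork", function(object) {
  self_n <- sum(object@selfLoop > 0)
  cat(sprintf(
    "ContextNetwork: %d nodes, %d edges (%d self-loops), mean strength %.3f\n",
    length(object@nodes), nrow(object@edges), self_n,
    if (length(object@strength)) mean(object@strength) else 0))
})

setMethod("show", "RegexMotif", function(object) {
  cat(sprintf("RegexMotif: %s%s%s\n", object@patternText,
              if (object@anchoredCterm) "  [C-terminal anchored]" else "",
              if (!is.na(object@anchorGroup))
                sprintf("  [anchor group %d]", object@anchorGroup) else ""))
})

setMethod("show", "PSSM", function(object) {
  cat(sprintf(
    "PSSM: %d positions, trained on %d peptide(s), pseudocount total %g\n",
    ncol(object@logOdds), object@nPeptides, object@pseudocountTotal))
  cat("consensus:", paste(rownames(object@logOdds)[
    apply(object@logOdds, 2, which.max)], collapse = ""), "\n")
})

#' Number of motif positions in a PSSM
#' @param x a [PSSM-class] object.
#' @return integer scalar.
#' @export
motifLength <- function(x) {
  stopifnot(is(x, "PSSM"))
  ncol(x@logOdds)
}

#' Network accessors
#'
#' `networkNodes` returns the node ids, `networkEdges` the canonical edge
#' table, `nodeStrength` the cached strengths \eqn{S(v)}, and
#' `selfLoopWeight` the self-loop confidences \eqn{C(v,v)}.
#'
#' @param x a [ContextNetwork-class].
#' @param v optional node ids to subset to.
#' @return character vector, data.frame, or named numeric respectively.
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "ContextNetwork"))
  x@nodes
}

#' @rdname networkNodes
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "ContextNetwork"))
  x@edges
}

#' @rdname networkNodes
#' @export
nodeStrength <- function(x, v = NULL) {
  stopifnot(is(x, "ContextNetwork"))
  if (is.null(v)) x@strength else x@strength[v]
}

#' @rdname networkNodes
#' @export
selfLoopWeight <- function(x, v = NULL) {
  stopifnot(is(x, "ContextNetwork"))
  if (is.null(v)) x@selfLoop else x@selfLoop[v]
}

#' Confidence of a single edge
#'
#' @param x a [ContextNetwork-class].
#' @param u,v node ids; `u == v` queries the self-loop.
#' @return the confidence, or 0 when no such edge exists.
#' @export
edgeConfidence <- function(x, u, v) {
  stopifnot(is(x, "ContextNetwork"))
  if (u == v) {
    if (u %in% x@nodes) unname(x@selfLoop[[u]]) else 0
  } else {
    nb <- x@adjacency[[u]]
    if (!is.null(nb) && v %in% names(nb)) unname(nb[[v]]) else 0
  }
}
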