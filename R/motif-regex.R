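#' Compile a motif pattern in the restricted regex dialect
#'
#' The dialect covers what short-linear-motif resources use: one-letter
#' residue codes, `.` (any residue), residue classes like `[DE]`, the
#' quantifiers `*`, `+`, `{m}`, `{m,n}` (whitespace inside braces is
#' tolerated, as in `{3, 4}`), the anchors `^` (N-terminus) and `$`
#' (C-terminus), and at most one capture group `(...)` marking the
#' modified/anchor residue, e.g. `(K)` in the SUMOylation motif
#' `[VILMAFP](K).E`. Any other construct — alternation, escapes,
#' lookaround, nested groups — is rejected with an error naming it.
#'
#' @param patternText the motif pattern.
#' @return a [RegexMotif-class].
#' @examples
#' compileMotifRegex("[VILMAFP](K).E")           # SUMOylation
#' compileMotifRegex(".[DEFILSTVY].[ACVILF]$")   # merged PDZ-binding
#' @export
compileMotifRegex <- function(patternText) {
  stopifnot(is.character(patternText), length(patternText) == 1L,
            nzchar(patternText))
  chars <- strsplit(patternText, "")[[1]]
  i <- 1L; n <- length(chars)
  out <- character(0)
  n_groups <- 0L
  in_group <- FALSE
  anchor_group <- NA_integer_
  last_was_atom <- FALSE
  peek <- function() if (i <= n) chars[i] else ""
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i != 1L) stop("'^' only allowed at the start of the pattern")
      out <- c(out, "^"); i <- i + 1L; last_was_atom <- FALSE
    } else if (ch == "$") {
      if (i != n) stop("'$' only allowed at the end of the pattern")
      out <- c(out, "$"); i <- i + 1L; last_was_atom <- FALSE
    } else if (ch == ".") {
      out <- c(out, "."); i <- i + 1L; last_was_atom <- TRUE
    } else if (ch %in% AA_CANONICAL) {
      out <- c(out, ch); i <- i + 1L; last_was_atom <- TRUE
    } else if (ch == "[") {
      j <- i + 1L
      cls <- character(0)
      while (j <= n && chars[j] != "]") { cls <- c(cls, chars[j]); j <- j + 1L }
      if (j > n) stop("unterminated residue class '['")
      if (!length(cls)) stop("empty residue class '[]'")
      bad <- setdiff(cls, AA_CANONICAL)
      if (length(bad))
        stop(sprintf("residue class may contain only amino-acid codes; found '%s'",
                     paste(bad, collapse = "")))
      out <- c(out, paste0("[", paste(cls, collapse = ""), "]"))
      i <- j + 1L; last_was_atom <- TRUE
    } else if (ch == "(") {
      if (n_groups >= 1L) stop("at most one capture group '(...)' allowed")
      if (in_group) stop("nested groups unsupported")
      if (peek() == "" ) stop("unterminated group '('")
      if (i + 1L <= n && chars[i + 1L] == "?")
        stop("lookaround / non-capturing group '(?' unsupported")
      in_group <- TRUE; n_groups <- n_groups + 1L
      anchor_group <- n_groups
      out <- c(out, "("); i <- i + 1L; last_was_atom <- FALSE
    } else if (ch == ")") {
      if (!in_group) stop("unbalanced ')'")
      in_group <- FALSE
      out <- c(out, ")"); i <- i + 1L; last_was_atom <- TRUE
    } else if (ch %in% c("*", "+")) {
      if (!last_was_atom) stop(sprintf("quantifier '%s' must follow a residue atom", ch))
      out <- c(out, ch); i <- i + 1L; last_was_atom <- FALSE
    } else if (ch == "{") {
      if (!last_was_atom) stop("quantifier '{...}' must follow a residue atom")
      j <- i + 1L
      body <- character(0)
      while (j <= n && chars[j] != "}") { body <- c(body, chars[j]); j <- j + 1L }
      if (j > n) stop("unterminated quantifier '{'")
      body <- gsub("\\s", "", paste(body, collapse = ""))
      if (!grepl("^[0-9]+(,[0-9]*)?$", body))
        stop(sprintf("malformed quantifier '{%s}'", body))
      out <- c(out, paste0("{", body, "}"))
      i <- j + 1L; last_was_atom <- FALSE
    } else if (ch == "|") {
      stop("alternation '|' unsupported")
    } else if (ch == "\\") {
      stop("escape sequences '\\' unsupported")
    } else {
      stop(sprintf("unsupported construct '%s' in motif pattern", ch))
    }
  }
  if (in_group) stop("unterminated group '('")
  new("RegexMotif",
      patternText = patternText,
      compiled = paste(out, collapse = ""),
      anchoredCterm = identical(out[length(out)], "$"),
      anchorGroup = anchor_group)
}

#' Scan sequences for motif matches
#'
#' `scanMotif` is the generic proteome scanner. For a [RegexMotif-class] it
#' reports every distinct start position at which the (greedy) pattern
#' matches — overlapping matches are all reported — with a binary motif
#' score (`motif_score = NA`; ranking then falls back to the association
#' score alone). `$`-anchored patterns match only when the match terminates
#' at the C-terminus. When the pattern carries a capture group, the column
#' `anchor_pos` reports the captured (modified) residue position.
#'
#' For a [PSSM-class] every window of the motif length is scored as the sum
#' of per-position log-odds (`raw_score`); windows containing `X` are
#' skipped (unknown residues must not fabricate score); `motif_score` is
#' the logistic transform of `raw_score` (see [normalizeScores()]).
#'
#' @param proteome a [Proteome-class] (or named character vector).
#' @param motif a [RegexMotif-class] or [PSSM-class].
#' @param ... unused.
#' @return data.frame with columns `protein_id`, `start`, `end`,
#'   `matched_peptide`, `raw_score`, `motif_score` (plus `anchor_pos` for
#'   regex motifs with a capture group), with attribute
#'   `scoreMode` = `"binary"` or `"graded"`.
#' @export
setGeneric("scanMotif", function(proteome, motif, ...) standardGeneric("scanMotif"))

.as_seqs <- function(proteome) {
  if (is(proteome, "AAStringSet")) {
    setNames(as.character(proteome), names(proteome))
  } else {
    stopifnot(is.character(proteome), !is.null(names(proteome)))
    proteome
  }
}

#' @rdname scanMotif
#' @export
setMethod("scanMotif", signature(motif = "RegexMotif"),
  function(proteome, motif, ...) {
    seqs <- .as_seqs(proteome)
    pat <- sub("^\\^", "", motif@compiled)
    anchored_n <- startsWith(motif@compiled, "^")
    pat_here <- paste0("^(?:", pat, ")")
    has_group <- !is.na(motif@anchorGroup)
    rows <- vector("list", length(seqs))
    for (k in seq_along(seqs)) {
      id <- names(seqs)[k]; s <- seqs[[k]]; L <- nchar(s)
      starts <- integer(0); ends <- integer(0); anchors <- integer(0)
      for (i in if (anchored_n) 1L else seq_len(L)) {
        m <- regexpr(pat_here, substr(s, i, L), perl = TRUE)
        if (m[1L] == -1L) next
        len <- attr(m, "match.length")
        if (len == 0L) next
        starts <- c(starts, i); ends <- c(ends, i + len - 1L)
        if (has_group) {
          cs <- attr(m, "capture.start")[1L]
          anchors <- c(anchors, i + cs - 1L)
        }
      }
      if (length(starts)) {
        df <- data.frame(protein_id = id, start = starts, end = ends,
                         matched_peptide = substring(s, starts, ends),
                         raw_score = NA_real_, motif_score = NA_real_,
                         stringsAsFactors = FALSE)
        if (has_group) df$anchor_pos <- anchors
        rows[[k]] <- df
      }
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) {
      out <- data.frame(protein_id = character(0), start = integer(0),
                        end = integer(0), matched_peptide = character(0),
                        raw_score = numeric(0), motif_score = numeric(0),
                        stringsAsFactors = FALSE)
      if (has_group) out$anchor_pos <- integer(0)
    }
    out <- out[order(out$protein_id, out$start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "scoreMode") <- "binary"
    out
  })

#' @rdname scanMotif
#' @export
setMethod("scanMotif", signature(motif = "PSSM"),
  function(proteome, motif, ...) {
    seqs <- .as_seqs(proteome)
    L <- motifLength(motif)
    lo <- motif@logOdds
    rows <- vector("list", length(seqs))
    for (k in seq_along(seqs)) {
      id <- names(seqs)[k]; s <- seqs[[k]]; n <- nchar(s)
      if (n < L) next
      res <- strsplit(s, "")[[1]]
      n_win <- n - L + 1L
      raw <- numeric(n_win)
      ok <- logical(n_win)
      ridx <- match(res, AA_CANONICAL)      # NA for X
      for (i in seq_len(n_win)) {
        idx <- ridx[i:(i + L - 1L)]
        if (anyNA(idx)) next                # window contains X: skip
        ok[i] <- TRUE
        raw[i] <- sum(lo[cbind(idx, seq_len(L))])
      }
      if (any(ok)) {
        st <- which(ok)
        rows[[k]] <- data.frame(protein_id = id, start = st,
                                end = st + L - 1L,
                                matched_peptide = substring(s, st, st + L - 1L),
                                raw_score = raw[st],
                                stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out))
      out <- data.frame(protein_id = character(0), start = integer(0),
                        end = integer(0), matched_peptide = character(0),
                        raw_score = numeric(0), stringsAsFactors = FALSE)
    out$motif_score <- normalizeScores(out$raw_score)
    out <- out[order(out$protein_id, out$start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "scoreMode") <- "graded"
    out
  })
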