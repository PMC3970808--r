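#' Construct a Proteome from sequences
#'
#' Sequences are uppercased; residues outside the 20-letter canonical
#' alphabet (plus `X`) are mapped to `X` and the replacement count is
#' reported through a warning. Duplicate or empty ids are hard errors.
#'
#' @param x named character vector of amino-acid sequences, or an
#'   `AAStringSet`.
#' @return a [Proteome-class].
#' @examples
#' Proteome(c(P1 = "MVKSE", P2 = "AVKTEG"))
#' @export
Proteome <- function(x) {
  if (is(x, "AAStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("x must be a named character vector or AAStringSet")
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(sprintf("duplicate id %s", dup[1L]))
  x <- toupper(x)
  n_bad <- 0L
  ok <- sprintf("[^%s]", paste(AA_EXTENDED, collapse = ""))
  bad_counts <- vapply(gregexpr(ok, x), function(m) {
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1))
  n_bad <- sum(bad_counts)
  if (n_bad > 0L) {
    x <- gsub(ok, "X", x)
    warning(sprintf("%d non-canonical residue(s) mapped to X", n_bad))
  }
  new("Proteome", Biostrings::AAStringSet(x))
}

#' Read a proteome from FASTA
#'
#' The header token up to the first whitespace becomes the protein id.
#' Case is normalized to upper; non-canonical residues become `X` (warning
#' reports the count). Duplicate ids and empty files are errors.
#'
#' @param path path to a FASTA file.
#' @return a [Proteome-class].
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  names(seqs) <- ids
  Proteome(seqs)
}

#' Write a proteome to FASTA
#' @param proteome a [Proteome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(proteome, path) {
  stopifnot(is(proteome, "Proteome"))
  Biostrings::writeXStringSet(proteome, path, width = 70L)
  invisible(path)
}

.build_network <- function(edges) {
  # edges: data.frame(a, b, weight), already unit-scaled and range-checked
  a <- as.character(edges$a); b <- as.character(edges$b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  # reciprocal / duplicate rows: conservative merge keeping max confidence
  w <- tapply(edges$weight, key, max)
  parts <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  e <- data.frame(a = parts[, 1L], b = parts[, 2L], weight = as.numeric(w),
                  stringsAsFactors = FALSE)
  e <- e[order(e$a, e$b), , drop = FALSE]
  rownames(e) <- NULL
  nodes <- sort(unique(c(e$a, e$b)))
  self <- setNames(numeric(length(nodes)), nodes)
  is_loop <- e$a == e$b
  self[e$a[is_loop]] <- e$weight[is_loop]
  proper <- e[!is_loop, , drop = FALSE]
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- numeric(0)
  for (i in seq_len(nrow(proper))) {
    u <- proper$a[i]; v <- proper$b[i]; wt <- proper$weight[i]
    adj[[u]][[v]] <- wt
    adj[[v]][[u]] <- wt
  }
  strength <- vapply(nodes, function(v) sum(adj[[v]]) + self[[v]], numeric(1))
  new("ContextNetwork", nodes = nodes, edges = e, adjacency = adj,
      strength = strength, selfLoop = self)
}

#' Construct a ContextNetwork from an edge table
#'
#' Reciprocal and duplicate rows are merged keeping the maximum confidence;
#' self-loops are retained (the hub penalty subtracts \eqn{C(v,v)}); node
#' strengths are cached.
#'
#' @param edges data.frame with columns `a`, `b`, `weight` (confidences in
#'   \[0,1\]).
#' @return a [ContextNetwork-class].
#' @examples
#' ContextNetwork(data.frame(a = c("A", "B"), b = c("B", "C"),
#'                           weight = c(0.8, 0.5)))
#' @export
ContextNetwork <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "weight") %in% names(edges)))
  if (nrow(edges) == 0L) stop("network must contain at least one edge")
  if (any(!is.finite(edges$weight)) ||
      any(edges$weight < 0) || any(edges$weight > 1))
    stop("edge confidences must lie in [0, 1]")
  .build_network(edges)
}

#' Read a weighted association network from 3-column TSV
#'
#' Expects tab- or whitespace-separated rows `id_a  id_b  score` with no
#' header; lines starting with `#` are skipped. The score scale must be
#' declared explicitly: `"unit"` for confidences already in \[0,1\],
#' `"string1000"` for STRING-style 0--1000 integers (divided by 1000).
#' Out-of-range scores are hard errors naming the offending line.
#'
#' @param path path to the edge TSV.
#' @param scoreScale `"unit"` or `"string1000"`.
#' @return a [ContextNetwork-class].
#' @export
readNetworkTsv <- function(path, scoreScale = c("unit", "string1000")) {
  scoreScale <- match.arg(scoreScale)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("no edge rows in %s", path))
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop(sprintf("line %d: expected 3 columns, found %d",
                 lineno[which(nf != 3L)[1L]], nf[nf != 3L][1L]))
  m <- do.call(rbind, fields)
  score <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(score))
    stop(sprintf("line %d: non-numeric score '%s'",
                 lineno[which(is.na(score))[1L]], m[is.na(score), 3L][1L]))
  hi <- switch(scoreScale, unit = 1, string1000 = 1000)
  bad <- which(score < 0 | score > hi)
  if (length(bad))
    stop(sprintf("line %d: score %s outside declared scale [0, %s]",
                 lineno[bad[1L]], format(score[bad[1L]]), format(hi)))
  w <- if (scoreScale == "string1000") score / 1000 else score
  ContextNetwork(data.frame(a = m[, 1L], b = m[, 2L], weight = w,
                            stringsAsFactors = FALSE))
}

#' Write a network as a unit-scale edge TSV
#' @param network a [ContextNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetworkTsv <- function(network, path) {
  stopifnot(is(network, "ContextNetwork"))
  e <- network@edges
  writeLines(sprintf("%s\t%s\t%s", e$a, e$b, format(e$weight, digits = 15,
                                                    scientific = FALSE)),
             path)
  invisible(path)
}

#' Read a protein-to-domain annotation table
#'
#' Two whitespace-separated columns `protein_id  domain_accession`, no
#' header required, `#` comment lines skipped. Duplicate pairs collapse.
#' An empty file yields an empty (valid) table.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `protein_id`, `domain_accession`.
#' @export
readDomainTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep))
    return(data.frame(protein_id = character(0),
                      domain_accession = character(0)))
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop(sprintf("line %d: expected 2 columns, found %d",
                 lineno[which(nf != 2L)[1L]], nf[nf != 2L][1L]))
  m <- do.call(rbind, fields)
  if (any(!nzchar(m)))
    stop(sprintf("line %d: empty field", lineno[which(rowSums(!nzchar(m)) > 0)[1L]]))
  d <- unique(data.frame(protein_id = m[, 1L], domain_accession = m[, 2L],
                         stringsAsFactors = FALSE))
  rownames(d) <- NULL
  d
}

#' Write a domain annotation table
#' @param table data.frame with columns `protein_id`, `domain_accession`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDomainTable <- function(table, path) {
  writeLines(sprintf("%s\t%s", table$protein_id, table$domain_accession), path)
  invisible(path)
}

#' Read an external motif-prediction table
#'
#' Whitespace-separated columns `protein_id  position  score`; a header row
#' is tolerated (detected by a non-numeric position field on line 1), `#`
#' comments skipped. Positions must be positive integers; scores finite and
#' non-negative.
#'
#' @param path path to the predictions TSV.
#' @return data.frame with columns `protein_id`, `position`, `score`.
#' @export
readPredictionTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("no prediction rows in %s", path))
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  if (length(fields) && lengths(fields)[1L] == 3L &&
      is.na(suppressWarnings(as.numeric(fields[[1L]][2L])))) {
    fields <- fields[-1L]; lineno <- lineno[-1L]   # header row
    if (!length(fields)) stop(sprintf("no prediction rows in %s", path))
  }
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop(sprintf("line %d: expected 3 columns, found %d",
                 lineno[which(nf != 3L)[1L]], nf[nf != 3L][1L]))
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.numeric(m[, 2L]))
  score <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(pos) | pos < 1 | pos != round(pos))
  if (length(bad))
    stop(sprintf("line %d: position must be a positive integer", lineno[bad[1L]]))
  bad <- which(!is.finite(score) | score < 0)
  if (length(bad))
    stop(sprintf("line %d: score must be finite and non-negative", lineno[bad[1L]]))
  data.frame(protein_id = m[, 1L], position = as.integer(pos), score = score,
             stringsAsFactors = FALSE)
}

HITS_COLUMNS <- c("protein_id", "start", "end", "matched_peptide",
                  "motif_score", "association_score", "best_interactor",
                  "final_score")

#' Write a ranked hits table
#'
#' Columns `protein_id, start, end, matched_peptide, motif_score,
#' association_score, best_interactor, final_score`, sorted by
#' `final_score` descending with ties broken by `(protein_id, start)`.
#' Coordinates are 1-based closed intervals; a comment line in the output
#' records this convention. Numeric scores are written to 6 significant
#' digits (the read/write round-trip contract).
#'
#' @param hits data.frame of ranked hits, as produced by [rankHits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitsTsv <- function(hits, path) {
  stopifnot(all(HITS_COLUMNS %in% names(hits)))
  h <- hits[order(-hits$final_score, hits$protein_id, hits$start), HITS_COLUMNS]
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(signif(x, 6), digits = 6,
                                                   format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, closed intervals", con)
  writeLines(paste(HITS_COLUMNS, collapse = "\t"), con)
  if (nrow(h))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s",
                       h$protein_id, h$start, h$end, h$matched_peptide,
                       fmt(h$motif_score), fmt(h$association_score),
                       ifelse(is.na(h$best_interactor), "NA", h$best_interactor),
                       fmt(h$final_score)), con)
  invisible(path)
}

#' Read a hits table written by [writeHitsTsv()]
#' @param path path to the hits TSV.
#' @return data.frame with the standard hit columns.
#' @export
readHitsTsv <- function(path) {
  h <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE,
                  colClasses = c("character", "integer", "integer",
                                 "character", "numeric", "numeric",
                                 "character", "numeric"))
  names(h) <- HITS_COLUMNS
  h
}
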