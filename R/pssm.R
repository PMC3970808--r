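#' Background residue frequencies of a proteome
#'
#' Frequencies over the 20 canonical residues; `X` is excluded from both
#' numerator and denominator. Add-one smoothing is applied so that a
#' residue absent from the proteome receives exactly the floor
#' `1 / (total residue count + 20)` while the vector still sums to 1:
#' `freq(a) = (count(a) + 1) / (total + 20)`.
#'
#' @param proteome a [Proteome-class] (or named character vector).
#' @return named numeric(20) summing to 1, all entries > 0.
#' @export
backgroundFrequencies <- function(proteome) {
  seqs <- .as_seqs(proteome)
  all_res <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  counts <- table(factor(all_res[all_res != "X"], levels = AA_CANONICAL))
  total <- sum(counts)
  if (total == 0L) stop("proteome contains no canonical residues")
  setNames(as.numeric(counts + 1) / (total + 20), AA_CANONICAL)
}

#' Read a peptide set (one aligned peptide per line)
#'
#' Plain text, one peptide per line, `#` comments and blank lines skipped.
#' @param path path to the peptide file.
#' @return character vector of peptides.
#' @export
readPeptides <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path))
  pep <- toupper(lines[!grepl("^#", lines) & nzchar(lines)])
  if (!length(pep)) stop(sprintf("no peptides in %s", path))
  pep
}

#' Build a PSSM from aligned binding peptides
#'
#' Per position `p` and residue `a` the pseudocounted frequency is
#' \deqn{\hat p(a) = \frac{count(a) + t \cdot bg(a)}{N + t}}
#' with `t = pseudocountTotal` distributed proportionally to the proteome
#' background `bg`, and the score is the base-2 log-odds
#' \eqn{\log_2(\hat p(a) / bg(a))}. A column whose residue usage equals the
#' background therefore scores exactly zero — the background correction
#' identity. With `pseudocountTotal = 0` a residue absent from a column
#' scores `-Inf`, and windows containing it are effectively non-matching.
#'
#' @param peptides character vector of equal-length peptides over the 20
#'   canonical residues.
#' @param background named numeric(20) as from [backgroundFrequencies()].
#' @param pseudocountTotal non-negative total pseudocount mass (default 1).
#' @return a [PSSM-class].
#' @examples
#' bg <- setNames(rep(0.05, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
#' buildPSSM(c("VKSE", "IKTE"), bg)
#' @export
buildPSSM <- function(peptides, background, pseudocountTotal = 1) {
  if (!length(peptides)) stop("peptide set must not be empty")
  peptides <- toupper(peptides)
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1L)
    stop(sprintf("peptides must have equal length; offending peptide '%s' (length %d, expected %d)",
                 peptides[lens != lens[1L]][1L], lens[lens != lens[1L]][1L],
                 lens[1L]))
  bad <- grepl(sprintf("[^%s]", paste(AA_CANONICAL, collapse = "")), peptides)
  if (any(bad))
    stop(sprintf("peptides must use canonical residues only; offending peptide '%s'",
                 peptides[bad][1L]))
  stopifnot(identical(names(background), AA_CANONICAL),
            all(background > 0), abs(sum(background) - 1) < 1e-9,
            pseudocountTotal >= 0)
  L <- lens[1L]
  N <- length(peptides)
  mat <- do.call(cbind, lapply(seq_len(L), function(p) {
    col <- substr(peptides, p, p)
    counts <- table(factor(col, levels = AA_CANONICAL))
    phat <- (as.numeric(counts) + pseudocountTotal * background) /
      (N + pseudocountTotal)
    log2(phat / background)
  }))
  rownames(mat) <- AA_CANONICAL
  colnames(mat) <- NULL
  new("PSSM", logOdds = mat, background = background,
      pseudocountTotal = pseudocountTotal, nPeptides = as.integer(N))
}

#' Map raw log-odds scores onto \[0,1\]
#'
#' Logistic transform on the odds scale: `2^raw / (1 + 2^raw)`. A raw
#' score of 0 (window indistinguishable from background) maps to 0.5;
#' `-Inf` maps to 0; the transform is strictly monotone elsewhere, so pure
#' motif ranking is unchanged.
#'
#' @param rawScores numeric vector of summed log-odds (base 2); `-Inf`
#'   allowed.
#' @return numeric vector in \[0,1\].
#' @export
normalizeScores <- function(rawScores) {
  plogis(rawScores * log(2))
}

#' Convert an external prediction table into motif matches
#'
#' Each row becomes a length-1 match at the stated 1-based position, with
#' scores min-max normalized to \[0,1\] over the whole table (a table with
#' a single distinct score maps to all 1.0). Rows naming proteins absent
#' from the proteome are dropped with a warning reporting the count; rows
#' whose position exceeds the protein length are errors.
#'
#' @param table data.frame as from [readPredictionTable()].
#' @param proteome a [Proteome-class] (or named character vector).
#' @return a graded match data.frame as from [scanMotif()].
#' @export
loadPredictions <- function(table, proteome) {
  stopifnot(all(c("protein_id", "position", "score") %in% names(table)))
  seqs <- .as_seqs(proteome)
  known <- table$protein_id %in% names(seqs)
  if (!any(known))
    stop("no prediction row names a protein present in the proteome")
  if (any(!known))
    warning(sprintf("%d prediction row(s) dropped: unknown protein",
                    sum(!known)))
  t <- table[known, , drop = FALSE]
  plen <- nchar(seqs[t$protein_id])
  if (any(t$position > plen))
    stop(sprintf("position %d exceeds length of protein %s",
                 t$position[t$position > plen][1L],
                 t$protein_id[t$position > plen][1L]))
  rng <- range(t$score)
  norm <- if (rng[1L] == rng[2L]) rep(1, nrow(t)) else
    (t$score - rng[1L]) / (rng[2L] - rng[1L])
  out <- data.frame(protein_id = t$protein_id,
                    start = as.integer(t$position),
                    end = as.integer(t$position),
                    matched_peptide = substring(seqs[t$protein_id],
                                                t$position, t$position),
                    raw_score = t$score,
                    motif_score = norm,
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scoreMode") <- "graded"
  out
}

#' Extract the log-odds matrix of a PSSM
#' @param pssm a [PSSM-class].
#' @return numeric matrix, 20 residues (rows) by motif positions.
#' @export
logOddsMatrix <- function(pssm) {
  stopifnot(is(pssm, "PSSM"))
  pssm@logOdds
}

#' Score a fixed set of aligned peptides with a PSSM
#'
#' Utility used by the cross-validation harness: scores each peptide (whose
#' length must equal the PSSM length) as the summed log-odds.
#'
#' @param pssm a [PSSM-class].
#' @param peptides character vector of peptides of the PSSM length;
#'   peptides containing `X` score `-Inf` (non-matching).
#' @return numeric vector of raw scores.
#' @export
scorePeptides <- function(pssm, peptides) {
  stopifnot(is(pssm, "PSSM"))
  L <- motifLength(pssm)
  if (any(nchar(peptides) != L))
    stop(sprintf("all peptides must have the PSSM length %d", L))
  vapply(peptides, function(p) {
    idx <- match(strsplit(toupper(p), "")[[1]], AA_CANONICAL)
    if (anyNA(idx)) return(-Inf)
    sum(pssm@logOdds[cbind(idx, seq_len(L))])
  }, numeric(1), USE.NAMES = FALSE)
}
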