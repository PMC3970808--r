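#' Fuse motif and association scores
#'
#' The weighted geometric combination
#' \deqn{final = motif^{1-\alpha} \cdot association^{\alpha}}
#' with `alpha` in \[0,1\] weighting cellular context against sequence
#' evidence. `0^0` is defined as 1 so that `alpha = 0` returns the motif
#' score exactly (a zero association is then irrelevant) and `alpha = 1`
#' the association score exactly. Strongly conserved motifs warrant small
#' `alpha`; degenerate motifs lean on context with large `alpha` (presets:
#' 0.4 for SUMO-style, 0.8 for PDZ-style runs — see [alphaPreset()]).
#'
#' @param motifScore,associationScore numeric vectors in \[0,1\]
#'   (recycled).
#' @param alpha weighting factor in \[0,1\].
#' @return numeric vector of final scores in \[0,1\].
#' @export
combineScores <- function(motifScore, associationScore, alpha = 0.5) {
  if (any(!is.finite(motifScore)) || any(motifScore < 0) || any(motifScore > 1))
    stop("motifScore must lie in [0, 1]")
  if (any(!is.finite(associationScore)) || any(associationScore < 0) ||
      any(associationScore > 1))
    stop("associationScore must lie in [0, 1]")
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  # R evaluates 0^0 as 1, which is exactly the convention required for the
  # alpha = 0 / alpha = 1 reduction identities
  motifScore^(1 - alpha) * associationScore^alpha
}

#' Alpha presets for packaged motif families
#'
#' `"sumo"` returns 0.4 and `"pdz"` 0.8: the context weight grows with the
#' degeneracy of the motif. The matching fixed-FPR evaluation cutoffs are
#' available via [fprPreset()].
#'
#' @param preset `"sumo"` or `"pdz"`.
#' @return numeric scalar alpha.
#' @export
alphaPreset <- function(preset = c("sumo", "pdz")) {
  switch(match.arg(preset), sumo = 0.4, pdz = 0.8)
}

#' @rdname alphaPreset
#' @export
fprPreset <- function(preset = c("sumo", "pdz")) {
  switch(match.arg(preset), sumo = 0.3, pdz = 0.15)
}

#' Packaged motif patterns
#'
#' `"sumo"`: the SUMOylation consensus `[VILMAFP](K).E` (the capture group
#' marks the modified lysine). `"pdz"`: the merged C-terminal PDZ-binding
#' motif `.[DEFILSTVY].[ACVILF]$`, the union of the three class-specific
#' patterns which differ only at the second position.
#'
#' @param preset `"sumo"` or `"pdz"`.
#' @return pattern string (compile with [compileMotifRegex()]).
#' @export
motifPreset <- function(preset = c("sumo", "pdz")) {
  switch(match.arg(preset),
         sumo = "[VILMAFP](K).E",
         pdz = ".[DEFILSTVY].[ACVILF]$")
}

#' Rank motif matches by the combined score
#'
#' Graded matches (PSSM or imported predictions) get
#' `final = motif^(1-alpha) * association^alpha`; binary matches (regex
#' scan) fall back to ranking by the association score alone. Matches whose
#' protein lacks an association result score 0 on the association side.
#' Output is sorted by `final_score` descending, ties broken by
#' `(protein_id, start)`.
#'
#' @param matches match data.frame from [scanMotif()] or
#'   [loadPredictions()]; all rows must share one score mode (a single run
#'   uses one motif source).
#' @param associations named list from [associationScores()].
#' @param alpha weighting factor in \[0,1\].
#' @return data.frame of ranked hits with the columns of [writeHitsTsv()].
#' @export
rankHits <- function(matches, associations, alpha = 0.5) {
  has_score <- !is.na(matches$motif_score)
  if (nrow(matches) && any(has_score) && !all(has_score))
    stop("mixed graded and binary motif scores: a single run uses one motif mode")
  mode <- attr(matches, "scoreMode")
  binary <- if (nrow(matches)) !all(has_score) else !identical(mode, "graded")
  at <- associationTable(associations)
  idx <- match(matches$protein_id, at$substrate_id)
  assoc_score <- ifelse(is.na(idx), 0, at$association_score[idx])
  interactor <- ifelse(is.na(idx), NA_character_, at$best_interactor[idx])
  final <- if (binary) assoc_score else
    combineScores(matches$motif_score, assoc_score, alpha)
  out <- data.frame(protein_id = matches$protein_id,
                    start = matches$start, end = matches$end,
                    matched_peptide = matches$matched_peptide,
                    motif_score = matches$motif_score,
                    association_score = assoc_score,
                    best_interactor = interactor,
                    final_score = final,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$final_score, out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scoreMode") <- if (binary) "binary" else "graded"
  out
}
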