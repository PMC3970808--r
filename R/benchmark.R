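#' ROC curve, AUC and TPR at fixed FPR
#'
#' Threshold sweep over the distinct score values with tied scores grouped
#' (one ROC vertex per distinct score, so ties cannot fabricate AUC); AUC
#' by the trapezoidal rule, which under grouped ties equals the
#' Mann-Whitney statistic with half-credit for ties. TPR at a fixed FPR is
#' read off the curve by linear interpolation between adjacent vertices.
#'
#' @param scores numeric vector of prediction scores (higher = more
#'   positive).
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive; both classes
#'   must be present.
#' @param fprCutoffs FPR values at which to report interpolated TPRs.
#' @return an `EvalReport`: list with `roc` (data.frame `fpr`, `tpr`,
#'   `threshold`), `auc`, `tpr_at_fpr` (named numeric),
#'   `sensitivity`/`specificity` at the first cutoff, `n_pos`, `n_neg`.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))$auc   # 1.0
#' @export
rocCurve <- function(scores, labels, fprCutoffs = c(0.3, 0.15)) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both a positive and a negative example are required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: cumulative counts at the last index of each tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                    threshold = c(Inf, s[last]))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  tpr_at <- vapply(fprCutoffs, function(cut) .interp_tpr(roc, cut), numeric(1))
  names(tpr_at) <- format(fprCutoffs)
  list(roc = roc, auc = auc, tpr_at_fpr = tpr_at,
       sensitivity = unname(tpr_at[1L]), specificity = 1 - fprCutoffs[1L],
       n_pos = n_pos, n_neg = n_neg)
}

.interp_tpr <- function(roc, cut) {
  stopifnot(cut >= 0, cut <= 1)
  fpr <- roc$fpr; tpr <- roc$tpr
  # at a vertical segment (repeated fpr) take the highest tpr reached there
  if (any(fpr == cut)) return(max(tpr[fpr == cut]))
  i <- max(which(fpr < cut)); j <- min(which(fpr > cut))
  tpr[i] + (tpr[j] - tpr[i]) * (cut - fpr[i]) / (fpr[j] - fpr[i])
}

#' Interpolated TPR at a fixed FPR from an existing report
#' @param report an `EvalReport` from [rocCurve()].
#' @param fprCutoff FPR in (0, 1).
#' @return numeric TPR.
#' @export
tprAtFixedFpr <- function(report, fprCutoff) {
  stopifnot(fprCutoff > 0, fprCutoff < 1)
  .interp_tpr(report$roc, fprCutoff)
}

.stratified_folds <- function(labels, k) {
  # per class, deal fold ids 1..k in random order; class ratio per fold is
  # then within one item of the global ratio
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Repeated stratified cross-validation of PSSM + context ranking
#'
#' Per repeat, the labeled sites are split into `k` stratified folds. For
#' each fold a PSSM is trained on the *positive* peptides of the remaining
#' folds (background from the proteome) and the held-out sites are scored
#' with the combined score `motif^(1-alpha) * association^alpha`; held-out
#' scores are pooled across folds into one per-repeat ROC. The reported
#' numbers are the medians across repeats. Association scores depend only
#' on the network, so they are computed once. Defaults `k = 5`,
#' `repeats = 5`, median-reported, mirror standard practice for small
#' motif datasets.
#'
#' @param sites data.frame of labeled sites: columns `protein_id`,
#'   `position`, `label` (`"positive"`/`"negative"`, or logical), `peptide`
#'   (aligned equal-length windows).
#' @param proteome a [Proteome-class] (background source).
#' @param network a [ContextNetwork-class].
#' @param domainTable domain annotation data.frame.
#' @param domains domain accessions defining the carrier set.
#' @param alpha context weight in \[0,1\] (`alpha = 0` is motif-only).
#' @param beta,maxHops association-score parameters.
#' @param pseudocountTotal PSSM pseudocount mass.
#' @param k number of folds (>= 2).
#' @param repeats number of CV repetitions.
#' @param fprCutoffs FPR cutoffs for the TPR readout.
#' @param seed integer seed; the partitioning is reproducible from it.
#' @return list with `auc` (median), `tpr_at_fpr` (median, named),
#'   `per_repeat` (list of per-repeat `EvalReport`s), `alpha`, `k`,
#'   `repeats`.
#' @export
crossValidate <- function(sites, proteome, network, domainTable, domains,
                          alpha = 0.5, beta = 0.34, maxHops = 3L,
                          pseudocountTotal = 1, k = 5L, repeats = 5L,
                          fprCutoffs = c(0.3, 0.15), seed = 1L) {
  stopifnot(k >= 2L, repeats >= 1L,
            all(c("protein_id", "position", "label", "peptide") %in%
                  names(sites)))
  lab <- if (is.logical(sites$label)) sites$label else
    sites$label == "positive"
  if (!any(lab) || all(lab)) stop("sites must contain both classes")
  if (length(unique(nchar(sites$peptide))) != 1L)
    stop("site peptides must have homogeneous length")
  bg <- backgroundFrequencies(proteome)
  assoc <- associationScores(network, unique(sites$protein_id),
                             domainTable, domains,
                             beta = beta, maxHops = maxHops)
  at <- associationTable(assoc)
  assoc_score <- at$association_score[match(sites$protein_id,
                                            at$substrate_id)]
  assoc_score[is.na(assoc_score)] <- 0
  set.seed(seed)
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- NULL
    for (attempt in seq_len(100L)) {
      cand <- .stratified_folds(lab, k)
      if (all(vapply(seq_len(k), function(f) any(lab[cand == f]),
                     logical(1)))) { fold <- cand; break }
    }
    if (is.null(fold))
      stop("could not draw a partition with positives in every fold")
    final <- numeric(nrow(sites))
    for (f in seq_len(k)) {
      train_pep <- sites$peptide[lab & fold != f]
      pssm <- buildPSSM(train_pep, bg, pseudocountTotal)
      test <- which(fold == f)
      motif <- normalizeScores(scorePeptides(pssm, sites$peptide[test]))
      final[test] <- combineScores(motif, assoc_score[test], alpha)
    }
    per_repeat[[r]] <- rocCurve(final, lab, fprCutoffs)
  }
  aucs <- vapply(per_repeat, `[[`, numeric(1), "auc")
  tprs <- do.call(rbind, lapply(per_repeat, `[[`, "tpr_at_fpr"))
  list(auc = median(aucs),
       tpr_at_fpr = apply(tprs, 2, median),
       per_repeat = per_repeat,
       alpha = alpha, k = k, repeats = repeats)
}

#' Read a labeled-sites table
#'
#' Whitespace-separated columns `protein_id position label peptide`;
#' header tolerated; `#` comments skipped; `label` must be `positive` or
#' `negative`.
#'
#' @param path path to the TSV.
#' @return data.frame of labeled sites.
#' @export
readSitesTsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("no site rows in %s", path))
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  if (length(fields) && identical(tolower(fields[[1L]][1L]), "protein_id"))
    fields <- fields[-1L]
  if (any(lengths(fields) != 4L)) stop("expected 4 columns in sites table")
  m <- do.call(rbind, fields)
  if (!all(m[, 3L] %in% c("positive", "negative")))
    stop("label must be 'positive' or 'negative'")
  data.frame(protein_id = m[, 1L], position = as.integer(m[, 2L]),
             label = m[, 3L], peptide = toupper(m[, 4L]),
             stringsAsFactors = FALSE)
}

#' Write a labeled-sites table
#' @param sites data.frame of labeled sites.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSitesTsv <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein_id\tposition\tlabel\tpeptide", con)
  if (nrow(sites))
    writeLines(sprintf("%s\t%d\t%s\t%s", sites$protein_id, sites$position,
                       sites$label, sites$peptide), con)
  invisible(path)
}
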