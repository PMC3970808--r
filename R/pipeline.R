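.score_quartiles <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(list(min = NA, q25 = NA, median = NA, q75 = NA,
                              max = NA))
  q <- unname(quantile(x, c(0, 0.25, 0.5, 0.75, 1)))
  list(min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5])
}

#' Run the full scan-and-rank pipeline
#'
#' The two-step workflow: define the motif (exactly one of `regex`,
#' `peptides`, `predictions`), name the binding domain(s), then scan the
#' proteome, compute hub-penalized association scores toward the domain
#' carriers, fuse the two scores and write the ranked hit list. A JSON
#' summary reports counts and the quartiles of the motif, association and
#' final score distributions (the numeric analogue of score-distribution
#' plots, for choosing a downstream cutoff).
#'
#' @param fasta path to the proteome FASTA.
#' @param network path to the edge TSV.
#' @param scoreScale `"unit"` or `"string1000"` (see [readNetworkTsv()]).
#' @param domainsTable path to the protein-domain TSV.
#' @param domains character vector of domain accessions (>= 1).
#' @param regex motif pattern string, or `NULL`.
#' @param peptides path to an aligned peptide file, or `NULL`.
#' @param predictions path to an external prediction TSV, or `NULL`.
#' @param alpha context weight; overridden by `preset` when given.
#' @param preset optional `"sumo"` or `"pdz"` (sets `alpha`).
#' @param beta,maxHops association-score parameters.
#' @param pseudocountTotal PSSM pseudocount mass.
#' @param out path for the ranked hits TSV; its `.json` sibling receives
#'   the summary (or pass `summaryOut`).
#' @param summaryOut optional explicit summary JSON path.
#' @return invisibly, a list with `hits` (data.frame) and `summary`
#'   (list).
#' @export
runScan <- function(fasta, network, scoreScale = "unit", domainsTable,
                    domains, regex = NULL, peptides = NULL,
                    predictions = NULL, alpha = 0.5, preset = NULL,
                    beta = 0.34, maxHops = 3L, pseudocountTotal = 1,
                    out = NULL, summaryOut = NULL) {
  sources <- c(regex = !is.null(regex), peptides = !is.null(peptides),
               predictions = !is.null(predictions))
  if (sum(sources) != 1L)
    stop("exactly one motif source required: regex, peptides or predictions")
  if (length(domains) < 1L) stop("at least one domain accession required")
  if (!is.null(preset)) alpha <- alphaPreset(preset)
  prot <- readProteome(fasta)
  net <- readNetworkTsv(network, scoreScale)
  dom <- readDomainTable(domainsTable)
  matches <- if (!is.null(regex)) {
    scanMotif(prot, compileMotifRegex(regex))
  } else if (!is.null(peptides)) {
    pep <- readPeptides(peptides)
    scanMotif(prot, buildPSSM(pep, backgroundFrequencies(prot),
                              pseudocountTotal))
  } else {
    loadPredictions(readPredictionTable(predictions), prot)
  }
  assoc <- associationScores(net, unique(matches$protein_id), dom, domains,
                             beta = beta, maxHops = maxHops)
  hits <- rankHits(matches, assoc, alpha)
  summary <- list(
    n_proteins = length(prot),
    n_matches = nrow(hits),
    n_domain_carriers = length(domainCarriers(dom, domains)),
    n_substrates_with_association = sum(associationTable(assoc)$association_score > 0),
    alpha = alpha, beta = beta, max_hops = maxHops,
    score_mode = attr(hits, "scoreMode"),
    motif_score_quartiles = .score_quartiles(hits$motif_score),
    association_score_quartiles = .score_quartiles(hits$association_score),
    final_score_quartiles = .score_quartiles(hits$final_score))
  if (!is.null(out)) {
    writeHitsTsv(hits, out)
    if (is.null(summaryOut))
      summaryOut <- paste0(sub("\\.tsv$", "", out), ".json")
  }
  if (!is.null(summaryOut))
    jsonlite::write_json(summary, summaryOut, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(list(hits = hits, summary = summary))
}

#' Run the cross-validation benchmark from files
#'
#' File-level wrapper around [crossValidate()]: reads the proteome,
#' network, domain table and labeled sites, runs repeated stratified
#' k-fold cross-validation of the combined PSSM + context ranking, and
#' writes the median report as JSON (and the per-repeat numbers as TSV).
#'
#' @inheritParams runScan
#' @param sites path to the labeled-sites TSV (see [readSitesTsv()]).
#' @param k,repeats cross-validation design (defaults 5 and 5).
#' @param fprCutoffs FPR cutoffs for the TPR readout.
#' @param seed integer seed for the fold partitioning.
#' @param out optional path for the JSON report; a `.tsv` sibling receives
#'   the per-repeat table.
#' @return invisibly, the [crossValidate()] result.
#' @export
runBenchmark <- function(fasta, network, scoreScale = "unit", domainsTable,
                         domains, sites, alpha = 0.5, preset = NULL,
                         beta = 0.34, maxHops = 3L, pseudocountTotal = 1,
                         k = 5L, repeats = 5L, fprCutoffs = c(0.3, 0.15),
                         seed = 1L, out = NULL) {
  if (!is.null(preset)) {
    alpha <- alphaPreset(preset)
    fprCutoffs <- fprPreset(preset)
  }
  prot <- readProteome(fasta)
  net <- readNetworkTsv(network, scoreScale)
  dom <- readDomainTable(domainsTable)
  st <- readSitesTsv(sites)
  cv <- crossValidate(st, prot, net, dom,
                      domains = domains, alpha = alpha, beta = beta,
                      maxHops = maxHops, pseudocountTotal = pseudocountTotal,
                      k = k, repeats = repeats, fprCutoffs = fprCutoffs,
                      seed = seed)
  if (!is.null(out)) {
    jsonlite::write_json(list(median_auc = cv$auc,
                              median_tpr_at_fpr = as.list(cv$tpr_at_fpr),
                              alpha = alpha, k = k, repeats = repeats,
                              seed = seed),
                         out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tsv <- paste0(sub("\\.json$", "", out), ".tsv")
    per <- data.frame(repeat_id = seq_along(cv$per_repeat),
                      auc = vapply(cv$per_repeat, `[[`, numeric(1), "auc"))
    for (nm in names(cv$per_repeat[[1L]]$tpr_at_fpr))
      per[[paste0("tpr_at_fpr_", trimws(nm))]] <-
        vapply(cv$per_repeat, function(r) r$tpr_at_fpr[[nm]], numeric(1))
    write.table(per, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(cv)
}
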