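#' Configuration for a synthetic benchmark scenario
#'
#' Describes a self-contained test universe: a random proteome with motif
#' instances planted at recorded positions, a weighted association network
#' in which true sites are preferentially connected to binding-domain
#' carriers, and the matching domain annotation table. Proteins play four
#' roles: `nPlantedPositives` substrate proteins each carrying one true
#' site, `nDecoys` proteins each carrying one decoy site (a genuine motif
#' match labeled negative — only context can separate it), a set of
#' `nDomainCarriers` annotated with `domain`, and filler proteins hosting
#' the Erdős–Rényi background network. With probability `contextSignal`
#' each positive's protein receives a planted path of at most 2 hops to a
#' random carrier with confidences from the upper half of
#' `confidenceRange`; `contextSignal = 0` therefore means the network
#' carries no information about the labels. Decoy proteins are left
#' unconnected (`decoyConnect = "none"`) or wired into the filler
#' background at the background density (`"random"`).
#'
#' @param nProteins total proteins (must cover the three special roles).
#' @param seqLength residues per protein.
#' @param nDomainCarriers,nPlantedPositives,nDecoys role counts.
#' @param motif motif pattern string (restricted dialect) whose instances
#'   are planted, or a character vector of >1 equal-length peptides to
#'   plant verbatim.
#' @param domain domain accession given to the carriers.
#' @param edgeDensity Erdős–Rényi edge probability of the background graph.
#' @param confidenceRange length-2 numeric, background confidence range in
#'   \[0,1\].
#' @param contextSignal probability in \[0,1\] that a positive's protein is
#'   wired to a carrier.
#' @param decoyConnect `"none"` or `"random"`.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return a `ScenarioConfig` (classed list).
#' @export
scenarioConfig <- function(nProteins = 60L, seqLength = 80L,
                           nDomainCarriers = 5L, nPlantedPositives = 15L,
                           nDecoys = 15L, motif = "[VILMAFP](K).E",
                           domain = "PF_SYNTH", edgeDensity = 0.08,
                           confidenceRange = c(0.4, 0.95),
                           contextSignal = 1, decoyConnect = c("none", "random"),
                           seed = 1L) {
  decoyConnect <- match.arg(decoyConnect)
  stopifnot(nProteins >= nDomainCarriers + nPlantedPositives + nDecoys + 1L,
            seqLength >= 1L, edgeDensity >= 0, edgeDensity <= 1,
            length(confidenceRange) == 2L,
            confidenceRange[1L] >= 0, confidenceRange[2L] <= 1,
            confidenceRange[1L] < confidenceRange[2L],
            contextSignal >= 0, contextSignal <= 1)
  structure(list(nProteins = as.integer(nProteins),
                 seqLength = as.integer(seqLength),
                 nDomainCarriers = as.integer(nDomainCarriers),
                 nPlantedPositives = as.integer(nPlantedPositives),
                 nDecoys = as.integer(nDecoys),
                 motif = motif, domain = domain,
                 edgeDensity = edgeDensity,
                 confidenceRange = confidenceRange,
                 contextSignal = contextSignal,
                 decoyConnect = decoyConnect,
                 seed = as.integer(seed)),
            class = "ScenarioConfig")
}

# draw one concrete instance of a motif pattern (quantifiers expanded:
# '*' -> 0-2 copies, '+' -> 1-2, '{m}' -> m, '{m,n}' -> uniform in m..n)
.instantiate_motif <- function(motif) {
  if (length(motif) > 1L) return(sample(motif, 1L))
  rm <- compileMotifRegex(motif)
  pat <- sub("^\\^", "", sub("\\$$", "", rm@compiled))
  chars <- strsplit(pat, "")[[1]]
  i <- 1L; n <- length(chars)
  atoms <- character(0)
  emit <- function(a) atoms <<- c(atoms, a)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("(", ")")) { i <- i + 1L; next }
    if (ch == ".") { atom <- sample(AA_CANONICAL, 1L); i <- i + 1L }
    else if (ch == "[") {
      j <- which(chars == "]" & seq_len(n) > i)[1L]
      atom <- sample(chars[(i + 1L):(j - 1L)], 1L)
      i <- j + 1L
    } else { atom <- ch; i <- i + 1L }
    reps <- 1L
    if (i <= n && chars[i] %in% c("*", "+", "{")) {
      if (chars[i] == "*") { reps <- sample(0:2, 1L); i <- i + 1L }
      else if (chars[i] == "+") { reps <- sample(1:2, 1L); i <- i + 1L }
      else {
        j <- which(chars == "}" & seq_len(n) > i)[1L]
        body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
        parts <- as.integer(strsplit(body, ",")[[1]])
        reps <- if (length(parts) == 2L) sample(parts[1L]:parts[2L], 1L)
                else parts[1L]
        i <- j + 1L
      }
    }
    if (reps > 0L) emit(strrep(atom, reps))
  }
  paste(atoms, collapse = "")
}

.round3 <- function(x) round(x, 3)

#' Generate a synthetic benchmark scenario
#'
#' See [scenarioConfig()] for the statistical design. Generation is fully
#' deterministic given the config's seed: the same config produces
#' byte-identical files through [writeScenario()]. Every planted site
#' (positive or decoy) is a genuine motif instance spliced into the
#' sequence at its recorded 1-based position, so a scan recovers it
#' exactly; C-terminal-anchored motifs are planted at the terminus.
#'
#' @param config a `ScenarioConfig`.
#' @return list with elements `proteome` ([Proteome-class]), `network`
#'   ([ContextNetwork-class]), `domainTable` (data.frame), `sites`
#'   (labeled-sites data.frame), `config`.
#' @export
generateScenario <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  set.seed(config$seed)
  is_peptide_set <- length(config$motif) > 1L
  inst0 <- .instantiate_motif(config$motif)
  if (nchar(inst0) > config$seqLength)
    stop("motif instances longer than seqLength")
  anchored <- !is_peptide_set &&
    compileMotifRegex(config$motif)@anchoredCterm

  n <- config$nProteins
  ids <- sprintf("SP%04d", seq_len(n))
  pos_ids <- ids[seq_len(config$nPlantedPositives)]
  dec_ids <- ids[config$nPlantedPositives + seq_len(config$nDecoys)]
  car_ids <- ids[config$nPlantedPositives + config$nDecoys +
                   seq_len(config$nDomainCarriers)]
  fil_ids <- setdiff(ids, c(pos_ids, dec_ids, car_ids))

  seqs <- vapply(seq_len(n), function(i)
    paste(sample(AA_CANONICAL, config$seqLength, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- ids

  plant <- function(id, label) {
    inst <- .instantiate_motif(config$motif)
    L <- nchar(inst)
    start <- if (anchored) config$seqLength - L + 1L
             else sample(seq_len(config$seqLength - L + 1L), 1L)
    s <- seqs[[id]]
    substr(s, start, start + L - 1L) <- inst
    seqs[[id]] <<- s
    data.frame(protein_id = id, position = start, label = label,
               peptide = inst, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, c(lapply(pos_ids, plant, label = "positive"),
                            lapply(dec_ids, plant, label = "negative")))

  # background Erdős–Rényi graph over fillers + carriers
  bg_nodes <- c(fil_ids, car_ids)
  pairs <- if (length(bg_nodes) >= 2L) utils::combn(bg_nodes, 2L) else
    matrix(character(0), nrow = 2)
  keep <- runif(ncol(pairs)) < config$edgeDensity
  edges <- data.frame(a = pairs[1L, keep], b = pairs[2L, keep],
                      weight = .round3(runif(sum(keep),
                                             config$confidenceRange[1L],
                                             config$confidenceRange[2L])),
                      stringsAsFactors = FALSE)
  hi_lo <- mean(config$confidenceRange)   # upper half of the range
  hi <- config$confidenceRange[2L]
  for (id in pos_ids) {
    if (runif(1) >= config$contextSignal) next
    carrier <- sample(car_ids, 1L)
    if (runif(1) < 0.5 || !length(fil_ids)) {      # direct edge
      edges <- rbind(edges, data.frame(a = id, b = carrier,
                                       weight = .round3(runif(1, hi_lo, hi))))
    } else {                                       # 2-hop via a filler linker
      linker <- sample(fil_ids, 1L)
      edges <- rbind(edges,
                     data.frame(a = c(id, linker), b = c(linker, carrier),
                                weight = .round3(runif(2, hi_lo, hi))))
    }
  }
  if (config$decoyConnect == "random") {
    for (id in dec_ids) {
      nb <- fil_ids[runif(length(fil_ids)) < config$edgeDensity]
      if (length(nb))
        edges <- rbind(edges,
                       data.frame(a = id, b = nb,
                                  weight = .round3(runif(length(nb),
                                                         config$confidenceRange[1L],
                                                         config$confidenceRange[2L]))))
    }
  }
  # guarantee a connected backbone so the graph is never empty
  if (!nrow(edges))
    edges <- data.frame(a = bg_nodes[1L], b = bg_nodes[2L],
                        weight = .round3(mean(config$confidenceRange)))

  list(proteome = Proteome(seqs),
       network = ContextNetwork(edges),
       domainTable = data.frame(protein_id = car_ids,
                                domain_accession = config$domain,
                                stringsAsFactors = FALSE),
       sites = sites,
       config = config)
}

#' Write a scenario to its standard on-disk representation
#'
#' Emits `proteome.fasta`, `network.tsv` (unit scale), `domains.tsv` and
#' `sites.tsv` into `dir`. The write/read round-trip is lossless
#' (confidences are 3-decimal by construction).
#'
#' @param scenario list from [generateScenario()].
#' @param dir output directory (created if missing).
#' @return named character vector of the four file paths, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteome = file.path(dir, "proteome.fasta"),
             network = file.path(dir, "network.tsv"),
             domains = file.path(dir, "domains.tsv"),
             sites = file.path(dir, "sites.tsv"))
  writeProteome(scenario$proteome, paths[["proteome"]])
  writeNetworkTsv(scenario$network, paths[["network"]])
  writeDomainTable(scenario$domainTable, paths[["domains"]])
  writeSitesTsv(scenario$sites, paths[["sites"]])
  invisible(paths)
}

#' Read back a scenario written by [writeScenario()]
#' @param dir directory holding the four standard files.
#' @return list with `proteome`, `network`, `domainTable`, `sites`.
#' @export
readScenario <- function(dir) {
  list(proteome = readProteome(file.path(dir, "proteome.fasta")),
       network = readNetworkTsv(file.path(dir, "network.tsv"), "unit"),
       domainTable = readDomainTable(file.path(dir, "domains.tsv")),
       sites = readSitesTsv(file.path(dir, "sites.tsv")))
}
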