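#' Hub-penalized step factor of a directed traversal of an edge
#'
#' For a step from `u` into `v` along an edge of confidence `C(u,v)` the
#' factor is
#' \deqn{\frac{C(u,v)}{(1 + S(v) - C(u,v) - C(v,v))^{\beta}}}
#' where \eqn{S(v)} is the strength (sum of all edge confidences at `v`,
#' self-loop included) and \eqn{C(v,v)} the self-loop confidence (0 when
#' absent). The denominator is at least 1, so the factor lies in
#' `(0, C(u,v)]`: traversing into a hub is penalized in proportion to the
#' hub's remaining connectivity. `beta = 0` disables the penalty. The
#' default `beta = 0.34` follows kinase-substrate context-scoring practice.
#'
#' @param network a [ContextNetwork-class].
#' @param u,v node ids; the edge `u`--`v` must exist. The factor is
#'   direction dependent (the denominator belongs to the entered node `v`).
#' @param beta hub-penalty exponent, non-negative.
#' @return numeric scalar in `(0, C(u,v)]`.
#' @export
stepFactor <- function(network, u, v, beta = 0.34) {
  stopifnot(is(network, "ContextNetwork"), beta >= 0)
  c_uv <- edgeConfidence(network, u, v)
  if (u == v || c_uv == 0)
    stop(sprintf("no edge %s--%s in network", u, v))
  c_vv <- edgeConfidence(network, v, v)
  s_v <- unname(network@strength[[v]])
  c_uv / (1 + s_v - c_uv - c_vv)^beta
}

#' Score of a path as the product of step factors
#'
#' Multiplies [stepFactor()] over successive edges of the path, entering
#' each node in turn. A single-node (or empty) path scores 1.0 — the empty
#' product, used when the substrate itself carries the binding domain.
#'
#' @param network a [ContextNetwork-class].
#' @param path character vector of node ids; consecutive nodes must be
#'   connected.
#' @param beta hub-penalty exponent.
#' @return numeric scalar in \[0,1\].
#' @export
pathScore <- function(network, path, beta = 0.34) {
  if (length(path) <= 1L) return(1.0)
  score <- 1.0
  for (i in seq_len(length(path) - 1L))
    score <- score * stepFactor(network, path[i], path[i + 1L], beta)
  score
}

.better_path <- function(score, hops, endid, best) {
  # tie rule: higher score, then fewer hops, then lexicographic end node
  if (score > best$score) return(TRUE)
  if (score < best$score) return(FALSE)
  if (hops < best$hops) return(TRUE)
  if (hops > best$hops) return(FALSE)
  endid < best$end
}

#' Best hub-penalized association of a substrate with a target set
#'
#' Maximizes [pathScore()] over all paths of at most `maxHops` edges from
#' the substrate to any member of `targetSet`. Implemented as hop-layered
#' dynamic programming over walks — exact for the best simple path because
#' every step factor lies in (0,1], so deleting a cycle from a walk never
#' lowers its score or raises its hop count. A substrate that is itself a
#' target scores 1.0 with the single-node path; a substrate absent from the
#' network, or with no path to a target within the hop bound, scores 0 with
#' no interactor. Ties between equal-score paths are broken by fewer hops,
#' then lexicographically smaller interactor id.
#'
#' @param network a [ContextNetwork-class].
#' @param substrate protein id carrying the motif match.
#' @param targetSet non-empty character vector of domain-carrier ids.
#' @param beta hub-penalty exponent.
#' @param maxHops maximum number of edges in a path (>= 1).
#' @return list with elements `substrate`, `interactor` (id or `NA`),
#'   `path` (character vector, empty when no path), `score`.
#' @export
bestAssociation <- function(network, substrate, targetSet,
                            beta = 0.34, maxHops = 3L) {
  stopifnot(is(network, "ContextNetwork"), maxHops >= 1L)
  if (!length(targetSet)) stop("targetSet must not be empty")
  if (substrate %in% targetSet)
    return(list(substrate = substrate, interactor = substrate,
                path = substrate, score = 1.0))
  if (!(substrate %in% network@nodes))
    return(list(substrate = substrate, interactor = NA_character_,
                path = character(0), score = 0))
  nodes <- network@nodes
  n <- length(nodes)
  # layer[h, v]: best score over walks substrate -> v with exactly h hops
  score_prev <- setNames(rep(-Inf, n), nodes)
  score_prev[substrate] <- 1.0
  pred <- matrix(NA_character_, nrow = maxHops, ncol = n,
                 dimnames = list(NULL, nodes))
  layers <- vector("list", maxHops)
  for (h in seq_len(maxHops)) {
    score_cur <- setNames(rep(-Inf, n), nodes)
    reached <- names(score_prev)[is.finite(score_prev)]
    for (u in reached) {
      nb <- network@adjacency[[u]]
      for (j in seq_along(nb)) {
        v <- names(nb)[j]
        sc <- score_prev[[u]] * stepFactor(network, u, v, beta)
        if (sc > score_cur[[v]]) {        # u scanned in sorted node order:
          score_cur[[v]] <- sc            # strict > keeps the lexicographically
          pred[h, v] <- u                 # smallest predecessor on ties
        }
      }
    }
    layers[[h]] <- score_cur
    score_prev <- score_cur
  }
  res <- list(substrate = substrate, interactor = NA_character_,
              path = character(0), score = 0)
  winner <- list(score = -Inf, hops = .Machine$integer.max)
  for (h in seq_len(maxHops)) {          # ascending h: fewer hops wins ties
    for (t in sort(intersect(targetSet, nodes))) {
      sc <- layers[[h]][[t]]
      if (is.finite(sc) && .better_path(sc, h, t,
                                        list(score = winner$score,
                                             hops = winner$hops,
                                             end = res$interactor %||% "￿"))) {
        winner <- list(score = sc, hops = h)
        res$interactor <- t
        res$score <- sc
      }
    }
  }
  if (!is.na(res$interactor)) {
    path <- res$interactor
    v <- res$interactor
    for (h in seq(winner$hops, 1L)) {
      v <- pred[h, v]
      path <- c(v, path)
    }
    res$path <- unname(path)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Association scores for a set of substrates
#'
#' The target set is every protein annotated with at least one of the
#' requested domains. Each substrate gets its [bestAssociation()]; the
#' highest-scoring potential interactor is the one reported. Substrates
#' absent from the network score 0.
#'
#' @param network a [ContextNetwork-class].
#' @param substrates character vector of substrate protein ids.
#' @param domainTable data.frame with columns `protein_id`,
#'   `domain_accession` (see [readDomainTable()]).
#' @param domains one or more domain accessions of interest.
#' @param beta hub-penalty exponent.
#' @param maxHops path hop bound.
#' @return named list (one entry per unique substrate) of
#'   [bestAssociation()] results.
#' @export
associationScores <- function(network, substrates, domainTable, domains,
                              beta = 0.34, maxHops = 3L) {
  carriers <- domainCarriers(domainTable, domains)
  subs <- unique(substrates)
  setNames(lapply(subs, function(s)
    bestAssociation(network, s, carriers, beta = beta, maxHops = maxHops)),
    subs)
}

#' Proteins carrying any of the requested domains
#' @param domainTable data.frame with columns `protein_id`,
#'   `domain_accession`.
#' @param domains character vector of domain accessions.
#' @return character vector of carrier protein ids (union over domains).
#' @export
domainCarriers <- function(domainTable, domains) {
  stopifnot(length(domains) >= 1L)
  carriers <- unique(domainTable$protein_id[
    domainTable$domain_accession %in% domains])
  if (!length(carriers))
    stop(sprintf("no protein carries any of the requested domain(s): %s",
                 paste(domains, collapse = ", ")))
  carriers
}

#' Tabulate association results
#' @param assoc named list as returned by [associationScores()].
#' @return data.frame with columns `substrate_id`, `best_interactor`,
#'   `association_score`, `hops`.
#' @export
associationTable <- function(assoc) {
  data.frame(substrate_id = vapply(assoc, `[[`, character(1), "substrate"),
             best_interactor = vapply(assoc, `[[`, character(1), "interactor"),
             association_score = vapply(assoc, `[[`, numeric(1), "score"),
             hops = vapply(assoc, function(a)
               max(length(a$path) - 1L, 0L), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
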