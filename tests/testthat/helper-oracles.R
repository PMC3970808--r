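# Independent oracles used across the suite. These deliberately avoid the
# package's DP / vectorized code paths: plain enumeration and pairwise
# counting only.

# exhaustive simple-path enumeration: best hub-penalized path from
# `substrate` to any node in `targets` with <= maxHops edges
oracle_best_association <- function(net, substrate, targets, beta, maxHops) {
  if (substrate %in% targets)
    return(list(interactor = substrate, path = substrate, score = 1.0))
  best <- list(interactor = NA_character_, path = character(0), score = 0,
               hops = Inf)
  if (!(substrate %in% networkNodes(net))) return(best[1:3])
  recurse <- function(path, score) {
    tail <- path[length(path)]
    if (length(path) > 1L && tail %in% targets) {
      hops <- length(path) - 1L
      if (score > best$score ||
          (score == best$score && hops < best$hops) ||
          (score == best$score && hops == best$hops && tail < best$interactor)) {
        best <<- list(interactor = tail, path = path, score = score,
                      hops = hops)
      }
    }
    if (length(path) - 1L >= maxHops) return()
    nbs <- names(which(sapply(networkNodes(net), function(v)
      v != tail && edgeConfidence(net, tail, v) > 0)))
    for (v in setdiff(nbs, path)) {
      recurse(c(path, v), score * stepFactor(net, tail, v, beta))
    }
  }
  recurse(substrate, 1.0)
  best[c("interactor", "path", "score")]
}

# random connected-ish weighted graph on <= maxNodes nodes
random_graph <- function(maxNodes = 8L, p_edge = 0.45, p_selfloop = 0.15) {
  n <- sample(2:maxNodes, 1L)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(ids, 2L)
  keep <- runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample(ncol(pairs), 1L)] <- TRUE
  edges <- data.frame(a = pairs[1L, keep], b = pairs[2L, keep],
                      weight = round(runif(sum(keep), 0.05, 1), 3))
  loops <- ids[runif(n) < p_selfloop]
  if (length(loops))
    edges <- rbind(edges, data.frame(a = loops, b = loops,
                                     weight = round(runif(length(loops),
                                                          0.05, 1), 3)))
  ContextNetwork(edges)
}

# AUC as the normalized Mann-Whitney pairwise comparison count
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# direct per-window PSSM rescore, independent of scanMotif's vectorization
oracle_window_score <- function(pssm, window) {
  lo <- logOddsMatrix(pssm)
  res <- strsplit(window, "")[[1]]
  s <- 0
  for (p in seq_along(res)) s <- s + unname(lo[res[p], p])
  s
}

uniform_bg <- function() {
  setNames(rep(0.05, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
}

toy_proteome <- function() {
  Proteome(c(P1 = "AVKTEG", P2 = "MGETDV", P3 = "ETDVAG"))
}

toy_two_edge_network <- function() {
  ContextNetwork(data.frame(a = c("A", "B"), b = c("B", "C"),
                            weight = c(0.8, 0.5)))
}
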