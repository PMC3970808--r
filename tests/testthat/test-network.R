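test_that("step factor matches the hub-penalty closed form", {
  net <- toy_two_edge_network()
  # S(B) = 0.8 + 0.5; denominator 1 + 1.3 - 0.8 = 1.5
  expect_equal(stepFactor(net, "A", "B", beta = 0.34), 0.8 / 1.5^0.34)
  # entering C, whose only neighbor is B: denominator 1, factor = confidence
  expect_equal(stepFactor(net, "B", "C", beta = 0.34), 0.5)
  expect_error(stepFactor(net, "A", "C"), "no edge")
})

test_that("an isolated edge's step factor equals its confidence exactly", {
  net <- ContextNetwork(data.frame(a = "A", b = "B", weight = 0.73))
  expect_identical(stepFactor(net, "A", "B", beta = 0.34), 0.73)
  expect_identical(stepFactor(net, "B", "A", beta = 0.34), 0.73)
})

test_that("beta = 0 removes the hub penalty for any topology", {
  set.seed(21)
  for (rep in 1:5) {
    net <- random_graph()
    e <- networkEdges(net)
    proper <- e[e$a != e$b, ]
    for (i in seq_len(nrow(proper)))
      expect_identical(stepFactor(net, proper$a[i], proper$b[i], beta = 0),
                       proper$weight[i])
  }
})

test_that("self-loops enter both strength and the denominator subtraction", {
  net <- ContextNetwork(data.frame(a = c("A", "B"), b = c("B", "B"),
                                   weight = c(0.8, 0.6)))
  # S(B) = 0.8 + 0.6; subtracting C(A,B) and C(B,B) restores denominator 1
  expect_equal(stepFactor(net, "A", "B", beta = 0.34), 0.8)
})

test_that("path score is the sequential product of step factors", {
  net <- toy_two_edge_network()
  expect_identical(pathScore(net, "A"), 1.0)                 # empty product
  expect_equal(pathScore(net, c("A", "B")), stepFactor(net, "A", "B"))
  expect_equal(pathScore(net, c("A", "B", "C")),
               (0.8 / 1.5^0.34) * 0.5)
  expect_error(pathScore(net, c("A", "C")), "no edge")
})

test_that("step factors are direction dependent and bounded by the confidence", {
  set.seed(31)
  for (rep in 1:10) {
    net <- random_graph()
    e <- networkEdges(net)
    proper <- e[e$a != e$b, ]
    for (i in seq_len(nrow(proper))) {
      f_ab <- stepFactor(net, proper$a[i], proper$b[i], beta = 0.34)
      f_ba <- stepFactor(net, proper$b[i], proper$a[i], beta = 0.34)
      expect_lte(f_ab, proper$weight[i])
      expect_lte(f_ba, proper$weight[i])
      expect_gt(f_ab, 0)
    }
  }
})

test_that("substrate identity and disconnection edge cases", {
  net <- toy_two_edge_network()
  self <- bestAssociation(net, "C", c("C", "A"))
  expect_identical(self$score, 1.0)
  expect_identical(self$path, "C")
  expect_identical(self$interactor, "C")

  absent <- bestAssociation(net, "ZZ", "A")
  expect_identical(absent$score, 0)
  expect_identical(absent$interactor, NA_character_)
  expect_length(absent$path, 0)

  # reachable only beyond the hop bound
  chain <- ContextNetwork(data.frame(a = c("A", "B", "C"),
                                     b = c("B", "C", "D"),
                                     weight = c(0.9, 0.9, 0.9)))
  expect_gt(bestAssociation(chain, "A", "D", maxHops = 3L)$score, 0)
  expect_identical(bestAssociation(chain, "A", "D", maxHops = 2L)$score, 0)

  expect_error(bestAssociation(net, "A", character(0)), "targetSet")
})

test_that("hop-bounded DP equals exhaustive simple-path enumeration on random graphs", {
  set.seed(1234)
  for (rep in 1:30) {
    net <- random_graph(8L)
    nodes <- networkNodes(net)
    substrate <- sample(nodes, 1L)
    targets <- sample(setdiff(nodes, substrate),
                      min(2L, length(nodes) - 1L))
    maxHops <- sample(2:4, 1L)
    dp <- bestAssociation(net, substrate, targets, beta = 0.34,
                          maxHops = maxHops)
    oracle <- oracle_best_association(net, substrate, targets, 0.34, maxHops)
    expect_identical(dp$score, oracle$score)
    expect_identical(dp$interactor, oracle$interactor)
    if (dp$score > 0)
      expect_equal(pathScore(net, dp$path, 0.34), dp$score)
  }
})

test_that("the reported best path reproduces the reported score", {
  set.seed(77)
  for (rep in 1:10) {
    net <- random_graph(8L)
    nodes <- networkNodes(net)
    res <- bestAssociation(net, nodes[1L], nodes[length(nodes)],
                           maxHops = 3L)
    if (res$score > 0) {
      expect_identical(res$path[1L], nodes[1L])
      expect_identical(res$path[length(res$path)], res$interactor)
      expect_equal(pathScore(net, res$path), res$score)
    }
  }
})

test_that("adding an off-path edge to an intermediate node lowers scores through it", {
  set.seed(404)
  for (rep in 1:100) {
    w1 <- round(runif(1, 0.2, 1), 3)
    w2 <- round(runif(1, 0.2, 1), 3)
    w_extra <- round(runif(1, 0.05, 1), 3)
    base <- ContextNetwork(data.frame(a = c("A", "B"), b = c("B", "C"),
                                      weight = c(w1, w2)))
    # extra edge incident to intermediate B, not on the A-B-C path
    perturbed <- ContextNetwork(data.frame(a = c("A", "B", "B"),
                                           b = c("B", "C", "D"),
                                           weight = c(w1, w2, w_extra)))
    expect_lt(stepFactor(perturbed, "A", "B", beta = 0.34),
              stepFactor(base, "A", "B", beta = 0.34))
    expect_lt(pathScore(perturbed, c("A", "B", "C"), beta = 0.34),
              pathScore(base, c("A", "B", "C"), beta = 0.34))
  }
})

test_that("appending an edge to a path never increases its score", {
  set.seed(55)
  for (rep in 1:20) {
    net <- random_graph(8L)
    nodes <- networkNodes(net)
    v <- sample(nodes, 1L)
    path <- v
    repeat {
      nbs <- setdiff(Filter(function(x) edgeConfidence(net, path[length(path)],
                                                       x) > 0, nodes), path)
      if (!length(nbs)) break
      path <- c(path, sample(nbs, 1L))
      if (length(path) > 4L) break
    }
    if (length(path) >= 3L)
      for (i in 2:(length(path) - 1L))
        expect_gte(pathScore(net, path[1:i]), pathScore(net, path[1:(i + 1L)]))
  }
})

test_that("beta = 0 reduces every path score to the plain confidence product", {
  set.seed(66)
  for (rep in 1:10) {
    net <- random_graph(8L)
    nodes <- networkNodes(net)
    res <- bestAssociation(net, nodes[1L], nodes[length(nodes)], beta = 0,
                           maxHops = 3L)
    if (res$score > 0) {
      confs <- vapply(seq_len(length(res$path) - 1L), function(i)
        edgeConfidence(net, res$path[i], res$path[i + 1L]), numeric(1))
      expect_equal(res$score, prod(confs))
    }
  }
})

test_that("association scoring unions carriers over domains and ignores order", {
  dom <- data.frame(protein_id = c("C", "D", "E"),
                    domain_accession = c("PF1", "PF2", "PF1"))
  expect_setequal(domainCarriers(dom, c("PF1", "PF2")), c("C", "D", "E"))
  expect_error(domainCarriers(dom, "PF9"), "PF9")

  net <- ContextNetwork(data.frame(a = c("A", "A", "B", "B"),
                                   b = c("C", "B", "C", "D"),
                                   weight = c(0.9, 0.4, 0.5, 0.7)))
  r1 <- associationScores(net, c("A", "B"), dom, "PF1")
  r2 <- associationScores(net, c("B", "A"), dom, "PF1")
  expect_identical(r1[["A"]], r2[["A"]])
  expect_identical(r1[["B"]], r2[["B"]])
  # direct strong edge beats weak two-hop detour
  expect_identical(r1[["A"]]$interactor, "C")
  # absent substrate scores zero
  r3 <- associationScores(net, "NOPE", dom, "PF1")
  expect_identical(r3[["NOPE"]]$score, 0)
})

test_that("a strong direct edge outranks a weak multiplicative detour", {
  net <- ContextNetwork(data.frame(a = c("A", "A", "M"),
                                   b = c("T", "M", "T"),
                                   weight = c(0.9, 0.5, 0.4)))
  res <- bestAssociation(net, "A", "T", beta = 0.34, maxHops = 3L)
  expect_identical(res$path, c("A", "T"))
  oracle <- oracle_best_association(net, "A", "T", 0.34, 3L)
  expect_identical(res$score, oracle$score)
})

test_that("association scores always lie in [0, 1]", {
  set.seed(88)
  for (rep in 1:10) {
    net <- random_graph(8L)
    nodes <- networkNodes(net)
    for (s in nodes) {
      sc <- bestAssociation(net, s, nodes[length(nodes)], maxHops = 3L)$score
      expect_gte(sc, 0); expect_lte(sc, 1)
    }
  }
})
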