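test_that("the restricted regex dialect compiles field motifs and flags anchors", {
  sumo <- compileMotifRegex("[VILMAFP](K).E")
  expect_false(sumo@anchoredCterm)
  expect_equal(sumo@anchorGroup, 1L)

  pdz <- compileMotifRegex(".[DEFILSTVY].[ACVILF]$")
  expect_true(pdz@anchoredCterm)
  expect_true(is.na(pdz@anchorGroup))

  # quantifiers, including whitespace inside braces
  expect_s4_class(compileMotifRegex("A{2}K+E*[DE]{3, 4}"), "RegexMotif")
})

test_that("unsupported regex constructs are rejected by name", {
  expect_error(compileMotifRegex("A|B"), "alternation")
  expect_error(compileMotifRegex("A(?=K)"), "lookaround")
  expect_error(compileMotifRegex("\\d"), "escape")
  expect_error(compileMotifRegex("(A)(B)"), "one capture group")
  expect_error(compileMotifRegex("[B]"), "amino-acid codes")
  expect_error(compileMotifRegex("*A"), "quantifier")
  expect_error(compileMotifRegex("A[DE"), "unterminated")
})

test_that("regex scan reports every start position, honors the C-terminal anchor", {
  p <- toy_proteome()
  m <- scanMotif(p, compileMotifRegex("[VILMAFP](K).E"))
  expect_equal(m$protein_id, "P1")
  expect_equal(m$start, 2L)
  expect_equal(m$end, 5L)
  expect_equal(m$matched_peptide, "VKTE")
  expect_equal(m$anchor_pos, 3L)     # the captured modified lysine
  expect_identical(attr(m, "scoreMode"), "binary")
  expect_true(all(is.na(m$motif_score)))

  pdz <- compileMotifRegex(".[DEFILSTVY].[ACVILF]$")
  mm <- scanMotif(p, pdz)
  # P2 "MGETDV" matches at the terminus; P3 "ETDVAG" has internal pattern
  # text only, excluded by the anchor
  expect_equal(mm$protein_id, "P2")
  expect_equal(mm$end, 6L)
  expect_false("P3" %in% mm$protein_id)
})

test_that("overlapping matches are all reported", {
  m <- scanMotif(c(P1 = "KKKK"), compileMotifRegex("KK"))
  expect_equal(m$start, 1:3)
})

test_that("scan results are invariant under proteome entry order", {
  seqs <- c(P1 = "AVKTEGLKSE", P2 = "MGETDVVKAE", P3 = "PKWEAVKTE")
  m1 <- scanMotif(seqs, compileMotifRegex("[VILMAFP](K).E"))
  m2 <- scanMotif(seqs[c(3, 1, 2)], compileMotifRegex("[VILMAFP](K).E"))
  expect_identical(m1, m2)
  bg <- uniform_bg()
  ps <- buildPSSM(c("VKTE", "LKSE"), bg)
  s1 <- scanMotif(seqs, ps)
  s2 <- scanMotif(seqs[c(2, 3, 1)], ps)
  expect_identical(s1, s2)
})

test_that("background frequencies follow add-one smoothing with the floor rule", {
  p <- suppressWarnings(Proteome(c(P1 = "AAAA")))
  bg <- backgroundFrequencies(p)
  expect_equal(sum(bg), 1, tolerance = 1e-12)
  expect_true(all(bg > 0))
  expect_equal(bg[["A"]], 5 / 24)          # (4+1)/(4+20)
  expect_equal(bg[["W"]], 1 / 24)          # absent residue floor 1/(total+20)

  # equal counts of all 20 residues -> uniform 0.05
  p2 <- Proteome(c(P1 = "ACDEFGHIKLMNPQRSTVWY"))
  expect_equal(unname(backgroundFrequencies(p2)), rep(0.05, 20))

  expect_error(backgroundFrequencies(Proteome(c(P1 = "XXX"))),
               "no canonical residues")
})

test_that("PSSM background correction: columns matching background give zero log-odds", {
  # column usage exactly equal to the background: uniform background,
  # one peptide per residue
  bg <- uniform_bg()
  peps <- names(bg)                     # 20 length-1 peptides
  pssm <- buildPSSM(peps, bg, pseudocountTotal = 1)
  expect_equal(unname(logOddsMatrix(pssm)[, 1]), rep(0, 20), tolerance = 1e-12)
  # and the identity is pseudocount-independent (pseudocounts are
  # background-proportional)
  pssm0 <- buildPSSM(peps, bg, pseudocountTotal = 0)
  expect_equal(unname(logOddsMatrix(pssm0)[, 1]), rep(0, 20), tolerance = 1e-12)
})

test_that("PSSM pseudocount arithmetic matches the closed form", {
  bg <- uniform_bg()
  pssm <- buildPSSM("K", bg, pseudocountTotal = 1)
  # single peptide: phat(K) = (1 + 1*0.05) / (1 + 1)
  expect_equal(unname(logOddsMatrix(pssm)["K", 1]),
               log2(((1 + 0.05) / 2) / 0.05))
  expect_equal(unname(logOddsMatrix(pssm)["A", 1]),
               log2((0.05 / 2) / 0.05))
})

test_that("zero pseudocounts yield -Inf for absent residues and non-matching windows", {
  bg <- uniform_bg()
  pssm <- buildPSSM("K", bg, pseudocountTotal = 0)
  expect_identical(unname(logOddsMatrix(pssm)["A", 1]), -Inf)
  sc <- scanMotif(c(P1 = "AK"), pssm)
  expect_equal(sc$motif_score[sc$matched_peptide == "A"], 0)
  expect_equal(sc$raw_score[sc$matched_peptide == "K"],
               log2((1 / 1) / 0.05))
})

test_that("PSSM build rejects unequal lengths and non-canonical residues", {
  expect_error(buildPSSM(c("VKTE", "VKT"), uniform_bg()), "VKT")
  expect_error(buildPSSM(c("VKXE"), uniform_bg()), "canonical")
  expect_error(buildPSSM(character(0), uniform_bg()), "empty")
})

test_that("PSSM scan agrees with a direct-summation oracle on random windows", {
  set.seed(314)
  bg <- uniform_bg()
  peps <- replicate(6, paste(sample(names(bg), 5, TRUE), collapse = ""))
  pssm <- buildPSSM(peps, bg)
  seqs <- setNames(replicate(4, paste(sample(names(bg), 60, TRUE),
                                      collapse = "")),
                   sprintf("P%d", 1:4))
  sc <- scanMotif(seqs, pssm)
  idx <- sample(nrow(sc), 100, replace = TRUE)
  for (i in idx)
    expect_equal(sc$raw_score[i], oracle_window_score(pssm,
                                                          sc$matched_peptide[i]))
})

test_that("windows containing X are skipped, never scored", {
  pssm <- buildPSSM(c("KK"), uniform_bg())
  sc <- suppressWarnings(scanMotif(Proteome(c(P1 = "KXKK")), pssm))
  expect_equal(sc$start, 3L)          # only the X-free window
})

test_that("training peptides score above background windows on average", {
  set.seed(99)
  bg <- uniform_bg()
  peps <- c("VKSE", "IKTE", "LKAE", "VKTE")
  pssm <- buildPSSM(peps, bg)
  train_scores <- scorePeptides(pssm, peps)
  random_windows <- replicate(1000, paste(sample(names(bg), 4, TRUE),
                                          collapse = ""))
  expect_true(all(train_scores >= mean(scorePeptides(pssm, random_windows))))
})

test_that("logistic normalization maps 0 to 0.5, -Inf to 0, and preserves ranking", {
  expect_equal(normalizeScores(0), 0.5)
  expect_equal(normalizeScores(-Inf), 0)
  expect_equal(normalizeScores(1e6), 1)      # saturates without NaN
  set.seed(5)
  raw <- c(rnorm(50, sd = 10), -Inf)
  norm <- normalizeScores(raw)
  expect_true(all(norm >= 0 & norm <= 1))
  expect_equal(order(raw), order(norm))
  expect_equal(cor(rank(raw), rank(norm)), 1)   # Spearman rho = 1
})

test_that("external predictions become length-1 matches with min-max normalization", {
  p <- toy_proteome()
  tab <- data.frame(protein_id = c("P1", "P2", "P3"), position = c(2L, 3L, 1L),
                    score = c(2, 4, 6))
  m <- loadPredictions(tab, p)
  expect_equal(sort(m$motif_score), c(0, 0.5, 1))
  expect_equal(m$end - m$start, rep(0L, 3))
  expect_identical(attr(m, "scoreMode"), "graded")

  single <- loadPredictions(data.frame(protein_id = "P1", position = 1L,
                                       score = 7), p)
  expect_equal(single$motif_score, 1.0)

  tab$protein_id[2] <- "ABSENT"
  expect_warning(m2 <- loadPredictions(tab, p), "1 prediction row")
  expect_equal(nrow(m2), 2L)
  expect_error(
    loadPredictions(data.frame(protein_id = "NOPE", position = 1L, score = 1),
                    p),
    "no prediction row")
})
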