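# Metrics: PCC, AUC, sign test, rank curves, ROC, information divergence.

test_that("pcc reproduces hand-computed correlations", {
  x <- c(1, 2, 3, 4)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pcc(x, rep(1, 4)), "variance")
  expect_error(pcc(1, 2), "length")
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  pairCountAuc <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    g <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    mean(g)
  }
  expect_equal(aucScore(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(aucScore(rep(1, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)),
               0.5)
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  l <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(aucScore(s, l), pairCountAuc(s, l))
  # property: random vectors with heavy ties, n up to 200
  set.seed(19)
  for (n in c(10, 57, 200)) {
    s <- sample(1:8, n, replace = TRUE)          # integer scores force ties
    l <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(l) || all(l)) next
    expect_equal(aucScore(s, l), pairCountAuc(s, l), tolerance = 1e-12)
  }
  expect_error(aucScore(1:3, c(TRUE, TRUE, TRUE)), "absent")
})

test_that("binomial sign test matches direct tail summation", {
  expect_equal(binomialSignTest(10, 0), 2^-10)
  expect_equal(binomialSignTest(8, 2), 56 / 1024)
  expect_gte(binomialSignTest(7, 7), 0.5)
  for (n in c(1, 5, 12, 25)) {
    for (n1 in c(0, n %/% 2, n)) {
      direct <- sum(stats::dbinom(n1:n, n, 0.5))
      expect_equal(binomialSignTest(n1, n - n1), direct, tolerance = 1e-12)
    }
  }
  expect_error(binomialSignTest(0, 0), "n1 \\+ n2")
})

test_that("information divergence matches closed-form values", {
  expect_equal(informationDivergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(informationDivergence(c(1, 0), c(0.5, 0.5)), 1)
  expect_equal(informationDivergence(c(0.75, 0.25), c(0.5, 0.5)),
               0.1887219, tolerance = 1e-6)
  expect_error(informationDivergence(c(0.7, 0.3), c(1, 0)), "infinite")
  expect_error(informationDivergence(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")
  # named vectors are aligned by allele
  expect_equal(informationDivergence(c(a = 0.75, b = 0.25),
                                     c(b = 0.5, a = 0.5)),
               0.1887219, tolerance = 1e-6)
})

test_that("selection divergence of a balanced selection is zero", {
  alleles <- rep(c("A", "B"), each = 10)
  scores <- c(10:1, 10:1)          # same scale: top-k alternates evenly
  ranks <- rep(1:10, 2)
  dv <- selectionDivergence(alleles, scores, ranks, k = 10)
  expect_equal(unname(dv["rank"]), 0, tolerance = 1e-9)
  # scales apart: affinity selection picks only allele A
  dv2 <- selectionDivergence(alleles, c(20:11, 10:1), ranks, k = 10)
  expect_equal(unname(dv2["affinity"]), 1, tolerance = 1e-9)
  expect_gt(unname(dv2["affinity"]), unname(dv2["rank"]))
})

test_that("the internal ROC sweep agrees with the Mann-Whitney AUC", {
  set.seed(23)
  for (rep in 1:3) {
    s <- sample(1:10, 80, replace = TRUE)
    l <- runif(80) < plogis((s - 5))
    if (!any(l) || all(l)) next
    roc <- panMHC:::.rocCurve(s, l)
    expect_equal(roc$auc, aucScore(s, l), tolerance = 1e-12)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  }
})

test_that("cross-validation tables apply the inclusion thresholds", {
  fx <- tinyTrained()
  proteome <- makeProteome(5, 120, seed = 31)
  aug <- addArtificialNegatives(fx$sim$dataset, proteome, nPerLength = 5,
                                seed = 32)
  cfg <- panConfig(hidden = 8, nSeeds = 1, maxEpochs = 8, patience = 8,
                   seed = 33)
  ens <- trainEnsemble(aug, fx$world@pseudo, cfg)
  tab <- evaluateCrossValidation(ens, aug)
  expect_true(all(c("allele", "length", "n", "nBinders", "pcc", "auc",
                    "included") %in% names(tab)))
  expect_true(all(tab$included == (tab$nBinders >= 3 & tab$n >= 20)))
  # artificial negatives excluded from every cell count
  rec <- records(aug)
  real <- rec[!rec$is_artificial, ]
  for (i in seq_len(nrow(tab))) {
    expect_identical(tab$n[i],
                     sum(real$allele == tab$allele[i] &
                           nchar(real$peptide) == tab$length[i]))
  }
})

test_that("ligand rank curves are monotone and find planted top ligands", {
  fx <- tinyTrained()
  bench <- makeLigandBenchmark(fx$world, nProteins = 6, proteinLength = 60,
                               seed = 41)
  rc <- ligandRankCurve(fx$ens, bench$benchmark, bench$proteins)
  expect_true(all(diff(rc$curve$identified) >= 0))
  expect_true(all(rc$curve$identified >= 0 & rc$curve$identified <= 100))

  # a ligand that tops its protein is identified at the smallest threshold
  best <- which(rc$ranks == 0)
  if (length(best)) {
    one <- bench$benchmark[best[1], , drop = FALSE]
    rc1 <- ligandRankCurve(fx$ens, one, bench$proteins)
    expect_equal(rc1$curve$identified[1], 100)
  }

  # ligand absent from its protein: row skipped with a warning
  bad <- bench$benchmark
  bad$ligand[1] <- strrep("W", 9)
  expect_warning(rcb <- ligandRankCurve(fx$ens, bad, bench$proteins),
                 "skipped")
  expect_identical(rcb$skipped, 1L)
})

test_that("a random-scoring model identifies ligands at chance level", {
  world <- makeWorld(2, 0.9, seed = 51)
  bench <- makeLigandBenchmark(world, nProteins = 40, proteinLength = 80,
                               ligandsPerProtein = 2, seed = 52)
  ens <- randomEnsemble(world@pseudo, nNets = 1, hidden = 4, seed = 53)
  rc <- ligandRankCurve(ens, bench$benchmark, bench$proteins,
                        thresholds = c(10, 25, 50, 75))
  # untrained scores are unrelated to planting: identified% ~ selected%
  expect_true(all(abs(rc$curve$identified - rc$curve$threshold) < 18))
})

test_that("benchmark filtering keeps rows under the rank threshold", {
  fx <- tinyTrained()
  proteome <- makeProteome(4, 150, seed = 61)
  ens <- calibrateEnsemble(fx$ens, proteome, nPerLength = 200, seed = 62)
  bench <- makeLigandBenchmark(fx$world, nProteins = 10, proteinLength = 60,
                               seed = 63)$benchmark

  full <- benchmarkFilter(bench, list(ens), rankThreshold = 100)
  expect_identical(nrow(full), nrow(bench))
  expect_identical(attr(full, "removed"), 0L)

  none <- benchmarkFilter(bench, list(ens), rankThreshold = 0)
  expect_identical(nrow(none), 0L)   # mid-rank convention: no rank is <= 0

  # pick a threshold that splits the observed ranks
  pr <- do.call(rbind, lapply(unique(bench$allele), function(al)
    predictBinding(ens, al, bench$ligand[bench$allele == al])))
  th <- stats::median(pr$rank)
  part <- benchmarkFilter(bench, list(ens), rankThreshold = th)
  expect_lt(nrow(part), nrow(bench))
  expect_gt(nrow(part), 0L)
  expect_identical(nrow(part) + attr(part, "removed"), nrow(bench))

  uncal <- randomEnsemble(fx$world@pseudo, nNets = 1)
  expect_error(benchmarkFilter(bench, list(uncal)), "calibration")
})

test_that("rank and affinity ROCs coincide for a single allele", {
  fx <- tinyTrained()
  proteome <- makeProteome(4, 150, seed = 71)
  ens <- calibrateEnsemble(fx$ens, proteome, nPerLength = 200, seed = 72)
  world1 <- fx$world
  bench <- makeLigandBenchmark(world1, nProteins = 8, proteinLength = 60,
                               seed = 73)
  one <- bench$benchmark[bench$benchmark$allele == world1@alleles[1], ]
  roc <- rankVsAffinityRoc(ens, one, bench$proteins)
  # per-allele rank is a monotone transform of the score (up to the
  # finite resolution of the calibration sample)
  expect_equal(roc$affinity$auc, roc$rank$auc, tolerance = 0.01)
  # sensitivity cannot rise as specificity tightens
  expect_true(all(diff(roc$sensitivity$affinity) <= 1e-12))
})
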