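# Partitioning, artificial negatives and ensemble orchestration.

test_that("peptides sharing an 8mer land in the same partition", {
  ds <- AffinityDataset(rep("A1", 3),
                        c("AAAAAAAAA", "AAAAAAAAC", "CDEFGHIKL"),
                        c(50, 100, 200))
  p <- partitionCommon8mer(ds, nParts = 5, seed = 1)
  expect_identical(p[1], p[2])   # share 8mer AAAAAAAA
})

test_that("disjoint peptides are balanced across partitions", {
  set.seed(7)
  peps <- unique(randomPeptideSet(150, lengths = 9, seed = 7))[1:100]
  ds <- AffinityDataset(rep("A1", 100), peps, rep(100, 100))
  p <- partitionCommon8mer(ds, nParts = 5, seed = 3)
  expect_identical(sort(unique(p)), 1:5)
  expect_true(all(abs(table(p) - 20) <= 1))
})

test_that("no 8mer segment is shared between partitions (property)", {
  # multi-length peptides with deliberate overlaps
  set.seed(31)
  base <- randomPeptideSet(60, lengths = 9:11, seed = 31)
  shifted <- vapply(base[1:30], function(p)
    paste0(substr(p, 2, nchar(p)),
           sample(panMHC:::AA_ALPHABET, 1)), character(1))
  peps <- unique(c(base, shifted))
  ds <- AffinityDataset(rep("A1", length(peps)), peps,
                        rep(500, length(peps)))
  p <- partitionCommon8mer(ds, nParts = 5, seed = 2)
  mers <- lapply(split(records(ds)$peptide, p), function(ps)
    unique(unlist(lapply(ps, panMHC:::.eightMers))))
  for (i in seq_along(mers))
    for (j in seq_len(i - 1))
      expect_length(intersect(mers[[i]], mers[[j]]), 0)
  # determinism
  expect_identical(p, partitionCommon8mer(ds, nParts = 5, seed = 2))
})

test_that("one dominant cluster triggers a warning, not an error", {
  stem <- "ACDEFGHIKLMNPQ"   # all windows share 8mers with each other
  peps <- unique(substring(stem, 1:6, 9:14))
  ds <- AffinityDataset(rep("A1", length(peps)), peps,
                        rep(100, length(peps)))
  expect_warning(partitionCommon8mer(ds, nParts = 5, seed = 1),
                 "unbalanced")
})

test_that("artificial negatives follow the 25-per-length recipe", {
  proteome <- makeProteome(5, 80, seed = 2)
  ds1 <- AffinityDataset("A1", "ACDEFGHIK", 50)
  aug <- addArtificialNegatives(ds1, proteome, seed = 4)
  r <- records(aug)
  added <- r[r$is_artificial, ]
  expect_identical(nrow(added), 100L)                 # 25 x 4 lengths
  expect_true(all(added$target == 0))
  expect_true(all(added$ic50 == 50000))
  expect_identical(as.vector(table(nchar(added$peptide))), rep(25L, 4))
  # negatives are real proteome windows
  expect_true(all(vapply(added$peptide[1:10], function(p)
    any(grepl(p, proteome, fixed = TRUE)), logical(1))))

  ds3 <- AffinityDataset(c("A1", "A2", "A3"),
                         rep("ACDEFGHIK", 3), rep(50, 3))
  aug3 <- addArtificialNegatives(ds3, proteome, seed = 4)
  expect_identical(sum(records(aug3)$is_artificial), 300L)

  expect_identical(addArtificialNegatives(ds1, proteome, nPerLength = 0),
                   ds1)
  expect_error(addArtificialNegatives(ds1, c(p = "ACDEF"), seed = 1),
               "shorter")
  # reproducible
  expect_identical(records(addArtificialNegatives(ds1, proteome, seed = 4)),
                   records(aug))
})

test_that("all-9mer NNAlign training reduces to plain back-propagation", {
  pseudo <- toyPseudoMap()
  set.seed(9)
  peps <- unique(randomPeptideSet(40, lengths = 9, seed = 9))
  n <- length(peps)
  rec <- data.frame(allele = "HLA-T*01:01", peptide = peps,
                    target = runif(n), stringsAsFactors = FALSE)
  tr <- rec[1:(n - 10), ]; st <- rec[(n - 9):n, ]
  net <- trainNNAlign(tr, st, pseudo, hidden = 6, seed = 12,
                      maxEpochs = 15, patience = 100)
  # same data through the generic early-stopping trainer, same seed
  enc <- panMHC:::.encodeAll(rec$peptide, rec$allele, pseudo)
  fit <- trainEarlyStopping(enc$X[1:(n - 10), ], tr$target,
                            enc$X[(n - 9):n, ], st$target,
                            hidden = 6, seed = 12, maxEpochs = 15,
                            patience = 100)
  expect_identical(net$W1, fit$net$W1)
  expect_identical(net$b2, fit$net$b2)
})

test_that("training fails informatively when an allele lacks a pseudo-sequence", {
  pseudo <- toyPseudoMap()
  rec <- data.frame(allele = c("HLA-T*01:01", "HLA-T*09:99"),
                    peptide = rep("ACDEFGHIK", 2), target = c(0.5, 0.5))
  expect_error(trainNNAlign(rec, rec, pseudo, maxEpochs = 1),
               "HLA-T\\*09:99")
})

test_that("ensemble structure follows partitions x architectures x seeds", {
  fx <- tinyTrained()
  ens <- fx$ens                      # 5 partitions x 1 arch x 1 seed
  expect_length(networks(ens), 5L)
  prov <- data.frame(
    partition = vapply(networks(ens), `[[`, numeric(1), "partition"),
    stopPart = vapply(networks(ens), `[[`, numeric(1), "stopPartition"))
  expect_setequal(prov$partition, 1:5)
  expect_true(all(prov$stopPart != prov$partition))

  expect_error(trainEnsemble(fx$sim$dataset, fx$world@pseudo,
                             panConfig(nPartitions = 4)),
               "at least 5")
})

test_that("ensemble training is reproducible from the master seed", {
  world <- makeWorld(1, 1, seed = 55)
  sim <- sampleDataset(world, 60, noiseSd = 0.05, seed = 56)
  cfg <- panConfig(hidden = 8, nSeeds = 1, maxEpochs = 6, patience = 6,
                   seed = 57)
  e1 <- trainEnsemble(sim$dataset, world@pseudo, cfg)
  e2 <- trainEnsemble(sim$dataset, world@pseudo, cfg)
  for (k in seq_along(networks(e1))) {
    expect_identical(networks(e1)[[k]]$W1, networks(e2)[[k]]$W1)
    expect_identical(networks(e1)[[k]]$b2, networks(e2)[[k]]$b2)
  }
  expect_identical(e1@partition, e2@partition)
})

test_that("iterative core selection recovers a planted motif's cores", {
  world <- makeWorld(1, 1, seed = 71)
  sim <- sampleDataset(world, 220, lengthMix = c(0, 0.5, 0.5, 0),
                       noiseSd = 0.05, seed = 72)
  cfg <- panConfig(hidden = 12, nSeeds = 1, maxEpochs = 50, patience = 12,
                   seed = 73)
  ens <- trainEnsemble(sim$dataset, world@pseudo, cfg)
  cv <- cvPredictions(ens, sim$dataset)
  tr <- sim$truth
  sel <- tr$planted & tr$length == 10
  expect_gt(mean(cv$core[sel] == tr$plantedCore[sel]), 0.6)
  expect_gt(pcc(cv$score, cv$target), 0.7)
})
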