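# Affinity transform, core enumeration and input encoding.

test_that("affinity transform maps the canonical landmarks", {
  expect_equal(transformAffinity(1), 1)
  expect_equal(transformAffinity(50000), 0)
  # independently evaluated 1 - log(500)/log(50000)
  expect_equal(transformAffinity(500), 0.4256252, tolerance = 1e-6)
  expect_true(all(diff(transformAffinity(c(1, 10, 100, 1000, 50000))) < 0))
  # clamped outside the 1..50000 nM range
  expect_equal(transformAffinity(1e6), 0)
  expect_equal(transformAffinity(0.5), 1)
  expect_error(transformAffinity(0), "positive")
  expect_error(transformAffinity(-3), "positive")
})

test_that("inverse transform inverts the affinity transform", {
  expect_equal(inverseTransform(0), 50000)
  expect_equal(inverseTransform(1), 1)
  expect_equal(inverseTransform(0.5), 223.6068, tolerance = 1e-4)
  ic50 <- c(1, 5, 50, 500, 5000, 49999)
  expect_equal(inverseTransform(transformAffinity(ic50)), ic50,
               tolerance = 1e-6)
  expect_error(inverseTransform(1.2), "0, 1")
  expect_error(inverseTransform(-0.1), "0, 1")
})

test_that("core enumeration yields the documented candidate sets", {
  c9 <- enumerateCores("ACDEFGHIK")
  expect_identical(nrow(c9), 1L)
  expect_identical(c9$core, "ACDEFGHIK")
  expect_identical(c9$gapKind, "none")

  c8 <- enumerateCores("ACDEFGHI")
  expect_identical(nrow(c8), 9L)
  expect_identical(c8$core[1], "XACDEFGHI")
  expect_identical(c8$core[9], "ACDEFGHIX")
  expect_true(all(c8$gapKind == "insertion"))
  expect_identical(c8$indelPos, 0:8)
  expect_true(all(nchar(c8$core) == 9))

  c10 <- enumerateCores("ACDEFGHIKL")
  expect_identical(nrow(c10), 10L)
  off0 <- c10[1, ]
  expect_identical(off0$core, "CDEFGHIKL")
  expect_identical(off0$gapKind, "protrusion")
  expect_identical(off0$pfrLeft, 1L)
  off4 <- c10[5, ]
  expect_identical(off4$core, "ACDEGHIKL")
  expect_identical(off4$gapKind, "deletion")
  expect_identical(off4$indelLen, 1L)

  expect_error(enumerateCores("ACDEFGH"), "shorter than 8")
  expect_warning(enumerateCores(strrep("A", 14)), "8-13")
})

test_that("candidate counts and coverage match a brute-force enumerator", {
  # independent enumerator: all 9mers obtainable by removing one
  # consecutive window (L > 9) or inserting X at any position (L = 8)
  bruteCores <- function(pep) {
    L <- nchar(pep)
    if (L == 9) return(pep)
    if (L == 8)
      return(vapply(0:8, function(i)
        paste0(substr(pep, 1, i), "X", substr(pep, i + 1, 8)),
        character(1)))
    d <- L - 9
    vapply(0:(L - d), function(s)
      paste0(substr(pep, 1, s), substr(pep, s + d + 1, L)), character(1))
  }
  set.seed(42)
  for (L in 8:13) {
    for (rep in 1:3) {
      pep <- paste(sample(panMHC:::AA_ALPHABET, L, replace = TRUE),
                   collapse = "")
      got <- suppressWarnings(enumerateCores(pep))
      expect_identical(nrow(got), if (L == 8) 9L else if (L == 9) 1L else 10L)
      expect_setequal(got$core, bruteCores(pep))
      # bookkeeping: residues in core + PFR + deleted == L (X adds none)
      fromPeptide <- 9 - (got$gapKind == "insertion") * got$indelLen
      deleted <- ifelse(got$gapKind == "deletion", got$indelLen, 0)
      expect_true(all(got$pfrLeft + got$pfrRight + fromPeptide + deleted == L))
    }
  }
})

test_that("the batch candidate enumerator agrees with the reference", {
  set.seed(91)
  peps <- randomPeptideSet(40, lengths = 8:13, seed = 91)
  tab <- suppressWarnings(panMHC:::.candidateTable(peps))
  for (i in seq_along(peps)) {
    ref <- suppressWarnings(enumerateCores(peps[i]))
    sub <- tab[tab$pepIdx == i, ]
    expect_identical(sub$core, ref$core)
    expect_identical(sub$gapKind, ref$gapKind)
    expect_identical(sub$indelLen, ref$indelLen)
    expect_identical(sub$pfrLeft, ref$pfrLeft)
    expect_identical(sub$pfrRight, ref$pfrRight)
  }
  # and the assembled input rows match buildInput() per candidate
  pseudo <- toyPseudoMap()
  enc <- panMHC:::.encodeAll(peps[1:8], rep("HLA-T*01:01", 8), pseudo)
  ps <- pseudoSeqs(pseudo)[[1]]
  for (i in 1:8) {
    ref <- enumerateCores(peps[i])
    for (j in seq_len(nrow(ref))) {
      expect_identical(
        unname(enc$X[enc$candStart[i] + j, ]),
        unname(buildInput(ref[j, ], ps)))
    }
  }
})

test_that("BLOSUM encoding is symmetric, scaled, and zero for X", {
  expect_identical(blosumEncode("X"), rep(0, 20))
  expect_identical(blosumEncode("A"), blosumEncode("A"))
  aa <- panMHC:::AA_ALPHABET
  for (a in aa) {
    ba <- blosumEncode(a)
    for (b in aa) {
      expect_identical(ba[match(b, aa)], blosumEncode(b)[match(a, aa)])
    }
  }
  # scaling: diagonal of BLOSUM50 for A is 5 -> 1 after /5
  expect_identical(blosumEncode("A")[1], 1)
  expect_error(blosumEncode("AZJ"), "alphabet")
})

test_that("input vectors have the documented layout", {
  P <- 34
  pseudo <- strrep("A", P)
  a9 <- enumerateCores("ACDEFGHIK")
  v9 <- buildInput(a9, pseudo)
  expect_identical(length(v9), encodingDim(P))
  expect_identical(length(v9), 868L)
  lenBin <- v9[(180 + 20 * P + 1):(180 + 20 * P + 4)]
  expect_identical(lenBin, c(0, 1, 0, 0))
  expect_identical(utils::tail(v9, 4), rep(0, 4))   # aux all zero

  a8 <- enumerateCores("ACDEFGHI")[1, ]
  v8 <- buildInput(a8, pseudo)
  expect_identical(utils::tail(v8, 4)[1], 1 / 3)    # insertion length 1
  expect_identical(v8[(180 + 20 * P + 1):(180 + 20 * P + 4)], c(1, 0, 0, 0))

  a11 <- enumerateCores("ACDEFGHIKLM")
  del <- a11[a11$gapKind == "deletion", ][1, ]
  v11 <- buildInput(del, pseudo)
  expect_identical(utils::tail(v11, 4)[2], 0.5)     # deletion length 2
  expect_identical(v11[(180 + 20 * P + 1):(180 + 20 * P + 4)], c(0, 0, 0, 1))

  prot <- a11[1, ]                                  # left protrusion, PFR 2
  expect_identical(utils::tail(buildInput(prot, pseudo), 4)[3], 0.5)

  # purity: identical inputs give bit-identical vectors
  expect_identical(buildInput(a9, pseudo), buildInput(a9, pseudo))
})
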