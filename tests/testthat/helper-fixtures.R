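# Shared fixtures. Heavy objects (trained ensembles) are built once per
# test run and memoised here so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# deterministic toy pseudo-sequence map (width 10 keeps encodings small)
toyPseudoMap <- function(alleles = c("HLA-T*01:01", "HLA-T*02:01")) {
  seqs <- c("ACDEFGHIKL", "ACDEFGHIKV")[seq_along(alleles)]
  PseudoSeqMap(setNames(seqs, alleles))
}

# a network with every weight set to a constant (0 gives score 0.5)
constantNet <- function(D, H = 3, value = 0) {
  list(W1 = matrix(value, D, H), b1 = rep(value, H), W2 = rep(value, H),
       b2 = value, partition = 1L, arch = as.integer(H), seedIndex = 1L,
       stopPartition = 2L, bestEpoch = 0L, netSeed = 0L)
}

# wrap explicit networks into a PanEnsemble without training
mockEnsemble <- function(nets, pseudo, partition = integer(0)) {
  new("PanEnsemble", networks = nets, pseudo = pseudo,
      config = panConfig(), partition = as.integer(partition),
      calibrations = list(),
      version = panMHC:::MODEL_FORMAT_VERSION)
}

# an ensemble of random untrained networks over a pseudo map
randomEnsemble <- function(pseudo, nNets = 2, hidden = 4, seed = 7) {
  D <- encodingDim(pseudo@width)
  nets <- lapply(seq_len(nNets), function(i) {
    n <- newNetwork(D, hidden, seed = seed + i)
    c(n[c("W1", "b1", "W2", "b2")],
      list(partition = 1L, arch = as.integer(hidden), seedIndex = i,
           stopPartition = 2L, bestEpoch = 0L, netSeed = seed + i))
  })
  mockEnsemble(nets, pseudo)
}

# small trained single-allele world: enough signal for sanity checks
tinyTrained <- function() {
  fixture("tinyTrained", function() {
    world <- makeWorld(2, 0.9, seed = 401)
    sim <- sampleDataset(world, 150, noiseSd = 0.05, seed = 402)
    cfg <- panConfig(hidden = 16, nSeeds = 1, maxEpochs = 40,
                     patience = 10, seed = 403)
    ens <- trainEnsemble(sim$dataset, world@pseudo, cfg)
    list(world = world, sim = sim, ens = ens)
  })
}

# random peptide strings (not proteome windows)
randomPeptideSet <- function(n, lengths = 9, seed = 1) {
  set.seed(seed)
  if (length(lengths) == 1) lengths <- rep(lengths, 2)
  vapply(sample(lengths, n, replace = TRUE), function(L)
    paste(sample(panMHC:::AA_ALPHABET, L, replace = TRUE), collapse = ""),
    character(1))
}
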