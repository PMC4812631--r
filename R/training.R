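# Training orchestration: partitioning, artificial negatives, NNAlign
# iterative core selection, cross-validated ensemble construction.

#' Default training configuration
#'
#' @param hidden hidden-layer sizes of the member architectures.
#' @param nSeeds networks per partition/architecture, each from a distinct
#'   random initialisation.
#' @param nPartitions cross-validation partitions.
#' @param learnRate online back-propagation learning rate.
#' @param maxEpochs epoch budget per network.
#' @param patience epochs without stop-set improvement before a network
#'   stops training (best-epoch weights are kept regardless).
#' @param seed master seed; every derived random stream flows from it.
#' @return named list of configuration values.
#' @export
panConfig <- function(hidden = c(56, 66), nSeeds = 5, nPartitions = 5,
                      learnRate = 0.05, maxEpochs = 300, patience = 25,
                      seed = 1) {
  list(hidden = as.integer(hidden), nSeeds = as.integer(nSeeds),
       nPartitions = as.integer(nPartitions), learnRate = learnRate,
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       seed = as.integer(seed))
}

# all 8mer substrings of a peptide
.eightMers <- function(p) {
  L <- nchar(p)
  unique(substring(p, 1:(L - 7), 8:L))
}

#' Partition a dataset for cross-validation without shared 8mers
#'
#' Peptides sharing any identical 8mer segment are clustered by single
#' linkage and whole clusters are assigned to partitions, so no 8mer
#' segment occurs in two partitions. Clusters are placed greedily,
#' largest first (record-weighted), onto the currently smallest
#' partition; ties in cluster size are broken by a seeded random order.
#'
#' @param dataset an \linkS4class{AffinityDataset}.
#' @param nParts number of partitions.
#' @param seed seed for tie-breaking.
#' @return integer vector of partition indices (1..nParts), one per
#'   record. A warning is raised when one cluster exceeds 1/nParts of the
#'   records.
#' @export
partitionCommon8mer <- function(dataset, nParts = 5, seed = 1) {
  rec <- records(dataset)
  if (nrow(rec) == 0) stop("empty dataset", call. = FALSE)
  peps <- unique(rec$peptide)
  np <- length(peps)

  # union-find over peptides, linked through shared 8mers
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  mers <- lapply(peps, .eightMers)
  merId <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(np)) {
    for (m in mers[[i]]) {
      j <- merId[[m]]
      if (is.null(j)) merId[[m]] <- i
      else { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
    }
  }
  cluster <- vapply(seq_len(np), find, integer(1))
  cluster <- match(cluster, unique(cluster))

  recCluster <- cluster[match(rec$peptide, peps)]
  w <- tabulate(recCluster)                    # record-weighted sizes
  if (any(w > nrow(rec) / nParts))
    warning(sprintf("a common-8mer cluster holds %d of %d records (more than 1/%d); partitions will be unbalanced",
                    max(w), nrow(rec), nParts), call. = FALSE)
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(deriveSeed(seed, 811L))
  tie <- sample.int(length(w))
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)
  ord <- order(-w, tie)
  sizes <- numeric(nParts)
  assign <- integer(length(w))
  for (cl in ord) {
    p <- which.min(sizes)
    assign[cl] <- p
    sizes[p] <- sizes[p] + w[cl]
  }
  assign[recCluster]
}

#' Add artificial negatives to a dataset
#'
#' For each allele, \code{nPerLength} random natural peptides of each
#' length are sampled from the proteome and added as negatives with an
#' assigned IC50 of 50000 nM (target exactly 0), flagged
#' \code{is_artificial} so evaluations can exclude them. Sampling is
#' reproducible: each allele uses a seed derived from \code{seed} and its
#' position in the allele list.
#'
#' @param dataset an \linkS4class{AffinityDataset}.
#' @param proteome named character vector of protein sequences.
#' @param nPerLength negatives per length per allele.
#' @param lengths peptide lengths to sample.
#' @param seed master seed.
#' @return the augmented \linkS4class{AffinityDataset}.
#' @export
addArtificialNegatives <- function(dataset, proteome, nPerLength = 25,
                                   lengths = 8:11, seed = 1) {
  if (!length(proteome)) stop("empty proteome", call. = FALSE)
  if (nPerLength == 0) return(dataset)
  alleles <- alleleNames(dataset)
  extra <- lapply(seq_along(alleles), function(ai) {
    peps <- sampleRandomPeptides(proteome, nPerLength, lengths,
                                 seed = deriveSeed(seed, 97L, ai))
    data.frame(allele = alleles[ai], peptide = peps,
               ic50 = AFFINITY_CEILING_NM, stringsAsFactors = FALSE)
  })
  extra <- do.call(rbind, extra)
  rec <- records(dataset)
  AffinityDataset(c(rec$allele, extra$allele),
                  c(rec$peptide, extra$peptide),
                  c(rec$ic50, extra$ic50),
                  is_artificial = c(rec$is_artificial,
                                    rep(TRUE, nrow(extra))),
                  rowErrors = dataset@rowErrors)
}

#' Train one network with iterative binding-core selection
#'
#' Each epoch, for every training peptide, all candidate 9mer-core
#' alignments are scored by the current network; the highest-scoring
#' candidate is taken as the current binding core and back-propagation
#' runs on its encoding (ties go to the lowest candidate offset). Early
#' stopping monitors the stop records scored the same way. For all-9mer
#' data this reduces exactly to plain online back-propagation.
#'
#' @param trainRecords,stopRecords data.frames with columns allele,
#'   peptide, target (e.g. subsets of \code{records(dataset)}).
#' @param pseudo a \linkS4class{PseudoSeqMap} covering all alleles present.
#' @param hidden hidden-layer size.
#' @param seed initialisation/shuffling seed.
#' @param learnRate,maxEpochs,patience see [panConfig()].
#' @return a member network: weights plus \code{bestEpoch} and error logs.
#' @export
trainNNAlign <- function(trainRecords, stopRecords, pseudo, hidden = 56,
                         seed = 1, learnRate = 0.05, maxEpochs = 300,
                         patience = 25) {
  stopifnot(nrow(trainRecords) > 0)
  if (nrow(stopRecords) == 0) stop("empty stop set", call. = FALSE)
  all <- rbind(trainRecords[, c("allele", "peptide", "target")],
               stopRecords[, c("allele", "peptide", "target")])
  enc <- .encodeAll(all$peptide, all$allele, pseudo)
  n <- nrow(trainRecords)
  fit <- cppTrainNNAlign(enc$X, enc$candStart, enc$candCount,
                         target = all$target,
                         trainIdx = seq_len(n) - 1L,
                         stopIdx = n + seq_len(nrow(stopRecords)) - 1L,
                         H = as.integer(hidden), lr = learnRate,
                         maxEpochs = as.integer(maxEpochs),
                         patience = as.integer(patience),
                         seed = as.integer(seed))
  list(W1 = fit$W1, b1 = as.numeric(fit$b1), W2 = as.numeric(fit$W2),
       b2 = fit$b2, arch = as.integer(hidden), netSeed = as.integer(seed),
       bestEpoch = fit$bestEpoch, trainErr = as.numeric(fit$trainErr),
       stopErr = as.numeric(fit$stopErr))
}

#' Train a cross-validated ensemble
#'
#' For each held-out partition, each architecture and each of
#' \code{nSeeds} random initialisations, one network is trained on all
#' but two partitions, with one of the remaining partitions rotated out
#' for early stopping (rotation indexed by the seed number). The default
#' configuration — 5 partitions, hidden sizes \{56, 66\}, 5 seeds —
#' yields 10 networks per partition and 50 networks in total.
#'
#' @param dataset an \linkS4class{AffinityDataset}.
#' @param pseudo a \linkS4class{PseudoSeqMap} covering the dataset alleles.
#' @param config configuration from [panConfig()].
#' @param partition optional precomputed partition vector; by default
#'   [partitionCommon8mer()] is applied with a seed derived from the
#'   configuration seed.
#' @param verbose print per-network progress.
#' @return a \linkS4class{PanEnsemble}.
#' @export
trainEnsemble <- function(dataset, pseudo, config = panConfig(),
                          partition = NULL, verbose = FALSE) {
  P <- config$nPartitions
  if (P - 2L < 3L)
    stop("fewer than 3 training partitions: need at least 5 partitions",
         call. = FALSE)
  rec <- records(dataset)
  if (is.null(partition))
    partition <- partitionCommon8mer(dataset, P,
                                     seed = deriveSeed(config$seed, 1L))
  stopifnot(length(partition) == nrow(rec))
  enc <- .encodeAll(rec$peptide, rec$allele, pseudo)
  nets <- list()
  for (t in seq_len(P)) {
    rest <- setdiff(seq_len(P), t)
    for (hi in seq_along(config$hidden)) {
      for (s in seq_len(config$nSeeds)) {
        stopPart <- rest[(s - 1L) %% length(rest) + 1L]
        trainParts <- setdiff(rest, stopPart)
        trIdx <- which(partition %in% trainParts) - 1L
        stIdx <- which(partition == stopPart) - 1L
        if (!length(trIdx) || !length(stIdx))
          stop("empty training or stopping partition", call. = FALSE)
        netSeed <- deriveSeed(config$seed, 7L, t, hi, s)
        fit <- cppTrainNNAlign(enc$X, enc$candStart, enc$candCount,
                               target = rec$target,
                               trainIdx = trIdx, stopIdx = stIdx,
                               H = config$hidden[hi], lr = config$learnRate,
                               maxEpochs = config$maxEpochs,
                               patience = config$patience, seed = netSeed)
        nets[[length(nets) + 1L]] <- list(
          W1 = fit$W1, b1 = as.numeric(fit$b1), W2 = as.numeric(fit$W2),
          b2 = fit$b2, partition = t, arch = config$hidden[hi],
          seedIndex = s, stopPartition = stopPart,
          bestEpoch = fit$bestEpoch, netSeed = netSeed)
        if (verbose)
          message(sprintf("net %d: held-out %d arch %d seed %d (best epoch %d)",
                          length(nets), t, config$hidden[hi], s,
                          fit$bestEpoch))
      }
    }
  }
  new("PanEnsemble", networks = nets, pseudo = pseudo, config = config,
      partition = as.integer(partition), calibrations = list(),
      version = MODEL_FORMAT_VERSION)
}

#' Cross-validated predictions for the training records
#'
#' Each record is predicted only by the member networks whose held-out
#' partition is the record's own partition — networks that never saw the
#' record during training or stopping.
#'
#' @param ensemble a \linkS4class{PanEnsemble} from [trainEnsemble()].
#' @param dataset the dataset the ensemble was trained on (record order
#'   must match the stored partition vector).
#' @return data.frame of records with added columns \code{partition},
#'   \code{score} (cross-validated ensemble mean) and \code{core}.
#' @export
cvPredictions <- function(ensemble, dataset) {
  rec <- records(dataset)
  part <- ensemble@partition
  stopifnot(length(part) == nrow(rec))
  enc <- .encodeAll(rec$peptide, rec$allele, ensemble@pseudo)
  heldOut <- vapply(ensemble@networks, `[[`, numeric(1), "partition")
  score <- numeric(nrow(rec))
  core <- character(nrow(rec))
  for (p in sort(unique(part))) {
    nets <- ensemble@networks[heldOut == p]
    if (!length(nets))
      stop(sprintf("no networks held out partition %d", p), call. = FALSE)
    idx <- which(part == p)
    res <- .scoreEncoded(nets, enc, idx)
    score[idx] <- res$score
    core[idx] <- res$core
  }
  cbind(rec, partition = part, score = score, core = core,
        stringsAsFactors = FALSE)
}

# Score encoded records (subset idx) under a list of networks: per network
# max over candidates, averaged; reported core maximises the ensemble-mean
# per-candidate score.
.scoreEncoded <- function(nets, enc, idx = seq_along(enc$candCount)) {
  rows <- unlist(lapply(idx, function(i)
    enc$candStart[i] + seq_len(enc$candCount[i])), use.names = FALSE)
  X <- enc$X[rows, , drop = FALSE]
  candOf <- rep(seq_along(idx), enc$candCount[idx])
  perNetMax <- matrix(0, length(idx), length(nets))
  meanCand <- numeric(nrow(X))
  for (k in seq_along(nets)) {
    s <- as.numeric(cppForward(nets[[k]]$W1, nets[[k]]$b1, nets[[k]]$W2,
                               nets[[k]]$b2, X))
    perNetMax[, k] <- vapply(split(s, candOf), max, numeric(1))
    meanCand <- meanCand + s
  }
  meanCand <- meanCand / length(nets)
  bestCand <- vapply(split(seq_along(meanCand), candOf), function(j)
    j[which.max(meanCand[j])], integer(1))
  list(score = rowMeans(perNetMax), core = enc$core[rows[bestCand]],
       gapKind = enc$gapKind[rows[bestCand]], perNetMax = perNetMax)
}
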