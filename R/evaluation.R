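# Metrics and benchmarks: PCC, AUC, binomial sign test, ligand rank
# curves, rank-versus-affinity ROC, information divergence.

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 2, each with nonzero
#'   variance.
#' @return correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("pcc needs two equal-length vectors of length >= 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pcc undefined: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a random positive outscores a random
#' negative, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) class labels; both classes must occur.
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("AUC undefined: one class is absent", call. = FALSE)
  r <- rank(scores)                        # midranks handle ties as 0.5
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' One-sided binomial sign test
#'
#' Probability of observing \code{n1} or more wins for method 1 among
#' \code{n1 + n2} untied comparisons under the null that both methods win
#' each comparison with probability one half (ties are excluded before
#' counting).
#'
#' @param n1 wins of method 1.
#' @param n2 wins of method 2.
#' @return exact one-sided p-value.
#' @export
binomialSignTest <- function(n1, n2) {
  if (n1 < 0 || n2 < 0 || n1 + n2 < 1)
    stop("need non-negative win counts with n1 + n2 >= 1", call. = FALSE)
  stats::pbinom(n1 - 1, n1 + n2, 0.5, lower.tail = FALSE)
}

#' Cross-validation performance per allele and peptide length
#'
#' Computes PCC and AUC (binder threshold 500 nM) from cross-validated
#' predictions for every allele-length cell, excluding artificial
#' negatives. Cells are flagged as included when they hold at least
#' \code{minBinders} binders and \code{minN} data points.
#'
#' @param ensemble a \linkS4class{PanEnsemble} from [trainEnsemble()].
#' @param dataset the training dataset.
#' @param binderThreshold IC50 below which a peptide counts as a binder.
#' @param minBinders,minN inclusion thresholds.
#' @return data.frame with one row per allele-length cell: allele, length,
#'   n, nBinders, pcc, auc, included.
#' @export
evaluateCrossValidation <- function(ensemble, dataset,
                                    binderThreshold = 500,
                                    minBinders = 3, minN = 20) {
  cv <- cvPredictions(ensemble, dataset)
  cv <- cv[!cv$is_artificial, , drop = FALSE]
  cv$length <- nchar(cv$peptide)
  cells <- unique(cv[, c("allele", "length")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- cv[cv$allele == cells$allele[i] & cv$length == cells$length[i], ]
    lab <- sub$ic50 < binderThreshold
    nb <- sum(lab)
    ok <- nb >= minBinders && nrow(sub) >= minN
    p <- if (nrow(sub) >= 2 && stats::sd(sub$score) > 0 &&
             stats::sd(sub$target) > 0) pcc(sub$score, sub$target)
         else NA_real_
    a <- if (nb > 0 && nb < nrow(sub)) aucScore(sub$score, lab)
         else NA_real_
    data.frame(allele = cells$allele[i], length = cells$length[i],
               n = nrow(sub), nBinders = nb, pcc = p, auc = a,
               included = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# all unique windows of lengths 8-11 in a protein
.proteinWindows <- function(protein, lengths = 8:11) {
  L <- nchar(protein)
  unique(unlist(lapply(lengths, function(l) {
    if (L < l) return(character(0))
    substring(protein, 1:(L - l + 1), l:L)
  }), use.names = FALSE))
}

# scorer used by the benchmark machinery
.benchScores <- function(ensemble, allele, peptides,
                         method = c("direct", "lmer")) {
  method <- match.arg(method)
  switch(method,
         direct = predictBinding(ensemble, allele, peptides),
         lmer = lmerApproximate(ensemble, allele, peptides))
}

#' Ligand rank analysis on a source-protein benchmark
#'
#' Each validated ligand's source protein is scanned with a sliding
#' window of 8-11 residues; all unique windows are scored for the
#' ligand's restricting allele and the ligand's relative rank is the
#' fraction of windows scoring at or above it (ties counted against the
#' ligand, so reported ranks are conservative). The curve reports, for
#' each percentage-selected threshold, the percentage of ligands whose
#' rank falls within it.
#'
#' @param ensemble a \linkS4class{PanEnsemble}.
#' @param benchmark data.frame with columns allele, ligand, protein.
#' @param proteins named character vector of source-protein sequences.
#' @param thresholds percentage-selected grid.
#' @param method window scoring route: the ensemble's own multi-length
#'   alignment (\code{"direct"}) or the 9mer-only L-mer approximation
#'   (\code{"lmer"}).
#' @return list with \code{curve} (data.frame threshold, identified),
#'   \code{ranks} (per-ligand rank percentages) and \code{skipped}
#'   (rows whose ligand was absent from its protein).
#' @export
ligandRankCurve <- function(ensemble, benchmark, proteins,
                            thresholds = c(0.025, 0.05, 0.1, 0.25, 0.5,
                                           1, 2, 5, 10, 20, 50, 100),
                            method = c("direct", "lmer")) {
  method <- match.arg(method)
  missing <- setdiff(benchmark$protein, names(proteins))
  if (length(missing))
    stop("benchmark proteins absent from FASTA: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  ranks <- rep(NA_real_, nrow(benchmark))
  skipped <- integer(0)
  # score per allele in one batch across all of that allele's proteins
  for (al in unique(benchmark$allele)) {
    prots <- unique(benchmark$protein[benchmark$allele == al])
    wins <- lapply(prots, function(p) .proteinWindows(proteins[[p]]))
    sc <- .benchScores(ensemble, al,
                       unlist(wins, use.names = FALSE), method)$score
    scSplit <- split(sc, rep(seq_along(prots), lengths(wins)))
    for (i in which(benchmark$allele == al)) {
      pi <- match(benchmark$protein[i], prots)
      j <- match(benchmark$ligand[i], wins[[pi]])
      if (is.na(j)) { skipped <- c(skipped, i); next }
      s <- scSplit[[pi]]
      ranks[i] <- 100 * (sum(s >= s[j]) - 1) / length(s)
    }
  }
  if (length(skipped))
    warning(sprintf("%d benchmark row(s) skipped: ligand not found in its source protein",
                    length(skipped)), call. = FALSE)
  found <- ranks[!is.na(ranks)]
  curve <- data.frame(threshold = thresholds,
                      identified = vapply(thresholds, function(th)
                        100 * mean(found <= th), numeric(1)))
  list(curve = curve, ranks = ranks, skipped = skipped)
}

#' Filter a ligand benchmark by predicted percentile rank
#'
#' Removes peptide-MHC pairs that none of the supplied models consider
#' plausible binders: a row is kept only when its predicted percentile
#' rank is at or below \code{rankThreshold} under every model. All
#' models must carry rank calibrations for the alleles present.
#'
#' @param benchmark data.frame with columns allele, ligand, protein.
#' @param models list of calibrated \linkS4class{PanEnsemble} objects.
#' @param rankThreshold maximum allowed percentile rank.
#' @return the filtered benchmark, with attribute \code{removed} giving
#'   the number of rows dropped.
#' @export
benchmarkFilter <- function(benchmark, models, rankThreshold = 10) {
  if (!is.list(models) || !length(models)) stop("no models supplied")
  keep <- rep(TRUE, nrow(benchmark))
  for (m in models) {
    stopifnot(is(m, "PanEnsemble"))
    for (al in unique(benchmark$allele)) {
      if (is.null(m@calibrations[[al]]))
        stop("missing rank calibration for allele ", al, call. = FALSE)
      rows <- which(benchmark$allele == al)
      pr <- predictBinding(m, al, benchmark$ligand[rows])
      keep[rows] <- keep[rows] & (pr$rank <= rankThreshold)
    }
  }
  out <- benchmark[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

# ROC by threshold sweep; x is the score (higher = more positive)
.rocCurve <- function(x, labels) {
  ord <- order(-x)
  labels <- as.logical(labels)[ord]
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("ROC undefined: one class is absent", call. = FALSE)
  tp <- cumsum(labels); fp <- cumsum(!labels)
  # collapse ties on the score value
  last <- !duplicated(x[ord], fromLast = TRUE)
  tpr <- c(0, tp[last] / npos); fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Rank-based versus affinity-based ligand identification ROC
#'
#' Pools all unique 8-11mer windows of every benchmark source protein
#' (positives: the validated ligands; negatives: all other windows) and
#' computes two ROC curves over the pooled set — one ordering peptides
#' by predicted affinity score, one by per-allele percentile rank. With
#' heterogeneous affinity scales across alleles the rank ordering is
#' expected to dominate.
#'
#' @param ensemble a calibrated \linkS4class{PanEnsemble}.
#' @param benchmark data.frame with columns allele, ligand, protein.
#' @param proteins named character vector of source proteins.
#' @param specificities grid at which sensitivities are reported.
#' @return list with components \code{affinity} and \code{rank} (each
#'   fpr/tpr/auc) and \code{sensitivity} (data.frame specificity,
#'   affinity, rank).
#' @export
rankVsAffinityRoc <- function(ensemble, benchmark, proteins,
                              specificities = c(0.90, 0.95, 0.98, 1.00)) {
  score <- rank <- numeric(0); label <- logical(0)
  for (key in unique(paste(benchmark$allele, benchmark$protein))) {
    rows <- which(paste(benchmark$allele, benchmark$protein) == key)
    al <- benchmark$allele[rows[1]]
    if (is.null(ensemble@calibrations[[al]]))
      stop("missing rank calibration for allele ", al, call. = FALSE)
    windows <- .proteinWindows(proteins[[benchmark$protein[rows[1]]]])
    pr <- predictBinding(ensemble, al, windows)
    score <- c(score, pr$score)
    rank <- c(rank, pr$rank)
    label <- c(label, windows %in% benchmark$ligand[rows])
  }
  if (!any(label)) stop("no positives in the pooled benchmark", call. = FALSE)
  rocAff <- .rocCurve(score, label)
  rocRank <- .rocCurve(-rank, label)
  sens <- function(roc, spec) max(c(0, roc$tpr[roc$fpr <= 1 - spec + 1e-12]))
  list(affinity = rocAff, rank = rocRank,
       sensitivity = data.frame(
         specificity = specificities,
         affinity = vapply(specificities, function(s) sens(rocAff, s),
                           numeric(1)),
         rank = vapply(specificities, function(s) sens(rocRank, s),
                       numeric(1))))
}

#' Information divergence between allele distributions
#'
#' \code{I = sum_a f_a log2(f_a / b_a)} in bits, where \code{f} is the
#' allele distribution of a selected peptide set and \code{b} the
#' background distribution. Terms with \code{f_a = 0} contribute 0; a
#' positive \code{f_a} with zero background is an error (infinite
#' divergence).
#'
#' @param f,b numeric vectors summing to 1 (aligned alleles; names are
#'   matched when both are named).
#' @return divergence in bits (non-negative for normalized inputs).
#' @export
informationDivergence <- function(f, b) {
  if (!is.null(names(f)) && !is.null(names(b))) {
    stopifnot(setequal(names(f), names(b)))
    b <- b[names(f)]
  }
  stopifnot(length(f) == length(b))
  if (abs(sum(f) - 1) > 1e-9 || abs(sum(b) - 1) > 1e-9)
    stop("distributions must sum to 1", call. = FALSE)
  if (any(f > 0 & b == 0))
    stop("infinite divergence: observed allele with zero background",
         call. = FALSE)
  pos <- f > 0
  sum(f[pos] * log2(f[pos] / b[pos]))
}

#' Allele sampling divergence of top-scoring selections
#'
#' Helper for the selection-bias analysis: given pooled per-peptide
#' alleles with affinity scores and percentile ranks, selects the top
#' \code{k} peptides by each criterion and returns the information
#' divergence of each selection's allele distribution from the
#' background.
#'
#' @param alleles allele of each pooled peptide.
#' @param scores predicted affinity scores (higher = stronger).
#' @param ranks percentile ranks (lower = stronger).
#' @param k selection size.
#' @return named numeric: divergence (bits) of the affinity-based and the
#'   rank-based selection.
#' @export
selectionDivergence <- function(alleles, scores, ranks, k) {
  stopifnot(k >= 1, k <= length(alleles))
  lev <- unique(alleles)
  bg <- as.numeric(table(factor(alleles, lev))) / length(alleles)
  names(bg) <- lev
  fOf <- function(sel) {
    f <- as.numeric(table(factor(alleles[sel], lev))) / length(sel)
    names(f) <- lev
    f
  }
  selAff <- order(-scores)[seq_len(k)]
  selRank <- order(ranks)[seq_len(k)]
  c(affinity = informationDivergence(fOf(selAff), bg),
    rank = informationDivergence(fOf(selRank), bg))
}
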