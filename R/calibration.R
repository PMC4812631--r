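# Percentile-rank calibration and predicted length profiles.

#' Sample random natural peptides from a proteome
#'
#' Draws peptides uniformly over all windows of each requested length
#' across all proteome sequences (without replacement when enough
#' distinct windows exist, with replacement otherwise). Reproducible by
#' seed.
#'
#' @param proteome named character vector of protein sequences.
#' @param nPerLength peptides to draw per length.
#' @param lengths peptide lengths (default 8-11).
#' @param seed sampling seed.
#' @return character vector of length \code{nPerLength * length(lengths)},
#'   grouped by length.
#' @export
sampleRandomPeptides <- function(proteome, nPerLength, lengths = 8:11,
                                 seed = 1) {
  if (!length(proteome)) stop("empty proteome", call. = FALSE)
  if (max(nchar(proteome)) < max(lengths))
    stop("all proteome sequences are shorter than the requested peptide length",
         call. = FALSE)
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(seed)
  unlist(lapply(lengths, function(L) {
    nw <- pmax(nchar(proteome) - L + 1L, 0L)
    total <- sum(nw)
    if (total == 0)
      stop(sprintf("no windows of length %d in the proteome", L),
           call. = FALSE)
    idx <- sample.int(total, nPerLength, replace = nPerLength > total)
    cum <- cumsum(nw)
    seqi <- findInterval(idx - 1L, cum) + 1L
    off <- idx - c(0L, cum)[seqi]
    substring(proteome[seqi], off, off + L - 1L)
  }), use.names = FALSE)
}

#' Calibrate percentile ranks for one allele
#'
#' Predicts the supplied random natural peptides with the ensemble and
#' stores the descending-sorted score sample; [scoreToRank()] turns any
#' later score into a percentile rank against it. The classic sample is
#' 400000 peptides, 100000 of each length 8-11.
#'
#' @param ensemble a \linkS4class{PanEnsemble}.
#' @param allele allele name.
#' @param peptides random natural peptides (e.g. from
#'   [sampleRandomPeptides()]).
#' @param seed seed recorded as the sample's provenance.
#' @param proteomeId identifier recorded as the sample's provenance.
#' @return a \linkS4class{RankCalibration}.
#' @export
calibrateRanks <- function(ensemble, allele, peptides, seed = NA_integer_,
                           proteomeId = "unspecified") {
  if (!length(peptides)) stop("no calibration peptides", call. = FALSE)
  pred <- predictBinding(ensemble, allele, peptides)
  new("RankCalibration", allele = allele,
      scores = sort(pred$score, decreasing = TRUE),
      seed = as.integer(seed), proteomeId = proteomeId)
}

#' Attach rank calibrations for several alleles to an ensemble
#'
#' @param ensemble a \linkS4class{PanEnsemble}.
#' @param proteome named character vector to sample peptides from.
#' @param alleles alleles to calibrate (default: all in the pseudo map).
#' @param nPerLength peptides per length per allele (the full-scale
#'   default is 100000; desk-scale runs use less).
#' @param lengths peptide lengths.
#' @param seed master seed; each allele derives its own sampling seed.
#' @param proteomeId provenance string stored in each calibration.
#' @return the ensemble with calibrations embedded.
#' @export
calibrateEnsemble <- function(ensemble, proteome,
                              alleles = alleleNames(ensemble),
                              nPerLength = 100000, lengths = 8:11,
                              seed = 1, proteomeId = "proteome") {
  for (ai in seq_along(alleles)) {
    s <- deriveSeed(seed, 31L, ai)
    peps <- sampleRandomPeptides(proteome, nPerLength, lengths, seed = s)
    ensemble@calibrations[[alleles[ai]]] <-
      calibrateRanks(ensemble, alleles[ai], peps, seed = s,
                     proteomeId = proteomeId)
  }
  ensemble
}

#' Convert scores to percentile ranks
#'
#' Mid-rank convention: \code{rank = 100 * (greater + 0.5) / n} where
#' \code{greater} counts calibration scores strictly above the query,
#' clamped to at most 100. Small ranks mean strong binders; the rank is
#' monotonically non-increasing in the score and never exactly 0.
#'
#' @param calibration a \linkS4class{RankCalibration}.
#' @param score numeric vector of prediction scores.
#' @return percentile ranks in (0, 100].
#' @export
scoreToRank <- function(calibration, score) {
  stopifnot(is(calibration, "RankCalibration"))
  asc <- rev(calibration@scores)
  n <- length(asc)
  greater <- n - findInterval(score, asc)   # strictly greater entries
  pmin(100 * (greater + 0.5) / n, 100)
}

#' Predicted length profile of an allele
#'
#' Scores random natural peptides of each length and reports the
#' fraction of each length among the top-scoring fraction — the model's
#' predicted length preference. The full-scale recipe scores 250000
#' peptides per length 8-11 and keeps the top 1 percent.
#'
#' @param ensemble a \linkS4class{PanEnsemble}.
#' @param allele allele name.
#' @param proteome named character vector to sample from.
#' @param nPerLength peptides per length.
#' @param topFraction fraction of top-scoring peptides kept (in (0, 1]).
#' @param lengths peptide lengths.
#' @param seed sampling seed.
#' @param method \code{"direct"} scores peptides with the ensemble's own
#'   multi-length alignment; \code{"lmer"} scores them through the
#'   9mer-only L-mer approximation ([lmerApproximate()]).
#' @return named numeric vector of per-length fractions (sums to 1).
#' @export
lengthProfile <- function(ensemble, allele, proteome, nPerLength = 250000,
                          topFraction = 0.01, lengths = 8:11, seed = 1,
                          method = c("direct", "lmer")) {
  method <- match.arg(method)
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must lie in (0, 1]", call. = FALSE)
  peps <- sampleRandomPeptides(proteome, nPerLength, lengths, seed = seed)
  pred <- switch(method,
                 direct = predictBinding(ensemble, allele, peps),
                 lmer = lmerApproximate(ensemble, allele, peps))
  k <- max(1L, ceiling(topFraction * nrow(pred)))
  # score ties are broken by a seeded permutation, not input order: the
  # sample is grouped by length, so a stable sort would skew the top set
  # toward the first length whenever scores tie (e.g. degenerate models)
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(deriveSeed(seed, 41L))
  tie <- sample.int(nrow(pred))
  top <- pred[order(-pred$score, tie)[seq_len(k)], ]
  frac <- vapply(lengths, function(L) mean(nchar(top$peptide) == L),
                 numeric(1))
  setNames(frac, as.character(lengths))
}
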