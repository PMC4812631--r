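# Applying ensembles to peptides; the 9mer-only L-mer approximation.

.checkAllele <- function(ensemble, allele) {
  known <- names(ensemble@pseudo@seqs)
  if (!allele %in% known) {
    d <- utils::adist(allele, known)
    near <- known[order(d)][seq_len(min(3, length(known)))]
    stop(sprintf("unknown allele '%s'; nearest known alleles: %s", allele,
                 paste(near, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict binding of peptides to an MHC allele
#'
#' The ensemble score of a peptide is the mean over member networks of
#' each network's maximum score across the peptide's candidate binding
#' cores. The reported core is the candidate maximising the
#' ensemble-mean per-candidate score. When a rank calibration for the
#' allele is embedded in the ensemble, percentile ranks are reported too.
#'
#' @param ensemble a \linkS4class{PanEnsemble}.
#' @param allele allele name (must be in the ensemble's pseudo map).
#' @param peptides character vector of peptides (length >= 8).
#' @return data.frame with columns allele, peptide, core, gapKind, score,
#'   ic50 (nM, inverse transform of the score) and rank (percentile; NA
#'   without a calibration), in input order.
#' @export
predictBinding <- function(ensemble, allele, peptides) {
  stopifnot(is(ensemble, "PanEnsemble"), length(allele) == 1)
  .checkAllele(ensemble, allele)
  # bound the encoded-matrix footprint for large batches
  if (length(peptides) > 5000) {
    chunks <- split(peptides, ceiling(seq_along(peptides) / 5000))
    out <- do.call(rbind, lapply(chunks, predictBinding,
                                 ensemble = ensemble, allele = allele))
    rownames(out) <- NULL
    return(out)
  }
  enc <- .encodeAll(peptides, rep(allele, length(peptides)),
                    ensemble@pseudo)
  res <- .scoreEncoded(ensemble@networks, enc)
  gap <- res$gapKind
  rank <- rep(NA_real_, length(peptides))
  cal <- ensemble@calibrations[[allele]]
  if (!is.null(cal)) rank <- scoreToRank(cal, res$score)
  data.frame(allele = allele, peptide = peptides, core = res$core,
             gapKind = gap, score = res$score,
             ic50 = inverseTransform(res$score), rank = rank,
             stringsAsFactors = FALSE)
}

#' Predict a batch of peptides, preserving order
#'
#' Elementwise identical to [predictBinding()]; kept as an explicit
#' entry point for pipelines that stream many peptides.
#'
#' @inheritParams predictBinding
#' @export
predictBatch <- function(ensemble, allele, peptides) {
  predictBinding(ensemble, allele, peptides)
}

#' L-mer approximation for a 9mer-only model
#'
#' Extrapolates predictions of a model trained only on 9mers to peptides
#' of length 8-11 by conforming each query to a series of 9mers —
#' inserting the wildcard X (8mers) or deleting a consecutive stretch
#' (10/11mers) at non-anchor positions only — and averaging the
#' predictions of the variants on the transformed score scale. Anchor
#' core positions (default 1, 2 and 9) are never insertion/deletion
#' sites.
#'
#' @param ensemble a \linkS4class{PanEnsemble} trained on 9mer data.
#' @param allele allele name.
#' @param peptides peptides of length 8-11.
#' @param anchors 1-based anchor core positions excluded as
#'   insertion/deletion sites.
#' @return data.frame as in [predictBinding()]; \code{core} is the
#'   best-scoring 9mer variant.
#' @export
lmerApproximate <- function(ensemble, allele, peptides, anchors = c(1, 2, 9)) {
  stopifnot(is(ensemble, "PanEnsemble"), length(allele) == 1)
  .checkAllele(ensemble, allele)
  Ls <- nchar(peptides)
  if (any(Ls < 8 | Ls > 11))
    stop("the L-mer approximation covers peptide lengths 8-11 only",
         call. = FALSE)
  variants <- lapply(peptides, .lmerVariants, anchors = anchors)
  nv <- vapply(variants, length, integer(1))
  flat <- unlist(variants, use.names = FALSE)
  pred <- predictBinding(ensemble, allele, flat)
  grp <- rep(seq_along(peptides), nv)
  score <- vapply(split(pred$score, grp), mean, numeric(1))
  core <- vapply(split(seq_len(nrow(pred)), grp), function(j)
    pred$peptide[j[which.max(pred$score[j])]], character(1))
  rank <- rep(NA_real_, length(peptides))
  cal <- ensemble@calibrations[[allele]]
  if (!is.null(cal)) rank <- scoreToRank(cal, score)
  data.frame(allele = allele, peptide = peptides, core = core,
             gapKind = ifelse(Ls == 9, "none",
                              ifelse(Ls == 8, "insertion", "deletion")),
             score = unname(score), ic50 = inverseTransform(unname(score)),
             rank = rank, stringsAsFactors = FALSE)
}

# the 9mer variants of one peptide under the L-mer approximation
.lmerVariants <- function(peptide, anchors = c(1, 2, 9)) {
  L <- nchar(peptide)
  if (L == 9) return(peptide)
  if (L == 8) {
    pos <- setdiff(1:9, anchors)            # core position taken by X
    return(vapply(pos, function(p)
      paste0(substr(peptide, 1, p - 1), "X", substr(peptide, p, 8)),
      character(1)))
  }
  d <- L - 9L
  # deletion window [s, s+d-1] (1-based) must avoid peptide positions
  # 1, 2 and L (the anchor-bearing termini)
  starts <- Filter(function(s)
    s >= max(anchors[anchors <= 2]) + 1 && (s + d - 1) <= L - 1,
    seq_len(L - d + 1))
  v <- vapply(starts, function(s)
    paste0(substr(peptide, 1, s - 1), substr(peptide, s + d, L)),
    character(1))
  if (!length(v)) stop("no admissible deletion windows", call. = FALSE)
  v
}
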