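# Central S4 containers.

#' PseudoSeqMap: allele name to MHC pseudo-sequence
#'
#' Maps allele names to fixed-length strings of the MHC residues in
#' contact with the peptide. All pseudo-sequences in one map share the
#' same width; the width is data, not a constant (34 in the classic
#' contact-position set, but any uniform width is accepted).
#'
#' @slot seqs named character vector, names are allele names.
#' @slot width common pseudo-sequence length.
#' @export
setClass("PseudoSeqMap",
         representation(seqs = "character", width = "integer"))

setValidity("PseudoSeqMap", function(object) {
  if (length(object@seqs) == 0) return("empty pseudo-sequence map")
  if (is.null(names(object@seqs)) || any(names(object@seqs) == ""))
    return("all pseudo-sequences must be named by allele")
  w <- nchar(object@seqs)
  if (length(unique(w)) != 1)
    return(sprintf("pseudo-sequences have unequal lengths: %s",
                   paste(unique(w), collapse = ", ")))
  if (w[1] != object@width) return("width slot disagrees with sequences")
  if (anyDuplicated(names(object@seqs))) return("duplicate allele names")
  TRUE
})

#' Construct a PseudoSeqMap
#'
#' @param seqs named character vector of pseudo-sequences.
#' @return a \linkS4class{PseudoSeqMap}.
#' @export
PseudoSeqMap <- function(seqs) {
  .checkAlphabet(seqs, allowX = TRUE, what = "pseudo-sequence")
  new("PseudoSeqMap", seqs = seqs, width = nchar(seqs[[1]]))
}

#' AffinityDataset: peptide-MHC binding measurements
#'
#' An ordered table of binding records. Each record holds an allele name,
#' a peptide (length >= 8, alphabet ACDEFGHIKLMNPQRSTVWY plus wildcard X),
#' the measured IC50 in nM, the transformed training target
#' 1 - log(IC50)/log(50000) clamped to \[0, 1\], and a flag marking
#' artificial negatives (random natural peptides used only in training).
#'
#' @slot records data.frame with columns allele, peptide, ic50, target,
#'   is_artificial.
#' @slot rowErrors data.frame describing input rows rejected at read time
#'   (columns line, message); empty for programmatically built datasets.
#' @export
setClass("AffinityDataset",
         representation(records = "data.frame", rowErrors = "data.frame"))

setValidity("AffinityDataset", function(object) {
  r <- object@records
  need <- c("allele", "peptide", "ic50", "target", "is_artificial")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r) == 0) return(TRUE)
  if (any(nchar(r$peptide) < 8)) return("peptides shorter than 8 residues")
  if (any(r$ic50 <= 0)) return("non-positive IC50")
  tgt <- .clamp01(1 - log(r$ic50) / log(AFFINITY_CEILING_NM))
  if (any(abs(tgt - r$target) > 1e-9))
    return("target column inconsistent with the affinity transform")
  TRUE
})

#' Construct an AffinityDataset
#'
#' Targets are computed from IC50 via [transformAffinity()].
#'
#' @param allele,peptide,ic50 parallel vectors of binding measurements.
#' @param is_artificial logical flag per record (default all FALSE).
#' @param rowErrors optional data.frame of rejected input rows.
#' @return an \linkS4class{AffinityDataset}.
#' @export
AffinityDataset <- function(allele, peptide, ic50,
                            is_artificial = rep(FALSE, length(allele)),
                            rowErrors = data.frame(line = integer(),
                                                   message = character())) {
  .checkAlphabet(peptide, allowX = TRUE)
  rec <- data.frame(allele = as.character(allele),
                    peptide = as.character(peptide),
                    ic50 = as.numeric(ic50),
                    target = transformAffinity(as.numeric(ic50)),
                    is_artificial = as.logical(is_artificial),
                    stringsAsFactors = FALSE)
  new("AffinityDataset", records = rec, rowErrors = rowErrors)
}

#' RankCalibration: per-allele score-to-percentile mapping
#'
#' Stores the descending-sorted prediction scores of a sample of random
#' natural peptides for one allele. A query score is converted to a
#' percentile rank by its position in this sample (mid-rank convention).
#'
#' @slot allele allele name.
#' @slot scores numeric vector sorted in decreasing order.
#' @slot seed seed used to draw the peptide sample.
#' @slot proteomeId identifier of the proteome sampled.
#' @export
setClass("RankCalibration",
         representation(allele = "character", scores = "numeric",
                        seed = "integer", proteomeId = "character"))

setValidity("RankCalibration", function(object) {
  if (length(object@scores) == 0) return("empty calibration sample")
  if (is.unsorted(rev(object@scores)))
    return("calibration scores must be sorted in decreasing order")
  TRUE
})

#' PanEnsemble: a cross-validated ensemble of binding-prediction networks
#'
#' Holds the trained member networks (with their held-out partition,
#' architecture and initialisation provenance), the pseudo-sequence map
#' the model was trained with, the training configuration snapshot, the
#' cross-validation partition of the training records, and any per-allele
#' rank calibrations.
#'
#' @slot networks list of member networks (weights plus provenance).
#' @slot pseudo the \linkS4class{PseudoSeqMap} used in training.
#' @slot config training configuration (see [panConfig()]).
#' @slot partition integer vector: cross-validation partition index of
#'   each training record (parallel to the training dataset).
#' @slot calibrations named list of \linkS4class{RankCalibration}.
#' @slot version model format version tag.
#' @export
setClass("PanEnsemble",
         representation(networks = "list", pseudo = "PseudoSeqMap",
                        config = "list", partition = "integer",
                        calibrations = "list", version = "character"))

setValidity("PanEnsemble", function(object) {
  if (length(object@networks) == 0) return("ensemble has no networks")
  need <- c("W1", "b1", "W2", "b2", "partition", "arch")
  for (n in object@networks)
    if (!all(need %in% names(n))) return("malformed member network")
  TRUE
})

#' SyntheticWorld: a simulated universe of MHC alleles with known truth
#'
#' Alleles carry planted 9-position scoring matrices (motifs) and
#' pseudo-sequences constructed so that pseudo-sequence similarity tracks
#' motif similarity — the structural assumption pan-specific prediction
#' exploits. Each allele also has a length-preference distribution over
#' peptide lengths 8-11 and a logistic mapping from motif score to
#' binding target (per-allele midpoints allow worlds where alleles bind
#' at very different affinity scales).
#'
#' @slot alleles allele names.
#' @slot pseudo pseudo-sequence map.
#' @slot motifs list of 9 x 20 score matrices, one per allele.
#' @slot lengthPrefs alleles x 4 matrix of length preferences (8..11).
#' @slot lengthBonus alleles x 4 matrix of additive log-odds bonuses that
#'   couple the length preference to binding strength (0 for the
#'   preferred length, negative for disfavoured lengths).
#' @slot midpoints,slope logistic mapping from motif score to target.
#' @slot beta sharpness of motif-biased residue sampling for planted cores.
#' @slot binderFraction fraction of sampled records that carry a planted core.
#' @slot seed master seed of the world.
#' @export
setClass("SyntheticWorld",
         representation(alleles = "character", pseudo = "PseudoSeqMap",
                        motifs = "list", lengthPrefs = "matrix",
                        lengthBonus = "matrix",
                        midpoints = "numeric", slope = "numeric",
                        beta = "numeric", binderFraction = "numeric",
                        seed = "integer"))

# ---- accessors ----

#' Extract the record table of a dataset
#' @param x an AffinityDataset.
#' @return data.frame of binding records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "AffinityDataset", function(x) x@records)

#' Distinct allele names present in an object
#' @param x an AffinityDataset, PseudoSeqMap or PanEnsemble.
#' @return character vector of allele names.
#' @export
setGeneric("alleleNames", function(x) standardGeneric("alleleNames"))

#' @rdname alleleNames
#' @export
setMethod("alleleNames", "AffinityDataset",
          function(x) unique(x@records$allele))

#' @rdname alleleNames
#' @export
setMethod("alleleNames", "PseudoSeqMap", function(x) names(x@seqs))

#' @rdname alleleNames
#' @export
setMethod("alleleNames", "PanEnsemble", function(x) names(x@pseudo@seqs))

#' Pseudo-sequences as a named character vector
#' @param x a PseudoSeqMap or PanEnsemble.
#' @return named character vector.
#' @export
setGeneric("pseudoSeqs", function(x) standardGeneric("pseudoSeqs"))

#' @rdname pseudoSeqs
#' @export
setMethod("pseudoSeqs", "PseudoSeqMap", function(x) x@seqs)

#' @rdname pseudoSeqs
#' @export
setMethod("pseudoSeqs", "PanEnsemble", function(x) x@pseudo@seqs)

#' @rdname pseudoSeqs
#' @export
setMethod("pseudoSeqs", "SyntheticWorld", function(x) x@pseudo@seqs)

#' Member networks of an ensemble
#' @param x a PanEnsemble.
#' @return list of member networks.
#' @export
setGeneric("networks", function(x) standardGeneric("networks"))

#' @rdname networks
#' @export
setMethod("networks", "PanEnsemble", function(x) x@networks)

#' Rank calibrations embedded in an ensemble
#' @param x a PanEnsemble.
#' @return named list of RankCalibration objects.
#' @export
setGeneric("calibrations", function(x) standardGeneric("calibrations"))

#' @rdname calibrations
#' @export
setMethod("calibrations", "PanEnsemble", function(x) x@calibrations)

# ---- show methods ----

setMethod("show", "PseudoSeqMap", function(object) {
  cat(sprintf("PseudoSeqMap: %d alleles, pseudo-sequence width %d\n",
              length(object@seqs), object@width))
  cat("  ", paste(utils::head(names(object@seqs), 6), collapse = " "),
      if (length(object@seqs) > 6) "..." else "", "\n")
})

setMethod("show", "AffinityDataset", function(object) {
  r <- object@records
  cat(sprintf("AffinityDataset: %d records, %d alleles, lengths %s\n",
              nrow(r), length(unique(r$allele)),
              if (nrow(r)) paste(range(nchar(r$peptide)), collapse = "-")
              else "-"))
  if (any(r$is_artificial))
    cat(sprintf("  %d artificial negatives\n", sum(r$is_artificial)))
  if (nrow(object@rowErrors))
    cat(sprintf("  %d input rows rejected at read time\n",
                nrow(object@rowErrors)))
})

setMethod("show", "PanEnsemble", function(object) {
  archs <- table(vapply(object@networks, `[[`, numeric(1), "arch"))
  cat(sprintf("PanEnsemble: %d networks (hidden sizes %s), %d alleles\n",
              length(object@networks),
              paste(sprintf("%sx%s", archs, names(archs)), collapse = ", "),
              length(object@pseudo@seqs)))
  cat(sprintf("  calibrated alleles: %d\n", length(object@calibrations)))
})

setMethod("show", "RankCalibration", function(object) {
  cat(sprintf("RankCalibration for %s: %d scores in [%.4f, %.4f]\n",
              object@allele, length(object@scores),
              min(object@scores), max(object@scores)))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld: %d alleles, pseudo width %d, seed %d\n",
    length(object@alleles), object@pseudo@width, object@seed))
})
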