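# Shared constants and small helpers.

# the 20 standard residues, fixed column order used throughout the encoding
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# IC50 (nM) assigned to artificial negatives; also the affinity at which
# the target transform reaches zero
AFFINITY_CEILING_NM <- 50000

MODEL_FORMAT_VERSION <- "panMHC-model-1"

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM50 encoding table
#'
#' Returns the 21 x 20 matrix used for residue encoding: one row per
#' standard residue plus a row for the wildcard \code{X}, columns in the
#' fixed order of \code{AA_ALPHABET}. Entries are BLOSUM50 substitution
#' scores divided by 5 so that inputs stay in a range comfortable for
#' sigmoid units; the \code{X} row is all zeros.
#'
#' @return numeric matrix with rownames \code{c(AA_ALPHABET, "X")}.
#' @export
blosumTable <- function() {
  if (is.null(.pkg_cache$blosum)) {
    env <- new.env()
    utils::data("BLOSUM50", package = "Biostrings", envir = env)
    b <- env$BLOSUM50[AA_ALPHABET, AA_ALPHABET] / 5
    b <- rbind(b, X = rep(0, length(AA_ALPHABET)))
    .pkg_cache$blosum <- b
  }
  .pkg_cache$blosum
}

# validate peptide strings; X allowed when allowX
.checkAlphabet <- function(x, allowX = TRUE, what = "peptide") {
  ok <- c(AA_ALPHABET, if (allowX) "X")
  bad <- vapply(strsplit(x, ""), function(ch) any(!ch %in% ok), logical(1))
  if (any(bad))
    stop(sprintf("%s contains characters outside the amino-acid alphabet: %s",
                 what, paste(utils::head(x[bad], 5), collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Derive a component seed from a master seed
#'
#' All randomness in the package flows from one master seed; components
#' (partitioning, weight initialisation, sampling) receive seeds derived
#' deterministically by mixing integer keys with a Lehmer-style step, kept
#' below 2^31.
#'
#' @param seed master seed (integer).
#' @param ... integer keys identifying the component.
#' @return a single integer seed.
#' @export
deriveSeed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) * 104729 + 12345) %% m
  }
  as.integer(s)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

# uniform random peptides (not proteome windows); used by the simulator
.randomResidues <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}
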