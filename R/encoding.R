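# Affinity transform, binding-core enumeration and input encoding.

#' Transform an IC50 affinity to the network target scale
#'
#' Affinities in nM are mapped to a 0-1 training target with
#' \code{1 - log(ic50)/log(50000)}, clamped to \[0, 1\]: 1 nM maps to 1,
#' 50000 nM (the value assigned to non-binders) maps to 0.
#'
#' @param ic50 numeric vector of affinities in nM, all positive.
#' @return numeric vector of targets in \[0, 1\].
#' @seealso [inverseTransform()]
#' @export
transformAffinity <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 values must be positive and finite", call. = FALSE)
  .clamp01(1 - log(ic50) / log(AFFINITY_CEILING_NM))
}

#' Invert the affinity transform
#'
#' @param target numeric vector in \[0, 1\].
#' @return IC50 in nM: \code{50000^(1 - target)}.
#' @export
inverseTransform <- function(target) {
  if (any(!is.finite(target)) || any(target < 0) || any(target > 1))
    stop("targets must lie in [0, 1]", call. = FALSE)
  AFFINITY_CEILING_NM^(1 - target)
}

#' Enumerate candidate binding-core alignments of a peptide
#'
#' Every peptide is reduced to a 9-residue binding core. A 9mer has the
#' single trivial alignment. An 8mer is extended by inserting the wildcard
#' residue X at each of the 9 core positions (9 candidates). A longer
#' peptide has one consecutive stretch of L-9 residues removed at each of
#' the 10 possible offsets: stretches flush with a terminus leave the
#' overhang outside the groove as a peptide flanking region (gap kind
#' \code{protrusion}), interior stretches bulge out of the groove (gap
#' kind \code{deletion}).
#'
#' @param peptide a single peptide string, length >= 8.
#' @return data.frame with one row per candidate and columns \code{core}
#'   (9 characters, may contain X), \code{gapKind} (none, insertion,
#'   deletion or protrusion), \code{indelPos} (0-based offset of the
#'   insertion/deletion in the peptide; NA when not applicable),
#'   \code{indelLen}, \code{pfrLeft}, \code{pfrRight} and \code{L}.
#' @export
enumerateCores <- function(peptide) {
  stopifnot(length(peptide) == 1)
  .checkAlphabet(peptide)
  L <- nchar(peptide)
  if (L < 8)
    stop(sprintf("peptide '%s' is shorter than 8 residues", peptide),
         call. = FALSE)
  if (L > 13)
    warning(sprintf("peptide of length %d: outside the 8-13 range typical of MHC-I training data", L),
            call. = FALSE)
  if (L == 9) {
    return(data.frame(core = peptide, gapKind = "none",
                      indelPos = NA_integer_, indelLen = 0L,
                      pfrLeft = 0L, pfrRight = 0L, L = L,
                      stringsAsFactors = FALSE))
  }
  if (L == 8) {
    ins <- vapply(0:8, function(i)
      paste0(substr(peptide, 1, i), "X", substr(peptide, i + 1, 8)),
      character(1))
    return(data.frame(core = ins, gapKind = "insertion",
                      indelPos = 0:8, indelLen = 1L,
                      pfrLeft = 0L, pfrRight = 0L, L = L,
                      stringsAsFactors = FALSE))
  }
  d <- L - 9L
  starts <- 0:9            # 0-based start of the removed window
  rows <- lapply(starts, function(s) {
    if (s == 0L) {
      data.frame(core = substr(peptide, d + 1, L), gapKind = "protrusion",
                 indelPos = NA_integer_, indelLen = 0L,
                 pfrLeft = d, pfrRight = 0L, L = L,
                 stringsAsFactors = FALSE)
    } else if (s == 9L) {
      data.frame(core = substr(peptide, 1, 9), gapKind = "protrusion",
                 indelPos = NA_integer_, indelLen = 0L,
                 pfrLeft = 0L, pfrRight = d, L = L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(core = paste0(substr(peptide, 1, s),
                               substr(peptide, s + d + 1, L)),
                 gapKind = "deletion", indelPos = s, indelLen = d,
                 pfrLeft = 0L, pfrRight = 0L, L = L,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' BLOSUM-encode a residue string
#'
#' Each residue contributes the 20 entries of its BLOSUM50 row divided by
#' 5; the wildcard X contributes 20 zeros.
#'
#' @param s a residue string (alphabet plus X).
#' @return numeric vector of length \code{20 * nchar(s)}.
#' @export
blosumEncode <- function(s) {
  stopifnot(length(s) == 1)
  .checkAlphabet(s, what = "residue string")
  b <- blosumTable()
  ch <- strsplit(s, "")[[1]]
  as.vector(t(b[match(ch, rownames(b)), , drop = FALSE]))
}

# one-hot length bins: L <= 8, L == 9, L == 10, L >= 11
.lengthBin <- function(L) {
  as.numeric(c(L <= 8, L == 9, L == 10, L >= 11))
}

# auxiliary-feature scaling, keeps counts in [0, 1)
.auxScale <- function(x) x / (x + 2)

#' Encoding dimension for a pseudo-sequence width
#'
#' @param P pseudo-sequence width.
#' @return \code{9*20 + P*20 + 4 + 4}: core block, pseudo-sequence block,
#'   one-hot length bins, scaled auxiliary features (insertion length,
#'   deletion length, left and right flanking-region lengths).
#' @export
encodingDim <- function(P) 180L + 20L * as.integer(P) + 8L

#' Build the network input vector for one core alignment
#'
#' @param alignment a single row of [enumerateCores()] output.
#' @param pseudoSeq the pseudo-sequence of the MHC molecule.
#' @return numeric vector of length \code{encodingDim(nchar(pseudoSeq))}.
#' @export
buildInput <- function(alignment, pseudoSeq) {
  stopifnot(is.data.frame(alignment), nrow(alignment) == 1)
  if (nchar(alignment$core) != 9) stop("core must be 9 residues")
  insLen <- if (alignment$gapKind == "insertion") alignment$indelLen else 0
  delLen <- if (alignment$gapKind == "deletion") alignment$indelLen else 0
  c(blosumEncode(alignment$core),
    blosumEncode(pseudoSeq),
    .lengthBin(alignment$L),
    .auxScale(c(insLen, delLen, alignment$pfrLeft, alignment$pfrRight)))
}

# Vectorized candidate enumeration for many peptides at once. Same
# alignment rules as enumerateCores() (which stays the single-peptide
# reference implementation; a property test asserts agreement). Returns
# one data.frame over all peptides, candidates grouped per peptide in
# offset order, with a pepIdx column.
.candidateTable <- function(peptides) {
  Ls <- nchar(peptides)
  if (any(Ls < 8))
    stop("peptides shorter than 8 residues", call. = FALSE)
  if (any(Ls > 13))
    warning(sprintf("%d peptide(s) longer than 13 residues", sum(Ls > 13)),
            call. = FALSE)
  parts <- list()
  for (L in sort(unique(Ls))) {
    idx <- which(Ls == L)
    pep <- peptides[idx]
    if (L == 9) {
      tab <- data.frame(pepIdx = idx, off = 0L, core = pep,
                        gapKind = "none", indelPos = NA_integer_,
                        indelLen = 0L, pfrLeft = 0L, pfrRight = 0L, L = L,
                        stringsAsFactors = FALSE)
    } else if (L == 8) {
      tab <- do.call(rbind, lapply(0:8, function(i)
        data.frame(pepIdx = idx, off = i,
                   core = paste0(substr(pep, 1, i), "X",
                                 substr(pep, i + 1, 8)),
                   gapKind = "insertion", indelPos = i, indelLen = 1L,
                   pfrLeft = 0L, pfrRight = 0L, L = L,
                   stringsAsFactors = FALSE)))
    } else {
      d <- L - 9L
      tab <- do.call(rbind, lapply(0:9, function(s) {
        if (s == 0L)
          data.frame(pepIdx = idx, off = s,
                     core = substr(pep, d + 1, L), gapKind = "protrusion",
                     indelPos = NA_integer_, indelLen = 0L,
                     pfrLeft = d, pfrRight = 0L, L = L,
                     stringsAsFactors = FALSE)
        else if (s == 9L)
          data.frame(pepIdx = idx, off = s,
                     core = substr(pep, 1, 9), gapKind = "protrusion",
                     indelPos = NA_integer_, indelLen = 0L,
                     pfrLeft = 0L, pfrRight = d, L = L,
                     stringsAsFactors = FALSE)
        else
          data.frame(pepIdx = idx, off = s,
                     core = paste0(substr(pep, 1, s),
                                   substr(pep, s + d + 1, L)),
                     gapKind = "deletion", indelPos = s, indelLen = d,
                     pfrLeft = 0L, pfrRight = 0L, L = L,
                     stringsAsFactors = FALSE)
      }))
    }
    parts[[length(parts) + 1L]] <- tab
  }
  tab <- do.call(rbind, parts)
  tab[order(tab$pepIdx, tab$off), , drop = FALSE]
}

# bulk BLOSUM encoding of equal-length residue strings -> n x (20*len)
.encodeStrings <- function(s) {
  b <- blosumTable()
  len <- nchar(s[1])
  ch <- matrix(unlist(strsplit(s, ""), use.names = FALSE), nrow = len)
  idx <- match(ch, rownames(b))
  if (anyNA(idx))
    stop("illegal residue character in sequence", call. = FALSE)
  M <- b[idx, , drop = FALSE]          # (len * n) rows, position-major
  matrix(as.vector(t(M)), ncol = 20L * len, byrow = TRUE)
}

# Encode a whole record table (peptide + allele vectors) against a
# pseudo map. Returns list(X, candStart (0-based), candCount, core,
# gapKind) with rows of X stacked in record order; core/gapKind are
# aligned with the rows of X.
.encodeAll <- function(peptides, alleles, pseudo) {
  stopifnot(is(pseudo, "PseudoSeqMap"))
  missing <- setdiff(unique(alleles), names(pseudo@seqs))
  if (length(missing))
    stop("alleles missing from the pseudo-sequence map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  .checkAlphabet(peptides)
  tab <- .candidateTable(peptides)
  n <- length(peptides)
  counts <- tabulate(tab$pepIdx, nbins = n)
  coreMat <- .encodeStrings(tab$core)
  pseudoMat <- .encodeStrings(pseudo@seqs)[match(alleles,
                                                 names(pseudo@seqs)),
                                           , drop = FALSE]
  lenBin <- cbind(tab$L <= 8, tab$L == 9, tab$L == 10, tab$L >= 11) * 1
  aux <- .auxScale(cbind(
    ifelse(tab$gapKind == "insertion", tab$indelLen, 0),
    ifelse(tab$gapKind == "deletion", tab$indelLen, 0),
    tab$pfrLeft, tab$pfrRight))
  X <- cbind(coreMat, pseudoMat[tab$pepIdx, , drop = FALSE], lenBin, aux)
  dimnames(X) <- NULL
  list(X = X,
       candStart = as.integer(cumsum(c(0L, counts[-n]))),
       candCount = counts,
       core = tab$core, gapKind = tab$gapKind)
}
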