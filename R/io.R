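# Readers and writers for external formats and serialized models.

#' Read a peptide-MHC binding affinity table
#'
#' Tab-separated columns allele, peptide, IC50 (nM). A header line is
#' auto-detected (non-numeric third field) unless \code{header} is given.
#' Malformed rows — fewer than three fields, non-positive or non-numeric
#' IC50, peptides shorter than 8 residues or with illegal characters —
#' are rejected individually and reported with their line numbers; well
#' formed rows are always retained, so rows in equal records out plus
#' errors reported.
#'
#' @param path file path.
#' @param header logical or NA (auto-detect).
#' @return an \linkS4class{AffinityDataset}; rejected rows are recorded in
#'   its \code{rowErrors} slot and summarised in a warning.
#' @export
readAffinityTsv <- function(path, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty affinity table: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields[[1]]) < 3)
    stop("affinity table needs columns allele, peptide, ic50", call. = FALSE)
  lineNo <- seq_along(lines)
  if (is.na(header))
    header <- suppressWarnings(is.na(as.numeric(fields[[1]][3])))
  if (isTRUE(header)) { fields <- fields[-1]; lineNo <- lineNo[-1] }

  ok <- logical(length(fields))
  msg <- character(length(fields))
  allele <- peptide <- character(length(fields))
  ic50 <- numeric(length(fields))
  legal <- c(AA_ALPHABET, "X")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) { msg[i] <- "fewer than 3 fields"; next }
    v <- suppressWarnings(as.numeric(f[3]))
    pep <- toupper(trimws(f[2]))
    if (is.na(v)) { msg[i] <- "non-numeric ic50"; next }
    if (v <= 0) { msg[i] <- "non-positive ic50"; next }
    if (nchar(pep) < 8) { msg[i] <- "peptide shorter than 8"; next }
    if (any(!strsplit(pep, "")[[1]] %in% legal)) {
      msg[i] <- "illegal residue character"; next
    }
    ok[i] <- TRUE
    allele[i] <- trimws(f[1]); peptide[i] <- pep; ic50[i] <- v
  }
  errs <- data.frame(line = lineNo[!ok], message = msg[!ok],
                     stringsAsFactors = FALSE)
  if (nrow(errs))
    warning(sprintf("%d malformed row(s) rejected (lines %s)", nrow(errs),
                    paste(utils::head(errs$line, 10), collapse = ", ")),
            call. = FALSE)
  if (!any(ok)) stop("no valid rows in ", path, call. = FALSE)
  AffinityDataset(allele[ok], peptide[ok], ic50[ok], rowErrors = errs)
}

#' Write an affinity table
#'
#' @param dataset an AffinityDataset.
#' @param path output path.
#' @param header write a header line (default TRUE).
#' @export
writeAffinityTsv <- function(dataset, path, header = TRUE) {
  r <- records(dataset)
  con <- file(path, "wb")  # binary mode: byte-stable line endings
  on.exit(close(con))
  if (header) writeLines("allele\tpeptide\tic50", con)
  writeLines(sprintf("%s\t%s\t%.6g", r$allele, r$peptide, r$ic50), con)
  invisible(path)
}

#' Read a pseudo-sequence map
#'
#' Whitespace-separated two-column file: allele name, pseudo-sequence.
#' All pseudo-sequences must share one length; duplicated identical
#' entries are collapsed, conflicting duplicates are an error.
#'
#' @param path file path.
#' @return a \linkS4class{PseudoSeqMap}.
#' @export
readPseudoSeq <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("allele", "pseudo"))
  tab <- unique(tab)
  if (anyDuplicated(tab$allele))
    stop("duplicate allele with conflicting pseudo-sequence: ",
         paste(tab$allele[duplicated(tab$allele)], collapse = ", "),
         call. = FALSE)
  if (length(unique(nchar(tab$pseudo))) != 1)
    stop("pseudo-sequences have unequal lengths", call. = FALSE)
  PseudoSeqMap(setNames(toupper(tab$pseudo), tab$allele))
}

#' Write a pseudo-sequence map
#' @param pseudo a PseudoSeqMap.
#' @param path output path.
#' @export
writePseudoSeq <- function(pseudo, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("%s %s", names(pseudo@seqs), pseudo@seqs), con)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' IDs are the first whitespace token of each header; sequences are
#' upper-cased and residues outside the 20-letter alphabet are mapped to
#' the wildcard X.
#'
#' @param path FASTA file path.
#' @return named character vector of protein sequences.
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("no sequences in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  s <- toupper(as.character(seqs))
  s <- vapply(s, function(x) {
    ch <- strsplit(x, "")[[1]]
    ch[!ch %in% AA_ALPHABET] <- "X"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  setNames(s, ids)
}

#' Write protein sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width (default 60).
#' @export
writeFasta <- function(seqs, path, width = 60) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a ligand benchmark table
#'
#' Tab-separated columns allele, ligand peptide, source-protein ID.
#'
#' @param path file path.
#' @param header logical or NA (auto-detect: first line whose second field
#'   is not a valid peptide is treated as a header).
#' @return data.frame with columns allele, ligand, protein.
#' @export
readBenchmarkTsv <- function(path, header = NA) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3)
    stop("benchmark table needs columns allele, ligand, protein",
         call. = FALSE)
  names(tab)[1:3] <- c("allele", "ligand", "protein")
  if (is.na(header)) {
    ch <- strsplit(toupper(tab$ligand[1]), "")[[1]]
    header <- any(!ch %in% c(AA_ALPHABET, "X")) || length(ch) < 8
  }
  if (isTRUE(header)) tab <- tab[-1, , drop = FALSE]
  tab$ligand <- toupper(tab$ligand)
  .checkAlphabet(tab$ligand, what = "ligand")
  tab[, c("allele", "ligand", "protein")]
}

# ---- model serialization ----

.netToList <- function(n) {
  list(W1 = as.vector(n$W1), dimW1 = dim(n$W1), b1 = as.vector(n$b1),
       W2 = as.vector(n$W2), b2 = n$b2,
       partition = n$partition, arch = n$arch, seedIndex = n$seedIndex,
       stopPartition = n$stopPartition, bestEpoch = n$bestEpoch,
       netSeed = n$netSeed)
}

.netFromList <- function(l) {
  list(W1 = matrix(unlist(l$W1), unlist(l$dimW1)[1], unlist(l$dimW1)[2]),
       b1 = as.numeric(unlist(l$b1)), W2 = as.numeric(unlist(l$W2)),
       b2 = as.numeric(l$b2),
       partition = as.integer(l$partition), arch = as.integer(l$arch),
       seedIndex = as.integer(l$seedIndex),
       stopPartition = as.integer(l$stopPartition),
       bestEpoch = as.integer(l$bestEpoch),
       netSeed = if (is.null(l$netSeed)) NA_integer_
                 else as.integer(l$netSeed))
}

#' Serialize a model bundle to a versioned JSON container
#'
#' The container is structured text (diff-able, language-agnostic);
#' numbers are written at full precision so that a load/save round trip
#' reproduces predictions bit-identically.
#'
#' @param ensemble a \linkS4class{PanEnsemble}.
#' @param path output path.
#' @export
saveModel <- function(ensemble, path) {
  stopifnot(is(ensemble, "PanEnsemble"))
  bundle <- list(
    format = MODEL_FORMAT_VERSION,
    config = ensemble@config,
    pseudo = list(alleles = names(ensemble@pseudo@seqs),
                  seqs = unname(ensemble@pseudo@seqs)),
    partition = ensemble@partition,
    networks = lapply(ensemble@networks, .netToList),
    calibrations = lapply(ensemble@calibrations, function(cl)
      list(allele = cl@allele, scores = cl@scores, seed = cl@seed,
           proteomeId = cl@proteomeId)))
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE, null = "null")
  invisible(path)
}

#' Load a model bundle
#'
#' @param path path written by [saveModel()].
#' @return a \linkS4class{PanEnsemble}.
#' @export
loadModel <- function(path) {
  bundle <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                     error = function(e)
                       stop("cannot parse model file: ", conditionMessage(e),
                            call. = FALSE))
  if (!identical(bundle$format, MODEL_FORMAT_VERSION))
    stop(sprintf("incompatible model format '%s' (expected '%s')",
                 as.character(bundle$format), MODEL_FORMAT_VERSION),
         call. = FALSE)
  pseudo <- PseudoSeqMap(setNames(unlist(bundle$pseudo$seqs),
                                  unlist(bundle$pseudo$alleles)))
  cals <- lapply(bundle$calibrations, function(cl)
    new("RankCalibration", allele = cl$allele,
        scores = as.numeric(unlist(cl$scores)),
        seed = as.integer(cl$seed), proteomeId = as.character(cl$proteomeId)))
  names(cals) <- vapply(cals, function(cl) cl@allele, character(1))
  cfg <- lapply(bundle$config, function(x) unlist(x, use.names = FALSE))
  new("PanEnsemble",
      networks = lapply(bundle$networks, .netFromList),
      pseudo = pseudo, config = cfg,
      partition = as.integer(unlist(bundle$partition)),
      calibrations = cals, version = MODEL_FORMAT_VERSION)
}
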