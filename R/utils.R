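# Internal helpers shared across modules.

# Round half away from zero (report convention for table-style percentages;
# base round() is banker's rounding).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Reverse complement of a plain character vector of DNA strings (IUPAC-aware).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between one string and a character vector of equal-length
# strings. Operates on raw bytes; inputs are upper-case ACGTN.
hamming <- function(x, ys) {
  xr <- charToRaw(x)
  vapply(ys, function(y) sum(charToRaw(y) != xr), integer(1), USE.NAMES = FALSE)
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Coerce a genome argument (FASTA path, DNAStringSet, or named character
# vector) to a named DNAStringSet. Gzipped FASTA is handled by Biostrings.
as_genome <- function(genome) {
  if (inherits(genome, "synth_genome")) genome <- genome$sequences
  if (inherits(genome, "DNAStringSet")) {
    seqs <- genome
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome)) {
    seqs <- Biostrings::DNAStringSet(toupper(genome))
  } else {
    abort("`genome` must be a FASTA path, a DNAStringSet, or a character vector.")
  }
  if (length(seqs) == 0) abort("Genome contains no sequences.")
  # FASTA headers may carry descriptions; keep the first token as the id.
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("contig", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", nm)
  seqs
}

#' Read a paired or single FASTQ file into a tibble
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] in FASTQ mode that
#' returns one row per record with the read id, sequence and quality string.
#'
#' @param path Path to a FASTQ file, optionally gzipped.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = names(seqs),
    seq = unname(as.character(seqs)),
    qual = unname(as.character(S4Vectors::mcols(seqs)$qualities))
  )
}

#' Write a read tibble to a (gzipped) FASTQ file
#'
#' @param reads A tibble with columns `id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix produces a gzipped file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path,
    format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Write sequences to a FASTA file
#'
#' @param x A named character vector, DNAStringSet, or [synth_genome()] result.
#' @param path Output path; `.gz` compresses.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- as_genome(x)
  Biostrings::writeXStringSet(seqs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}
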