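#' Demultiplex paired reads by variable-length inline barcode
#'
#' Read1 starts with the sample's inline barcode followed by the P1
#' enzyme's restriction remnant; with variable-length barcodes the remnant,
#' not a fixed position, delimits the barcode. Candidate barcodes are
#' compared over their own lengths at the read start, longer barcodes
#' first. An exact barcode hit with a remnant match at the following offset
#' wins immediately (prefix-free sets make exact matches unambiguous);
#' otherwise the unique candidate within `tol` mismatches whose downstream
#' remnant also matches within `tol` mismatches is taken. Ties (two
#' barcodes at the same best mismatch count) and no-candidate reads go to
#' the unassigned bucket. The barcode is trimmed from read1 on output.
#'
#' @param r1,r2 Read tibbles (`id`, `seq`, `qual`) from [read_fastq()] or a
#'   [simulate_library()] result, or FASTQ paths. `r2` may be NULL for
#'   single-end data.
#' @param sheet [build_sample_sheet()] rows for this pool (barcode,
#'   pool_index pairs must be unique).
#' @param enzyme_a P1-side enzyme providing the remnant anchor.
#' @param tol Mismatch tolerance for barcode and remnant (default 1,
#'   consistent with distance-2 barcode sets).
#' @return A `demux_result`: list with `assignments` (per-read tibble:
#'   `id`, `sample_id` or NA, `barcode`, plus trimmed `seq`/`qual` columns
#'   `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`) and `stats` (per-sample
#'   assigned counts plus an `unassigned` row). Conservation holds:
#'   assigned + unassigned = input records.
#' @export
demultiplex <- function(r1, r2 = NULL, sheet, enzyme_a = "AvaII", tol = 1) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  enzyme_a <- get_enzyme(enzyme_a)
  if (anyDuplicated(sheet$barcode)) {
    abort("Sheet has duplicated barcodes within one pool; demultiplexing is ambiguous.")
  }
  remnant_set <- expand_iupac(p1_remnant(enzyme_a))
  rem_len <- nchar(remnant_set[1])

  barcodes <- sheet$barcode[order(-nchar(sheet$barcode), sheet$barcode)]
  sample_of <- setNames(sheet$sample_id, sheet$barcode)

  match_one <- function(seq) {
    best_bc <- NA_character_; best_mm <- Inf; tie <- FALSE
    for (bc in barcodes) {
      bl <- nchar(bc)
      if (nchar(seq) < bl + rem_len) next
      mm_bc <- sum(charToRaw(substr(seq, 1, bl)) != charToRaw(bc))
      if (mm_bc > tol) next
      rem <- substr(seq, bl + 1, bl + rem_len)
      mm_rem <- min(hamming(rem, remnant_set))
      if (mm_rem > tol) next
      if (mm_bc == 0 && mm_rem == 0) return(bc)  # exact anchor: unambiguous
      if (mm_bc < best_mm) {
        best_bc <- bc; best_mm <- mm_bc; tie <- FALSE
      } else if (mm_bc == best_mm) {
        tie <- TRUE
      }
    }
    if (is.infinite(best_mm) || tie) NA_character_ else best_bc
  }

  hit_bc <- vapply(r1$seq, match_one, character(1), USE.NAMES = FALSE)
  assigned <- !is.na(hit_bc)
  bl <- ifelse(assigned, nchar(hit_bc), 0L)

  assignments <- tibble(
    id = r1$id,
    barcode = hit_bc,
    sample_id = ifelse(assigned, unname(sample_of[hit_bc]), NA_character_),
    r1_seq = substr(r1$seq, bl + 1, nchar(r1$seq)),
    r1_qual = substr(r1$qual, bl + 1, nchar(r1$qual))
  )
  if (!is.null(r2)) {
    assignments$r2_seq <- r2$seq
    assignments$r2_qual <- r2$qual
  }

  stats <- dplyr::count(assignments,
                        sample_id = dplyr::coalesce(.data$sample_id, "unassigned"),
                        name = "n_reads")
  structure(
    list(assignments = assignments, stats = stats,
         n_input = nrow(r1), n_assigned = sum(assigned), tol = tol),
    class = "demux_result"
  )
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("<demux_result> %d/%d reads assigned (%.1f%%), tol %d\n",
              x$n_assigned, x$n_input, 100 * x$n_assigned / max(1, x$n_input), x$tol))
  invisible(x)
}

#' Write demultiplexed reads to per-sample FASTQ files
#'
#' @param demux A [demultiplex()] result.
#' @param dir Output directory; files are `<sample>_R1.fastq.gz` (and `_R2`
#'   when paired). Unassigned reads go to `unassigned_R1.fastq.gz`.
#' @return `dir`, invisibly.
#' @export
write_demultiplexed <- function(demux, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  a <- demux$assignments
  a$sample_id[is.na(a$sample_id)] <- "unassigned"
  for (s in unique(a$sample_id)) {
    rows <- a[a$sample_id == s, ]
    write_fastq(tibble(id = rows$id, seq = rows$r1_seq, qual = rows$r1_qual),
                file.path(dir, paste0(s, "_R1.fastq.gz")))
    if ("r2_seq" %in% names(rows)) {
      write_fastq(tibble(id = rows$id, seq = rows$r2_seq, qual = rows$r2_qual),
                  file.path(dir, paste0(s, "_R2.fastq.gz")))
    }
  }
  invisible(dir)
}

#' Fraction of reads carrying the correct restriction remnant
#'
#' @param reads Character vector of read sequences (or a tibble with `seq`).
#' @param enzyme The enzyme whose remnant is checked.
#' @param side `"R1"` checks the post-barcode read1 remnant at `offset`;
#'   `"R2"` checks the read-start remnant of the P2 side.
#' @param offset 0-based position where the remnant starts (0 for
#'   barcode-trimmed read1 and for read2).
#' @return Fraction in `[0, 1]` of reads whose remnant window matches any
#'   concrete expansion of the retained remnant exactly.
#' @export
remnant_check <- function(reads, enzyme, side = c("R1", "R2"), offset = 0) {
  side <- match.arg(side)
  if (is.data.frame(reads)) reads <- reads$seq
  if (length(reads) == 0) return(NA_real_)
  pat <- if (side == "R1") p1_remnant(enzyme) else p2_remnant(enzyme)
  expansions <- expand_iupac(pat)
  k <- nchar(pat)
  window <- substr(reads, offset + 1, offset + k)
  mean(window %in% expansions)
}

#' Fraction of reads with adapter read-through at the 3' end
#'
#' Flags a read when a prefix of the adapter occurs at the read's 3' end
#' with at least `min_overlap` overlapping bases and at most 10% mismatches
#' (an overlap-mode 3' adapter search).
#'
#' @param reads Character vector of read sequences (or tibble with `seq`).
#' @param adapter_sequence Adapter sequence expected at the 3' end (for
#'   read1 this is the reverse complement of the P2 adapter top strand).
#' @param min_overlap Minimum overlap length (>= 5).
#' @param max_mismatch_rate Mismatch rate allowed within the overlap.
#' @return Fraction of reads flagged.
#' @export
adapter_fraction <- function(reads, adapter_sequence, min_overlap = 10,
                             max_mismatch_rate = 0.1) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (min_overlap < 5) abort("min_overlap must be >= 5.")
  if (length(reads) == 0) return(NA_real_)
  ad_len <- nchar(adapter_sequence)

  has_adapter <- function(seq) {
    n <- nchar(seq)
    # adapter starting at read position p runs to the read end (overlap
    # n - p + 1) or covers the full adapter inside the read
    for (p in seq_len(max(1, n - min_overlap + 1))) {
      ov <- min(n - p + 1, ad_len)
      if (ov < min_overlap) break
      mm <- sum(charToRaw(substr(seq, p, p + ov - 1)) !=
                  charToRaw(substr(adapter_sequence, 1, ov)))
      if (mm <= floor(max_mismatch_rate * ov)) return(TRUE)
    }
    FALSE
  }
  mean(vapply(reads, has_adapter, logical(1), USE.NAMES = FALSE))
}

#' Quality-filter reads by sliding-window mean Phred score
#'
#' Discards a read when any window of `sliding_window` consecutive bases
#' has mean Phred quality below `phred_threshold`; survivors pass
#' unchanged. Reads shorter than the window are judged on their full
#' length.
#'
#' @param reads Tibble with `seq` and `qual` columns (Phred+33).
#' @param phred_threshold Minimum window mean quality (default 10).
#' @param sliding_window Window length in bases (default 15).
#' @return The kept rows of `reads`, with attribute `n_discarded`.
#' @export
quality_filter <- function(reads, phred_threshold = 10, sliding_window = 15) {
  if (sliding_window < 1) abort("sliding_window must be >= 1.")
  keep <- vapply(reads$qual, function(q) {
    ph <- as.integer(charToRaw(q)) - 33L
    n <- length(ph)
    w <- min(sliding_window, n)
    cs <- cumsum(c(0L, ph))
    means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
    all(means >= phred_threshold)
  }, logical(1), USE.NAMES = FALSE)
  out <- reads[keep, ]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Pool / barcode balance report
#'
#' The coefficient of variation (sample standard deviation over mean) of
#' per-barcode or per-pool read counts quantifies how evenly a multiplexed
#' lane distributes over samples.
#'
#' @param counts Numeric vector of read counts (>= 2 values), optionally
#'   named.
#' @return A `balance_report`: list with `counts`, `mean`, `sd`, `cv`
#'   (4-decimal report).
#' @export
pool_balance <- function(counts) {
  if (length(counts) < 2) abort("Need at least 2 counts for a CV.")
  m <- mean(counts)
  s <- sd(counts)
  structure(
    list(counts = counts, mean = m, sd = s,
         cv = round(if (m == 0) 0 else s / m, 4)),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> n = %d, mean = %.1f, CV = %.4f\n",
              length(x$counts), x$mean, x$cv))
  invisible(x)
}

#' GC fraction of a set of reads
#'
#' @param reads Character vector of sequences (or tibble with `seq`).
#' @return `(G + C) / (A + C + G + T)` over all bases; ambiguous bases are
#'   excluded from the denominator.
#' @export
gc_fraction <- function(reads) {
  if (is.data.frame(reads)) reads <- reads$seq
  counts <- colSums(Biostrings::alphabetFrequency(Biostrings::DNAStringSet(reads)))
  acgt <- counts[c("A", "C", "G", "T")]
  unname((acgt["G"] + acgt["C"]) / sum(acgt))
}

#' Per-sample QC report for a demultiplexed pool
#'
#' Combines assignment counts, remnant-valid fractions for both mates,
#' adapter-read fractions, GC content and quality-filter losses into one
#' table, the standard post-sequencing health check of a ddRAD pool.
#'
#' @param demux A [demultiplex()] result with paired reads.
#' @param enzyme_a,enzyme_b Digestion pair (remnant checks).
#' @param adapter_r1,adapter_r2 Adapter sequences searched at the 3' ends of
#'   read1 / read2 (e.g. rc(P2 top) and rc(P1 top)); NULL skips the search.
#' @param phred_threshold,sliding_window Quality-filter parameters.
#' @param min_overlap Adapter-search overlap.
#' @return A tibble, one row per sample: read counts, `remnant_r1`,
#'   `remnant_r2`, `adapter_r1`, `adapter_r2`, `gc`, `n_quality_discarded`.
#' @export
qc_report <- function(demux, enzyme_a = "AvaII", enzyme_b = "MspI",
                      adapter_r1 = NULL, adapter_r2 = NULL,
                      phred_threshold = 10, sliding_window = 15,
                      min_overlap = 10) {
  a <- demux$assignments[!is.na(demux$assignments$sample_id), ]
  paired <- "r2_seq" %in% names(a)
  per_sample <- function(rows) {
    qf <- quality_filter(tibble(seq = rows$r1_seq, qual = rows$r1_qual),
                         phred_threshold, sliding_window)
    tibble(
      n_reads = nrow(rows),
      remnant_r1 = remnant_check(rows$r1_seq, enzyme_a, "R1"),
      remnant_r2 = if (paired) remnant_check(rows$r2_seq, enzyme_b, "R2") else NA_real_,
      adapter_r1 = if (is.null(adapter_r1)) NA_real_ else
        adapter_fraction(rows$r1_seq, adapter_r1, min_overlap),
      adapter_r2 = if (!paired || is.null(adapter_r2)) NA_real_ else
        adapter_fraction(rows$r2_seq, adapter_r2, min_overlap),
      gc = gc_fraction(c(rows$r1_seq, if (paired) rows$r2_seq)),
      n_quality_discarded = attr(qf, "n_discarded")
    )
  }
  out <- dplyr::group_modify(dplyr::group_by(a, .data$sample_id),
                             function(rows, key) per_sample(rows))
  dplyr::ungroup(out)
}
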