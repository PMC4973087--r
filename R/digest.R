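#' Double-digest a genome into restriction fragments
#'
#' Pools the top-strand cut coordinates of two enzymes per contig,
#' deduplicates and sorts them, and reports the fragments delimited by
#' consecutive cuts (contig boundaries included). Each fragment end is
#' labelled with the enzyme that produced the adjacent cut, or `"TERMINAL"`
#' at a contig boundary. Fragments tile every contig exactly: they are
#' contiguous, start at 0 and end at the contig length. Coordinates are
#' 0-based, half-open; fragment boundaries are top-strand cut positions
#' (sticky-end overhangs are ignored for length).
#'
#' @param genome FASTA path (plain or gzipped), DNAStringSet, named
#'   character vector, or [synth_genome()] result.
#' @param enzyme_a,enzyme_b The two enzymes ([restriction_enzyme()] or name);
#'   must differ by name. `enzyme_a` is the P1-adapter (read1) side.
#' @return A tibble with columns `contig`, `start`, `end`, `left_enzyme`,
#'   `right_enzyme`, `length`, `end_class` (`"AB"`, `"AA"`, `"BB"` or
#'   `"TERMINAL"`). Attributes `enzyme_a`, `enzyme_b` and `contig_lengths`
#'   record the digestion context.
#' @examples
#' double_digest(c(chr1 = "TTTGGACCTTTTCCGGTTT"), "AvaII", "MspI")
#' @export
double_digest <- function(genome, enzyme_a, enzyme_b) {
  enzyme_a <- get_enzyme(enzyme_a)
  enzyme_b <- get_enzyme(enzyme_b)
  if (identical(enzyme_a$name, enzyme_b$name)) {
    abort("The two enzymes must differ (got the same name twice).")
  }
  seqs <- as_genome(genome)
  contig_lengths <- setNames(Biostrings::width(seqs), names(seqs))

  sites <- dplyr::bind_rows(
    find_sites(seqs, enzyme_a),
    find_sites(seqs, enzyme_b)
  )

  frag_one <- function(contig) {
    clen <- contig_lengths[[contig]]
    s <- sites[sites$contig == contig, ]
    # coincident cut coordinates from the two enzymes collapse to one cut;
    # keep one label deterministically (alphabetical) so tiling holds and
    # double_digest(g, A, B) == double_digest(g, B, A)
    s <- s[s$cut_pos > 0 & s$cut_pos < clen, ]
    s <- s[order(s$cut_pos, s$enzyme), ]
    s <- s[!duplicated(s$cut_pos), ]
    bounds <- c(0L, s$cut_pos, clen)
    labels <- c("TERMINAL", s$enzyme, "TERMINAL")
    n <- length(bounds) - 1L
    tibble(
      contig = contig,
      start = bounds[seq_len(n)],
      end = bounds[seq_len(n) + 1L],
      left_enzyme = labels[seq_len(n)],
      right_enzyme = labels[seq_len(n) + 1L]
    )
  }

  frags <- dplyr::bind_rows(lapply(names(seqs), frag_one))
  frags <- dplyr::mutate(
    frags,
    length = .data$end - .data$start,
    end_class = classify_ends(.data$left_enzyme, .data$right_enzyme,
                              enzyme_a$name, enzyme_b$name)
  )
  attr(frags, "enzyme_a") <- enzyme_a$name
  attr(frags, "enzyme_b") <- enzyme_b$name
  attr(frags, "contig_lengths") <- contig_lengths
  frags
}

classify_ends <- function(left, right, a, b) {
  dplyr::case_when(
    left == "TERMINAL" | right == "TERMINAL" ~ "TERMINAL",
    left == a & right == b ~ "AB",
    left == b & right == a ~ "AB",
    left == a & right == a ~ "AA",
    left == b & right == b ~ "BB"
  )
}

#' Define a fragment size-selection window
#'
#' @param min_len,max_len Inclusive bounds in bp; the 400–700 bp window is
#'   the usual recommendation for ddRAD size selection on Illumina.
#' @return A `size_window` object.
#' @export
size_window <- function(min_len = 400, max_len = 700) {
  if (min_len <= 0 || min_len > max_len) abort("Need 0 < min_len <= max_len.")
  structure(list(min_len = min_len, max_len = max_len), class = "size_window")
}

#' @export
print.size_window <- function(x, ...) {
  cat(sprintf("<size_window> %d-%d bp (inclusive)\n", x$min_len, x$max_len))
  invisible(x)
}

#' Count fragments in a size window
#'
#' @param fragments Fragment tibble from [double_digest()].
#' @param window A [size_window()] (bounds inclusive), or NULL for no size
#'   filter.
#' @param classes End classes to count; the default `"AB"` counts only
#'   fragments with one end from each enzyme — the only class that receives
#'   both adapters and amplifies in a ddRAD library.
#' @return Integer count.
#' @export
count_fragments <- function(fragments, window = NULL, classes = "AB") {
  keep <- fragments$end_class %in% classes
  if (!is.null(window)) {
    keep <- keep & fragments$length >= window$min_len & fragments$length <= window$max_len
  }
  sum(keep)
}

#' Fragment-length histogram in fixed-width bins
#'
#' @param fragments Fragment tibble (pre-filter by class upstream if needed).
#' @param bin_width Bin width in bp.
#' @param max_bp Upper bound of the binned range; lengths `>= max_bp` land in
#'   a single overflow bin.
#' @return A tibble with `bin_start`, `bin_end` (half-open; the overflow row
#'   has `bin_end = Inf`) and `count`. Counts sum to `nrow(fragments)`.
#' @export
size_histogram <- function(fragments, bin_width = 100, max_bp = 1500) {
  if (bin_width <= 0) abort("bin_width must be positive.")
  n_bins <- ceiling(max_bp / bin_width)
  starts <- (seq_len(n_bins) - 1L) * bin_width
  idx <- pmin(fragments$length %/% bin_width, n_bins)  # n_bins -> overflow
  counts <- tabulate(idx + 1L, nbins = n_bins + 1L)
  tibble(
    bin_start = c(starts, max_bp),
    bin_end = c(starts + bin_width, Inf),
    count = counts
  )
}

#' Per-contig fragment counts
#'
#' @inheritParams count_fragments
#' @return A tibble with `contig` and `count`; counts partition the
#'   genome-wide [count_fragments()] value. Contigs with no qualifying
#'   fragment get a zero row when the fragment tibble carries its
#'   `contig_lengths` attribute.
#' @export
per_chromosome_counts <- function(fragments, window = NULL, classes = "AB") {
  keep <- fragments$end_class %in% classes
  if (!is.null(window)) {
    keep <- keep & fragments$length >= window$min_len & fragments$length <= window$max_len
  }
  counted <- dplyr::count(fragments[keep, ], .data$contig, name = "count")
  clens <- attr(fragments, "contig_lengths")
  if (!is.null(clens)) {
    all_contigs <- tibble(contig = names(clens))
    counted <- dplyr::left_join(all_contigs, counted, by = "contig")
    counted$count[is.na(counted$count)] <- 0L
  }
  counted
}

#' Summarise a double digestion into a profile
#'
#' Bundles per-enzyme site counts, fragment counts by end class, the
#' size-window count and the 100-bp length histogram for one genome and
#' enzyme pair.
#'
#' @inheritParams double_digest
#' @param window A [size_window()]; default 400–700 bp.
#' @param genome_size_bp Optional genome size override in bp for density
#'   metrics (defaults to total assembly length including Ns; cited
#'   C-value-based sizes can be supplied instead).
#' @param classes End classes counted in the windowed count (default AB).
#' @return A `digest_profile` object: a list with `genome_id`,
#'   `genome_length`, `site_counts`, `class_counts`, `window`,
#'   `window_count`, `histogram` (AB fragments) and `fragments`.
#' @export
digest_profile <- function(genome, enzyme_a, enzyme_b, window = size_window(),
                           genome_size_bp = NULL, classes = "AB") {
  seqs <- as_genome(genome)
  frags <- double_digest(seqs, enzyme_a, enzyme_b)
  enzyme_a <- get_enzyme(enzyme_a)
  enzyme_b <- get_enzyme(enzyme_b)
  site_counts <- c(
    nrow(find_sites(seqs, enzyme_a)),
    nrow(find_sites(seqs, enzyme_b))
  )
  names(site_counts) <- c(enzyme_a$name, enzyme_b$name)
  total_len <- sum(Biostrings::width(seqs))
  structure(
    list(
      genome_id = attr(seqs, "genome_id") %||% "genome",
      genome_length = genome_size_bp %||% total_len,
      assembly_length = total_len,
      enzyme_a = enzyme_a$name,
      enzyme_b = enzyme_b$name,
      site_counts = site_counts,
      class_counts = table(factor(frags$end_class,
                                  levels = c("AB", "AA", "BB", "TERMINAL"))),
      window = window,
      window_count = count_fragments(frags, window, classes),
      histogram = size_histogram(frags[frags$end_class == "AB", ]),
      fragments = frags
    ),
    class = "digest_profile"
  )
}

#' @export
print.digest_profile <- function(x, ...) {
  cat(sprintf("<digest_profile> %s + %s on %s (%s bp)\n",
              x$enzyme_a, x$enzyme_b, x$genome_id,
              format(x$assembly_length, big.mark = ",")))
  cat(sprintf("  sites: %s\n",
              paste(names(x$site_counts), x$site_counts, sep = "=", collapse = ", ")))
  cat(sprintf("  fragments: %s\n",
              paste(names(x$class_counts), as.integer(x$class_counts),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  in %d-%d bp window (AB): %d\n",
              x$window$min_len, x$window$max_len, x$window_count))
  invisible(x)
}

#' @rdname digest_profile
#' @param x A `digest_profile`.
#' @param ... Unused.
#' @export
glance.digest_profile <- function(x, ...) {
  tibble(
    genome = x$genome_id,
    enzyme_a = x$enzyme_a,
    enzyme_b = x$enzyme_b,
    genome_length = x$genome_length,
    sites_a = unname(x$site_counts[1]),
    sites_b = unname(x$site_counts[2]),
    total_ab = as.integer(x$class_counts[["AB"]]),
    window_count = x$window_count
  )
}

#' Write fragments as BED6
#'
#' Chrom/start/end with `name = leftEnzyme_rightEnzyme`, `score = length`
#' and `strand = "+"` (fragments are strandless intervals).
#'
#' @param fragments Fragment tibble from [double_digest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- tibble(
    chrom = fragments$contig,
    start = fragments$start,
    end = fragments$end,
    name = paste(fragments$left_enzyme, fragments$right_enzyme, sep = "_"),
    score = fragments$length,
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
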