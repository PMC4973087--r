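#' Screen enzyme pairs across genomes
#'
#' Runs [double_digest()] for every genome × enzyme-pair combination and
#' tabulates the total and size-window AB fragment counts, the raw material
#' for choosing a universal pair. A genome that fails to read is recorded as
#' an error row and the screen continues.
#'
#' @param genomes A named list of genome inputs (FASTA paths, DNAStringSets,
#'   character vectors or [synth_genome()] results), or a manifest tibble
#'   with columns `genome_id`, `fasta_path` and optionally `genome_size_mb`.
#' @param pairs A list of 2-element character vectors of enzyme names, e.g.
#'   `list(c("AvaII", "MspI"), c("EcoRI", "MspI"))`.
#' @param window A [size_window()]; default 400–700 bp.
#' @param classes End classes for the windowed count (default `"AB"`).
#' @return A tibble with one row per (genome, pair): `genome`, `pair`,
#'   `enzyme_a`, `enzyme_b`, `genome_size_mb`, `total_ab`, `window_ab`,
#'   `total_all`, `error` (NA unless that genome failed).
#' @export
screen_pairs <- function(genomes, pairs, window = size_window(), classes = "AB") {
  if (is.data.frame(genomes)) {
    manifest <- genomes
    stopifnot(all(c("genome_id", "fasta_path") %in% names(manifest)))
    genome_list <- setNames(as.list(manifest$fasta_path), manifest$genome_id)
    sizes_mb <- if ("genome_size_mb" %in% names(manifest)) {
      setNames(manifest$genome_size_mb, manifest$genome_id)
    } else NULL
  } else {
    genome_list <- genomes
    if (is.null(names(genome_list)) || any(!nzchar(names(genome_list)))) {
      names(genome_list) <- paste0("genome", seq_along(genome_list))
    }
    sizes_mb <- NULL
  }
  if (length(genome_list) == 0) abort("Need at least one genome.")
  if (length(pairs) == 0) abort("Need at least one enzyme pair.")

  rows <- purrr::map(names(genome_list), function(gid) {
    seqs <- tryCatch(as_genome(genome_list[[gid]]), error = function(e) e)
    size_mb <- if (!is.null(sizes_mb) && !is.na(sizes_mb[gid] %||% NA)) {
      unname(sizes_mb[gid])
    } else if (!inherits(seqs, "error")) {
      sum(Biostrings::width(seqs)) / 1e6
    } else NA_real_
    purrr::map(pairs, function(pr) {
      base <- tibble(
        genome = gid,
        pair = paste(pr[1], pr[2], sep = "+"),
        enzyme_a = pr[1], enzyme_b = pr[2],
        genome_size_mb = size_mb
      )
      if (inherits(seqs, "error")) {
        return(dplyr::mutate(base, total_ab = NA_integer_, window_ab = NA_integer_,
                             total_all = NA_integer_, error = conditionMessage(seqs)))
      }
      frags <- double_digest(seqs, pr[1], pr[2])
      dplyr::mutate(base,
        total_ab = count_fragments(frags, NULL, classes),
        window_ab = count_fragments(frags, window, classes),
        total_all = nrow(frags),
        error = NA_character_
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "window") <- window
  out
}

#' Model tag yield as a function of genome size
#'
#' Ordinary least-squares regression of fragment (tag) count on genome size
#' in Mb, across the genomes screened for one enzyme pair. Screens of real
#' plant genomes show tag counts rising close to linearly with genome size,
#' so a fitted line lets the expected tag number of an unscreened species be
#' read off its genome size.
#'
#' @param report Rows of a [screen_pairs()] tibble for a single pair, or any
#'   tibble with the size/count columns named below.
#' @param count Column with the response count (default `window_ab`).
#' @param size Column with genome size in Mb (default `genome_size_mb`).
#' @return A `tag_yield_fit` with `slope`, `intercept`, `r_squared` (reported
#'   to 4 decimals), the underlying `lm` fit and the training data.
#' @export
fit_genome_size_model <- function(report, count = "window_ab", size = "genome_size_mb") {
  dat <- tibble(size_mb = report[[size]], count = report[[count]])
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 3) abort("Need at least 3 genomes with counts to fit.")
  if (length(unique(dat$size_mb)) < 2) abort("Genome sizes have zero variance.")
  fit <- lm(count ~ size_mb, data = dat)
  # R^2 computed directly so a zero-variance response reports 0 rather than
  # the 0/0 noise summary.lm() can produce on perfectly flat data
  sst <- sum((dat$count - mean(dat$count))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(
      slope = unname(coef(fit)[["size_mb"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = round(r2, 4),
      fit = fit,
      data = dat
    ),
    class = "tag_yield_fit"
  )
}

#' @export
print.tag_yield_fit <- function(x, ...) {
  cat(sprintf("<tag_yield_fit> count = %.4g x size_Mb + %.4g  (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_genome_size_model
#' @param x A `tag_yield_fit`.
#' @param ... Unused.
#' @export
tidy.tag_yield_fit <- function(x, ...) {
  s <- stats::coef(summary(x$fit))
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_genome_size_model
#' @export
glance.tag_yield_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n = nrow(x$data))
}

#' Predict tag count for a genome size
#'
#' @param model A [fit_genome_size_model()] fit.
#' @param genome_size_mb Genome size(s) in Mb.
#' @return Predicted count(s), floored at 0 (a line extrapolated below zero
#'   has no physical meaning).
#' @export
predict_tag_count <- function(model, genome_size_mb) {
  pmax(0, model$slope * genome_size_mb + model$intercept)
}

#' Data-reduction summary metrics for a sequenced ddRAD library
#'
#' Computes the standard descriptive metrics of a reduced-representation
#' run: tag density per 100 kb, the simplification ratio (percentage of the
#' nuclear genome covered by tags), mean tag depth, and optionally the
#' expected/observed tag-count percentage from an in silico prediction.
#' Reported values are rounded half-away-from-zero to 2 decimals, the usual
#' table convention.
#'
#' @param tag_count Number of tags observed.
#' @param tag_length Tag length in bp (140 for PE150 truncated read1 tags;
#'   use 280 for a paired 2 x 140 bp convention).
#' @param genome_length Nuclear genome length in bp.
#' @param clean_read_count Clean reads supporting the tags (read1 count for
#'   paired data).
#' @param expected_tag_count Optional in silico expected tag count.
#' @return One-row tibble: `tag_count`, `tag_length`, `genome_length`,
#'   `clean_read_count`, `tags_per_100kb`, `simplification_ratio` (percent),
#'   `mean_tag_depth` (fold), and `expected_over_observed` (percent, NA when
#'   no expectation is supplied).
#' @examples
#' summary_metrics(66547, 140, 383e6, 14146516)
#' @export
summary_metrics <- function(tag_count, tag_length, genome_length,
                            clean_read_count, expected_tag_count = NULL) {
  vals <- c(tag_count, tag_length, genome_length, clean_read_count)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All counts and lengths must be positive.")
  }
  tibble(
    tag_count = tag_count,
    tag_length = tag_length,
    genome_length = genome_length,
    clean_read_count = clean_read_count,
    tags_per_100kb = round_half_up(tag_count / genome_length * 1e5),
    simplification_ratio = round_half_up(tag_count * tag_length / genome_length * 100),
    mean_tag_depth = round_half_up(clean_read_count / tag_count),
    expected_over_observed = if (is.null(expected_tag_count)) NA_real_ else {
      round_half_up(expected_tag_count / tag_count * 100)
    }
  )
}

#' Compare observed and expected per-chromosome tag counts
#'
#' Pairs in silico expected fragment counts with observed tag counts per
#' chromosome and reports their Pearson correlation, the consistency check
#' between prediction and sequencing.
#'
#' @param expected,observed Named numeric vectors (names = contigs) or
#'   tibbles with `contig`/`count` columns such as from
#'   [per_chromosome_counts()]. Keys must match; at least 3 contigs.
#' @return An `oe_comparison`: list with a `data` tibble (contig, expected,
#'   observed) and `pearson_r` (4 decimals).
#' @export
compare_observed_expected <- function(expected, observed) {
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(x$count, x$contig) else x
  }
  e <- as_named(expected)
  o <- as_named(observed)
  if (is.null(names(e)) || is.null(names(o))) abort("Counts must be named by contig.")
  if (!setequal(names(e), names(o))) {
    abort(sprintf(
      "Contig keys differ: only-in-expected {%s}; only-in-observed {%s}",
      paste(setdiff(names(e), names(o)), collapse = ", "),
      paste(setdiff(names(o), names(e)), collapse = ", ")
    ))
  }
  if (length(e) < 3) abort("Need at least 3 contigs to correlate.")
  o <- o[names(e)]
  structure(
    list(
      data = tibble(contig = names(e), expected = unname(e), observed = unname(o)),
      pearson_r = round(cor(e, o, method = "pearson"), 4)
    ),
    class = "oe_comparison"
  )
}

#' @export
print.oe_comparison <- function(x, ...) {
  cat(sprintf("<oe_comparison> %d contigs, Pearson r = %.4f\n",
              nrow(x$data), x$pearson_r))
  invisible(x)
}

#' @rdname compare_observed_expected
#' @param x An `oe_comparison`.
#' @param ... Unused.
#' @export
tidy.oe_comparison <- function(x, ...) x$data

#' @rdname compare_observed_expected
#' @export
glance.oe_comparison <- function(x, ...) {
  tibble(n_contigs = nrow(x$data), pearson_r = x$pearson_r)
}
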