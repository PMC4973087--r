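#' Plot a fragment-length histogram
#'
#' Bar chart of [size_histogram()] counts per 100-bp bin, with the
#' size-selection window shaded when given.
#'
#' @param histogram Tibble from [size_histogram()] (or a `digest_profile`,
#'   whose AB histogram is used).
#' @param window Optional [size_window()] to shade.
#' @return A ggplot object.
#' @export
plot_size_histogram <- function(histogram, window = NULL) {
  if (inherits(histogram, "digest_profile")) {
    window <- window %||% histogram$window
    histogram <- histogram$histogram
  }
  h <- histogram
  h$bin_label <- ifelse(is.finite(h$bin_end),
                        paste0(h$bin_start, "-", h$bin_end),
                        paste0(">=", h$bin_start))
  h$bin_mid <- ifelse(is.finite(h$bin_end),
                      (h$bin_start + h$bin_end) / 2,
                      h$bin_start + 50)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 90, fill = "grey35") +
    ggplot2::labs(x = "Fragment length (bp)", y = "Fragments",
                  title = "Double-digest fragment size distribution") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window$min_len, xmax = window$max_len,
                               ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' @rdname fit_genome_size_model
#' @param object A `tag_yield_fit`.
#' @export
autoplot.tag_yield_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$size_mb, y = .data$count)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Genome size (Mb)", y = "Fragment count",
      title = sprintf("Tag yield vs genome size (R² = %.4f)", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname compare_observed_expected
#' @param object An `oe_comparison`.
#' @export
autoplot.oe_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Expected fragments per chromosome",
      y = "Observed tags per chromosome",
      title = sprintf("Observed vs expected (Pearson r = %.4f)", object$pearson_r)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-barcode or per-pool read-count balance
#'
#' @param balance A [pool_balance()] report.
#' @return A ggplot bar chart annotated with the CV.
#' @export
plot_pool_balance <- function(balance) {
  counts <- balance$counts
  d <- tibble(
    unit = factor(names(counts) %||% as.character(seq_along(counts)),
                  levels = names(counts) %||% as.character(seq_along(counts))),
    reads = as.numeric(counts)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit, y = .data$reads)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = balance$mean, colour = "steelblue",
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Reads",
                  title = sprintf("Read-count balance (CV = %.4f)", balance$cv)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
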