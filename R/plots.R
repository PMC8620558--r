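#' Plot a rolling genome scan
#'
#' Line plot of the normalised rolling-mean mutation frequency and count
#' tracks across the circular genome, with the reference's feature
#' regions shaded underneath.
#'
#' @param object An `mt_genome_scan` from [genome_scan()].
#' @param ref Optional [mt_reference()] whose regions are shaded.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mt_genome_scan <- function(object, ref = NULL, ...) {
  long <- tidyr::pivot_longer(
    object[, c("pos", "norm_frequency", "norm_count")],
    cols = c("norm_frequency", "norm_count"),
    names_to = "track", values_to = "value"
  ) |>
    dplyr::mutate(track = ifelse(.data$track == "norm_frequency", "frequency", "count"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value, colour = .data$track))
  if (!is.null(ref)) {
    shade <- dplyr::filter(ref$features, .data$start <= .data$end)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, fill = .data$kind),
      ymin = -0.05, ymax = 0, alpha = 0.6, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "mtDNA position (bp)",
      y = sprintf("rolling mean (%d bp), normalised", attr(object, "window_bp") %||% 250L),
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mt_genome_scan
#' @param scan An `mt_genome_scan`.
#' @export
plot_genome_scan <- function(scan, ref = NULL) {
  autoplot(scan, ref = ref)
}

#' Plot a spectrum summary
#'
#' Bar chart of the count metric per grouping level (region, effect,
#' substitution class, codon position...), faceted by inheritance when
#' present and coloured by tissue when present.
#'
#' @param object An `mt_spectrum_summary`.
#' @param metric Which metric column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mt_spectrum_summary <- function(object, metric = "count_metric", ...) {
  grouping <- attr(object, "grouping") %||% setdiff(
    names(object),
    c(
      "animal_id", "tissue", "inheritance", "count_metric",
      "frequency_metric", "n_variants"
    )
  )[1]
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = factor(.data[[grouping]]), y = .data[[metric]])
  )
  if ("tissue" %in% names(object)) {
    p <- p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data$tissue), outlier.size = 0.5)
  } else {
    p <- p + ggplot2::geom_boxplot(outlier.size = 0.5)
  }
  if ("inheritance" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~inheritance)
  }
  p +
    ggplot2::labs(x = grouping, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.mt_spectrum_summary
#' @param spectrum An `mt_spectrum_summary`.
#' @export
plot_spectrum <- function(spectrum, metric = "count_metric") {
  autoplot(spectrum, metric = metric)
}
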