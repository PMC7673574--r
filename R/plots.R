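#' @include barcode_gap.R richness.R
NULL

#' Plot a minimum-interspecific-distance histogram
#'
#' Bar plot of per-taxon minimum interspecific distances; the zero-distance
#' category (barcode failures) is drawn in red, positive bins in grey, in the
#' style of published barcode-gap figures.
#'
#' @param object A `barcode_gap` object.
#' @param bin_width Histogram bin width (p-distance units).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barcode_gap <- function(object, bin_width = 0.005, ...) {
  h <- distance_histogram(object, bin_width = bin_width)
  h$mid <- (h$bin_low + h$bin_high) / 2
  h$mid[h$category == "zero"] <- -bin_width / 2
  ggplot2::ggplot(h, ggplot2::aes(
    x = .data$mid, y = .data$n, fill = .data$category
  )) +
    ggplot2::geom_col(width = bin_width * 0.95) +
    ggplot2::scale_fill_manual(
      values = c(zero = "#d7301f", positive = "grey40"), guide = "none"
    ) +
    ggplot2::labs(
      x = "Minimum interspecific distance (p-distance)",
      y = "Number of taxa"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-flora distance histograms side by side
#'
#' @param object A `flora_comparison` object.
#' @param bin_width Histogram bin width.
#' @param ... Unused.
#' @return A ggplot object faceted by flora.
#' @export
autoplot.flora_comparison <- function(object, bin_width = 0.005, ...) {
  h <- dplyr::bind_rows(lapply(names(object$reports), function(f) {
    dplyr::mutate(
      distance_histogram(object$reports[[f]], bin_width = bin_width),
      flora = f, .before = 1
    )
  }))
  h$mid <- (h$bin_low + h$bin_high) / 2
  h$mid[h$category == "zero"] <- -bin_width / 2
  ggplot2::ggplot(h, ggplot2::aes(
    x = .data$mid, y = .data$n, fill = .data$category
  )) +
    ggplot2::geom_col(width = bin_width * 0.95) +
    ggplot2::facet_wrap(~flora, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(zero = "#d7301f", positive = "grey40"), guide = "none"
    ) +
    ggplot2::labs(
      x = "Minimum interspecific distance (p-distance)",
      y = "Number of taxa"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a species accumulation curve
#'
#' Interpolated richness as a solid line, extrapolation dashed, the observed
#' endpoint as a point, and the bootstrap confidence band as grey shading.
#'
#' @param object An `incidence_accumulation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.incidence_accumulation <- function(object, ...) {
  cv <- object$curve
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$t, y = .data$estimate))
  if (!all(is.na(cv$ci_low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_line(
      data = cv[cv$t <= object$T, ], linetype = "solid"
    ) +
    ggplot2::geom_line(
      data = cv[cv$t >= object$T, ], linetype = "dashed"
    ) +
    ggplot2::geom_point(data = cv[cv$t == object$T, ], size = 2) +
    ggplot2::labs(
      x = "Sampling units (collection days)",
      y = "Species richness"
    ) +
    ggplot2::theme_minimal()
}
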