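# ggplot2 views of the main result types.

#' Plot a flatness profile
#'
#' Side-by-side mean boundary deviations per depth band; the flatter
#' (smaller-deviation) side is the flattened side of the cell.
#'
#' @param object A [flatness_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flatness_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(band = sprintf("%g-%g µm", .data$band_lo_um, .data$band_hi_um))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$band, y = .data$mean_dev_nm, fill = .data$side
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "depth band below neck", y = "mean deviation from tangent (nm)",
      fill = "side",
      subtitle = paste0("flattened side: ", attr(object, "flatter_side"))
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of sheet areas with class colours
#'
#' The log-area histogram that motivates the Type 1/2/3 split: a steeply
#' curved region of many small sheets, a flat region of intermediate
#' sheets, and a few very large sheets.
#'
#' @param object A [classify_sheets()] result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sheet_classification <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object$assignments, ggplot2::aes(
    x = .data$area_um2, fill = .data$class
  )) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(
      xintercept = c(object$t1_um2, object$t2_um2), linetype = 2
    ) +
    ggplot2::labs(
      x = expression(paste("sheet area (", mu, m^2, ", log scale)")),
      y = "sheets", fill = "type"
    ) +
    ggplot2::theme_minimal()
}

#' Volume fractions by hemisphere with binomial error bars
#'
#' @param fractions A [volume_fraction()] table with a grouping column.
#' @param group Name of the grouping column.
#' @return A ggplot.
#' @export
plot_volume_fractions <- function(fractions, group = "region") {
  ggplot2::ggplot(fractions, ggplot2::aes(
    x = .data[[group]], y = .data$fraction_frac
  )) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$fraction_frac - .data$se_frac,
        ymax = .data$fraction_frac + .data$se_frac
      ),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "membrane + mitochondria volume fraction") +
    ggplot2::theme_minimal()
}

#' Tether lengths by context
#'
#' @param object A [compare_contexts()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.link_context_report <- function(object, ...) {
  ggplot2::ggplot(object$by_context, ggplot2::aes(
    x = stats::reorder(.data$context, .data$mean_length_nm),
    y = .data$mean_length_nm
  )) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_length_nm - .data$se_length_nm,
        ymax = .data$mean_length_nm + .data$se_length_nm
      ),
      width = 0.2
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "tether length (nm, mean ± SE)") +
    ggplot2::theme_minimal()
}
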