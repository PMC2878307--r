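#' Plot an S/N periodicity spectrum
#'
#' Mean S/N against period (bp).  Restrict the period range with
#' `period_range` (default 2-250 bp, the range over which nucleosome-scale
#' periodicities live).
#'
#' @param object An `alu_spectrum`.
#' @param period_range Length-2 numeric period window (bp).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.alu_spectrum <- function(object, period_range = c(2, 250), ...) {
  df <- tidy(object)
  df <- df[df$period_bp >= period_range[1] & df$period_bp <= period_range[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period_bp, y = .data$mean_sn)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "period (bp)", y = "mean S/N",
      title = paste0(attr(object, "step"), " periodicity spectrum"),
      subtitle = paste0(attr(object, "n_fragments"), " fragments")
    ) +
    ggplot2::theme_minimal()
}

#' Plot an element-anchored nucleosome metaprofile
#'
#' @param object An `alu_metaprofile`.
#' @param ... Unused.
#' @return A ggplot; the background profile, when present, is drawn in
#'   blue.
#' @export
autoplot.alu_metaprofile <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_signal), colour = "firebrick")
  if ("mean_background" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$mean_background),
                                colour = "steelblue")
  }
  p +
    ggplot2::labs(
      x = paste0("offset from element ", attr(object, "anchor"), " (bp)"),
      y = "mean signal (p.p.b.)",
      subtitle = paste0(attr(object, "n_elements"), " elements")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tiling-array distance profile with its shuffled null band
#'
#' @param object An `alu_tiling_profile`.
#' @param ... Unused.
#' @return A ggplot faceted by element edge; the shaded band is the
#'   shuffled background mean +/- 2 SD.
#' @export
autoplot.alu_tiling_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$bg_mean - 2 * .data$bg_sd,
                                      ymax = .data$bg_mean + 2 * .data$bg_sd),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$bg_mean), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_value), colour = "firebrick",
                       na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$edge), nrow = 1) +
    ggplot2::labs(x = "distance from element edge (bp)",
                  y = "mean hybridisation value") +
    ggplot2::theme_minimal()
}

#' Plot expression rates per region category
#'
#' @param object An `alu_expression`.
#' @param log10 Log-scale the rate axis (default `TRUE`; the rates span
#'   orders of magnitude).
#' @param ... Unused.
#' @return A ggplot bar chart with error bars on the random category.
#' @export
autoplot.alu_expression <- function(object, log10 = TRUE, ...) {
  df <- tidy(object)
  df$category <- factor(df$category, levels = df$category)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$rate_ppm)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate_ppm - .data$rate_sd,
                   ymax = .data$rate_ppm + .data$rate_sd),
      width = 0.3, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "expression rate (p.p.m. per region)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}
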