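#' Forest plot of jurisdiction odds ratios with pooled estimates
#'
#' @param estimates Tibble with `jurisdiction`, `log_or`, `se`,
#'   `definition_type`.
#' @param meta Optional `meta_result` whose pooled per-definition ORs are
#'   drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates, meta = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("ggplot2 is required for plotting.")
  }
  z <- z_value(0.95)
  d <- as_tibble(estimates) %>%
    mutate(
      or = exp(.data$log_or),
      lo = exp(.data$log_or - z * .data$se),
      hi = exp(.data$log_or + z * .data$se)
    )
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$or, y = stats::reorder(.data$jurisdiction, .data$or),
    colour = .data$definition_type
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL,
                  colour = "Definition")
  if (!is.null(meta)) {
    p <- p + ggplot2::geom_vline(
      xintercept = meta$pooled$or, linetype = "dashed", alpha = 0.5
    )
  }
  p
}

#' Scatter of jurisdiction net survival against EP percentage with fit line
#'
#' @param points Tibble as in [fit_ecological()].
#' @param fit Optional `ecological_fit`; drawn at the narrow-definition
#'   level when a definition offset was estimated.
#' @return A ggplot object.
#' @export
plot_ecological <- function(points, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("ggplot2 is required for plotting.")
  }
  p <- ggplot2::ggplot(as_tibble(points), ggplot2::aes(
    x = .data$ep_pct, y = .data$net_survival_1yr,
    colour = .data$definition_type
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Emergency presentations (%)",
                  y = "1-year net survival (%)", colour = "Definition")
  if (!is.null(fit)) {
    cf <- coef(fit$fit)
    intercept <- cf["(Intercept)"] +
      if ("narrow" %in% names(cf)) cf["narrow"] else 0
    p <- p + ggplot2::geom_abline(
      intercept = intercept, slope = fit$beta_per_10pct / 10,
      linetype = "dashed"
    )
  }
  p
}
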