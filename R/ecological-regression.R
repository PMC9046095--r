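#' Jurisdiction-level ecological regression of net survival on EP percentage
#'
#' Ordinary least squares of 1-year net survival on the jurisdiction-level
#' EP percentage, adjusting for the operational definition type (a
#' narrow-definition indicator) when both types are present. The slope is
#' reported per 10 percentage-point increase in EP, the convention for
#' jurisdiction-level comparisons. The regression is unweighted and its
#' inference is from the t distribution.
#'
#' This is an ecological association: it relates population-level
#' quantities and carries no patient-level causal interpretation.
#'
#' @param points Tibble with columns `ep_pct`, `net_survival_1yr`,
#'   `definition_type`, optionally `site` and `jurisdiction`; one row per
#'   jurisdiction, all for one cancer site.
#' @param conf Confidence level.
#' @return An `ecological_fit` list: `site`, `beta_per_10pct`, `ci_low`,
#'   `ci_high`, `p_value`, `definition_offset` (narrow-vs-broad intercept
#'   shift, `NA` when only one type present), `r2`, `k`, and the `lm` fit.
#' @export
fit_ecological <- function(points, conf = 0.95) {
  points <- as_tibble(points)
  k <- nrow(points)
  if (k < 4) stop_validation("Need at least 4 jurisdiction points.")
  if (length(unique(points$ep_pct)) == 1) {
    stop_validation("Singular design: ep_pct is constant.")
  }
  two_types <- "definition_type" %in% names(points) &&
    length(unique(points$definition_type)) > 1
  if (two_types) {
    points$narrow <- as.integer(points$definition_type == "narrow")
    fit <- lm(net_survival_1yr ~ ep_pct + narrow, data = points)
  } else {
    fit <- lm(net_survival_1yr ~ ep_pct, data = points)
  }
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(confint(fit, "ep_pct", level = conf))
  # a constant outcome has zero total variance; report R2 = 0, not NaN
  r2 <- if (is.nan(sm$r.squared)) 0 else sm$r.squared
  structure(
    list(
      site = if ("site" %in% names(points)) unique(points$site)[1] else NA_character_,
      beta_per_10pct = 10 * unname(coef(fit)["ep_pct"]),
      ci_low = 10 * ci[1, 1],
      ci_high = 10 * ci[1, 2],
      p_value = sm$coefficients["ep_pct", "Pr(>|t|)"],
      definition_offset = if (two_types) unname(coef(fit)["narrow"]) else NA_real_,
      r2 = r2,
      k = k,
      fit = fit
    ),
    class = "ecological_fit"
  )
}

#' @method print ecological_fit
#' @export
print.ecological_fit <- function(x, ...) {
  cat(sprintf(
    "Ecological fit%s: beta %.2f (%.2f to %.2f) per 10%% EP, p = %.3g, R2 = %.2f, k = %d\n",
    if (is.na(x$site)) "" else paste0(" (", x$site, ")"),
    x$beta_per_10pct, x$ci_low, x$ci_high, x$p_value, x$r2, x$k
  ))
  invisible(x)
}

#' Ecological fits for every cancer site in a table
#'
#' @param points Tibble as in [fit_ecological()] with a `site` column.
#' @param conf Confidence level.
#' @return Tibble with one row per site: `site`, `beta_per_10pct`,
#'   `ci_low`, `ci_high`, `p_value`, `definition_offset`, `r2`, `k`.
#' @export
fit_ecological_by_site <- function(points, conf = 0.95) {
  points <- as_tibble(points)
  bind_rows(lapply(split(points, points$site), function(d) {
    f <- fit_ecological(d, conf = conf)
    tibble(
      site = f$site, beta_per_10pct = f$beta_per_10pct,
      ci_low = f$ci_low, ci_high = f$ci_high, p_value = f$p_value,
      definition_offset = f$definition_offset, r2 = f$r2, k = f$k
    )
  }))
}
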