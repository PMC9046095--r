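#' Wilson score interval for a binomial proportion
#'
#' Confidence interval obtained by inverting the normal-approximation score
#' test: centre \eqn{(\hat p + z^2/2n)/(1 + z^2/n)}, half-width
#' \eqn{z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}/(1 + z^2/n)}. Unlike the Wald
#' interval it always lies inside [0, 1] and is non-degenerate at
#' \eqn{\hat p = 0} or 1. No continuity correction is applied.
#'
#' @param k Integer vector of successes.
#' @param n Integer vector of trials (`n >= 1`).
#' @param conf Confidence level, default 0.95.
#' @return Tibble with columns `low` and `high` (proportions).
#' @examples
#' wilson_interval(9165, 38212)
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  if (any(n < 1)) stop_validation("Wilson interval undefined for n = 0.")
  if (any(k < 0) || any(k > n)) stop_validation("Require 0 <= k <= n.")
  z <- z_value(conf)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' EP percentages by stratum, with Wilson intervals
#'
#' Tabulates the percentage of diagnoses classified as emergency
#' presentations within each combination of the stratification variables,
#' with 95% Wilson score intervals. Percentages are kept at full precision;
#' rounding to one decimal is left to the presentation layer.
#'
#' @param data Tibble of tumour records joined to their EP labels, holding
#'   a logical column named by `definition` ("broad" or "narrow").
#' @param stratify_by Character vector of stratification variables (any
#'   subset of jurisdiction, site, age_group, sex, stage, year); empty for
#'   the pooled total.
#' @param definition Which definition's label column to summarise.
#' @param conf Confidence level for the Wilson interval.
#' @return Tibble with one row per observed stratum: the stratification
#'   columns plus `n`, `k`, `pct`, `ci_low`, `ci_high` (percentage scale)
#'   and `definition`.
#' @export
ep_percentage_by_stratum <- function(data, stratify_by = character(),
                                     definition = c("broad", "narrow"),
                                     conf = 0.95) {
  definition <- match.arg(definition)
  missing_vars <- setdiff(c(stratify_by, definition), names(data))
  if (length(missing_vars) > 0) {
    stop_config(sprintf("Unknown variable(s): %s",
                        paste(missing_vars, collapse = ", ")))
  }
  out <- data %>%
    group_by(across(all_of(stratify_by))) %>%
    summarise(
      n = dplyr::n(),
      k = sum(.data[[definition]]),
      .groups = "drop"
    )
  ci <- wilson_interval(out$k, out$n, conf)
  out %>%
    mutate(
      pct = 100 * .data$k / .data$n,
      ci_low = 100 * ci$low,
      ci_high = 100 * ci$high,
      definition = definition
    )
}

#' Concordance of cancer-site ordering across jurisdictions
#'
#' Correlates each jurisdiction's site-level EP-percentage vector against a
#' reference jurisdiction's vector, summarising how consistently the cancer
#' sites rank across jurisdictions. Pearson correlation on the percentages
#' is the default; Spearman rank correlation is available.
#'
#' @param pct_table Tidy tibble with columns `jurisdiction`, `site`,
#'   `ep_pct` covering the same sites in every jurisdiction.
#' @param reference Reference jurisdiction name.
#' @param method "pearson" (default) or "spearman".
#' @return Tibble `jurisdiction`, `r`, one row per non-reference
#'   jurisdiction.
#' @export
site_order_concordance <- function(pct_table, reference,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  wide <- tidyr::pivot_wider(
    pct_table %>% select("jurisdiction", "site", "ep_pct"),
    names_from = "site", values_from = "ep_pct"
  )
  if (!reference %in% wide$jurisdiction) {
    stop_config(sprintf("Reference jurisdiction '%s' not present.", reference))
  }
  mat <- as.matrix(wide[, -1])
  if (anyNA(mat)) {
    stop_validation("Every jurisdiction must cover the same sites.")
  }
  rownames(mat) <- wide$jurisdiction
  if (any(apply(mat, 1, function(v) length(unique(v)) == 1))) {
    stop_validation("Correlation undefined: a jurisdiction has zero variance.")
  }
  others <- setdiff(wide$jurisdiction, reference)
  tibble(
    jurisdiction = others,
    r = vapply(others, function(j) {
      cor(mat[reference, ], mat[j, ], method = method)
    }, numeric(1), USE.NAMES = FALSE)
  )
}
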