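#' Published jurisdiction-level EP percentages by cancer site
#'
#' Jurisdiction-level percentages of cancer diagnoses made through emergency
#' presentation, by cancer site, as published by the International Cancer
#' Benchmarking Partnership (ICBP) across 14 jurisdictions in six countries
#' (diagnoses 2012-2017). Five jurisdictions applied the narrow operational
#' definition (no intervening elective admission), nine the broad definition.
#' Percentages are the published values rounded to one decimal.
#'
#' These aggregates are inputs to cross-jurisdiction summaries such as
#' [site_order_concordance()]; patient-level data underlying them are not
#' shareable and are emulated by [generate_cohort()].
#'
#' @return A tibble with columns `jurisdiction`, `definition_type`
#'   ("broad"/"narrow"), `site` (the eight sites plus `"all"`), `ep_pct`.
#' @export
icbp_ep_percentages <- function() {
  sites <- c("all", EP_SITES)
  rows <- list(
    list("Denmark",               "narrow", c(30.9, 24.3, 32.2, 28.3, 13.5, 43.3, 48.0, 36.4, 20.6)),
    list("England",               "narrow", c(31.3, 19.7, 31.4, 29.3, 10.7, 42.4, 46.9, 34.7, 34.8)),
    list("Northern Ireland",      "narrow", c(27.9, 19.9, 29.6, 23.8,  9.1, 36.9, 42.7, 32.0, 29.6)),
    list("New South Wales",       "narrow", c(30.9, 26.9, 30.5, 27.6, 12.1, 36.8, 45.3, 36.4, 28.4)),
    list("Victoria",              "narrow", c(24.0, 20.0, 23.7, 22.9,  9.1, 31.9, 34.1, 27.8, 20.9)),
    list("Norway",                "broad",  c(36.5, 32.7, 40.0, 35.8, 15.8, 50.6, 55.4, 39.4, 34.9)),
    list("Scotland",              "broad",  c(38.5, 25.2, 39.1, 35.1, 14.1, 47.5, 59.2, 42.1, 42.8)),
    list("Wales",                 "broad",  c(37.4, 25.5, 39.1, 34.2, 13.8, 50.5, 56.7, 41.5, 40.8)),
    list("Alberta",               "broad",  c(30.0, 23.0, 34.6, 28.6, 12.9, 31.7, 40.9, 33.3, 25.7)),
    list("Atlantic Canada",       "broad",  c(26.9, 20.7, 30.4, 28.4, 12.6, 34.3, 38.8, 26.6, 28.1)),
    list("British Columbia",      "broad",  c(30.5, 28.3, 40.3, 27.5, 12.0, 38.1, 41.4, 33.2, 31.7)),
    list("Ontario",               "broad",  c(26.1, 20.3, 26.9, 27.2, 11.0, 28.3, 35.3, 27.5, 23.9)),
    list("Saskatchewan-Manitoba", "broad",  c(28.3, 18.5, 31.8, 27.7, 13.7, 33.3, 37.3, 30.6, 30.1)),
    list("New Zealand",           "broad",  c(42.5, 36.8, 47.8, 36.6, 19.8, 49.7, 60.4, 51.1, 48.1))
  )
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble(
      jurisdiction = r[[1]], definition_type = r[[2]],
      site = sites, ep_pct = r[[3]]
    )
  }))
}

#' Published pooled EP counts for selected cancer sites
#'
#' Numerator/denominator pairs behind headline EP percentages in the ICBP
#' emergency-presentation study: the cross-jurisdiction pooled counts for
#' the sites with the highest (pancreatic) and lowest (rectal) average EP
#' percentage, together with each site's jurisdictional extremes.
#'
#' @return A tibble with columns `site`, `scope`, `k` (EP cases), `n`
#'   (diagnoses).
#' @export
icbp_pooled_site_counts <- function() {
  tibble(
    site = c("pancreatic", "pancreatic", "pancreatic",
             "rectal", "rectal", "rectal"),
    scope = rep(c("pooled", "jurisdiction_min", "jurisdiction_max"), 2),
    k = c(30972L, 1083L, 1317L, 10051L, 403L, 643L),
    n = c(67173L, 3172L, 2182L, 83325L, 4438L, 3247L)
  )
}

#' Published 12-month mortality counts and odds ratios by jurisdiction
#'
#' Jurisdiction-level frequency of 12-month all-cause mortality by emergency
#' presentation (EP) status across all eight cancer sites combined, with the
#' published crude, stage-unadjusted and stage-adjusted odds ratios, as
#' published by the ICBP. British Columbia and Victoria did not contribute
#' stage data across all cancer sites (`has_full_stage = FALSE`) and are
#' excluded from pooled stage-adjusted analyses.
#'
#' @return A tibble with one row per jurisdiction: patient and death counts
#'   by EP status (`n_ep`, `d_ep`, `n_nonep`, `d_nonep`), the published ORs
#'   with their 95% CI bounds (`crude_*`, `adj_*`, `stageadj_*`),
#'   `definition_type`, and `has_full_stage`.
#' @export
icbp_mortality_table <- function() {
  tribble_rows <- list(
    #   jurisdiction            def      n_nonep d_nonep  n_ep   d_ep   crude            adj              stageadj         full_stage
    list("Denmark",              "narrow", 31804,  9013,  14199,  8597, c(3.88, 3.72, 4.05), c(3.28, 3.13, 3.43), c(2.62, 2.49, 2.76), TRUE),
    list("Norway",               "broad",  29281,  7222,  16866, 10107, c(4.57, 4.39, 4.76), c(4.37, 4.17, 4.58), c(3.31, 3.15, 3.49), TRUE),
    list("England",              "narrow", 256260, 99437, 116934, 88261, c(4.85, 4.78, 4.93), c(4.54, 4.46, 4.62), c(3.46, 3.39, 3.53), TRUE),
    list("Northern Ireland",     "narrow", 11179,  4328,   4322,  3380, c(5.68, 5.24, 6.17), c(5.46, 4.98, 5.99), c(3.53, 3.19, 3.92), TRUE),
    list("Scotland",             "broad",  27708, 10910,  17321, 12507, c(4.00, 3.84, 4.17), c(3.60, 3.44, 3.77), c(2.95, 2.80, 3.11), TRUE),
    list("Wales",                "broad",  16376,  6253,   9763,  7017, c(4.14, 3.92, 4.37), c(3.79, 3.57, 4.03), c(2.99, 2.79, 3.19), TRUE),
    list("Alberta",              "broad",  17741,  5599,   7441,  4839, c(4.03, 3.81, 4.27), c(3.86, 3.62, 4.12), c(2.63, 2.45, 2.83), TRUE),
    list("Atlantic Canada",      "broad",   8065,  2745,   2905,  1855, c(3.42, 3.13, 3.74), c(3.79, 3.42, 4.21), c(2.74, 2.44, 3.08), TRUE),
    list("British Columbia",     "broad",  11295,  3555,   5195,  3320, c(3.84, 3.59, 4.12), c(4.01, 3.70, 4.36), c(3.11, 2.85, 3.39), FALSE),
    list("Ontario",              "broad",  68316, 20197,  24131, 14623, c(3.66, 3.55, 3.78), c(3.87, 3.74, 4.00), c(2.95, 2.84, 3.06), TRUE),
    list("Saskatchewan-Manitoba","broad",   5985,  1955,   2400,  1520, c(3.57, 3.24, 3.95), c(3.77, 3.36, 4.24), c(2.72, 2.39, 3.09), TRUE),
    list("New South Wales",      "narrow", 36753,  9663,  16445,  9836, c(4.17, 4.01, 4.34), c(3.74, 3.58, 3.91), c(2.89, 2.75, 3.03), TRUE),
    list("Victoria",             "narrow", 29047,  7557,   9165,  5328, c(3.95, 3.76, 4.15), c(3.70, 3.50, 3.92), c(3.33, 3.15, 3.53), FALSE),
    list("New Zealand",          "broad",  16556,  4653,  12238,  7572, c(4.15, 3.95, 4.36), c(3.73, 3.53, 3.95), c(2.57, 2.42, 2.74), TRUE)
  )
  dplyr::bind_rows(lapply(tribble_rows, function(r) {
    tibble(
      jurisdiction = r[[1]], definition_type = r[[2]],
      n_nonep = r[[3]], d_nonep = r[[4]], n_ep = r[[5]], d_ep = r[[6]],
      crude_or = r[[7]][1], crude_lo = r[[7]][2], crude_hi = r[[7]][3],
      adj_or = r[[8]][1], adj_lo = r[[8]][2], adj_hi = r[[8]][3],
      stageadj_or = r[[9]][1], stageadj_lo = r[[9]][2], stageadj_hi = r[[9]][3],
      has_full_stage = r[[10]]
    )
  }))
}
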