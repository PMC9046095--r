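#' Binary mortality indicator at a fixed horizon
#'
#' A record counts as dead at the horizon iff its death date falls within
#' `horizon` of the diagnosis date (1m = 30 days, 3m = 91 days, 12m = 365
#' days). Records censored before the horizon are assumed to have survived
#' (they return `FALSE`), the convention appropriate when registry
#' follow-up is near-complete.
#'
#' @param diagnosis_date,death_date `Date` vectors; `death_date` is `NA`
#'   for patients not known to have died.
#' @param horizon One of "1m", "3m", "12m".
#' @return Logical vector.
#' @export
mortality_indicator <- function(diagnosis_date, death_date,
                                horizon = c("12m", "1m", "3m")) {
  horizon <- match.arg(horizon)
  days <- EP_HORIZON_DAYS[[horizon]]
  delta <- as.numeric(death_date - diagnosis_date)
  if (any(delta < 0, na.rm = TRUE)) {
    stop_validation("death_date precedes diagnosis_date.")
  }
  !is.na(delta) & delta <= days
}

effect_estimate <- function(term, log_or, se, conf = 0.95, ...) {
  z <- z_value(conf)
  tibble(
    term = term, log_or = log_or, se = se,
    or = exp(log_or),
    ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se),
    ...
  )
}

#' Crude odds ratio from a 2x2 table
#'
#' \eqn{OR = ad/bc} with the standard error of the log-OR
#' \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}} and a Wald CI on the log scale. Cells
#' are the exposed (EP) dead/alive counts `a`, `b` and unexposed (non-EP)
#' dead/alive counts `c`, `d`. A zero cell raises an error rather than
#' applying a silent continuity correction.
#'
#' @param a,b,c,d Non-negative counts.
#' @param conf Confidence level.
#' @return One-row tibble: `term`, `log_or`, `se`, `or`, `ci_low`,
#'   `ci_high`.
#' @examples
#' crude_or(8597, 5602, 9013, 22791)  # OR 3.88
#' @export
crude_or <- function(a, b, c, d, conf = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop_validation("Counts must be non-negative.")
  if (any(counts == 0)) {
    stop_validation("Zero cell in 2x2 table; crude OR undefined (no continuity correction applied).")
  }
  effect_estimate(
    term = "ep_statusTRUE",
    log_or = log((a * d) / (b * c)),
    se = sqrt(sum(1 / counts)),
    conf = conf
  )
}

#' Specify a logistic model
#'
#' @param outcome One of "ep", "death_1m", "death_3m", "death_12m".
#' @param covariates Ordered character vector drawn from `ep_status`,
#'   `site`, `age_group`, `sex`, `year`, `stage`; `ep_status` is only valid
#'   for mortality outcomes.
#' @param reference_levels Named list overriding the default reference
#'   levels (site = "colon", age_group = "15-64", sex = "male", year =
#'   earliest observed, stage = first level present, ep_status = FALSE).
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome = c("ep", "death_1m", "death_3m", "death_12m"),
                       covariates,
                       reference_levels = list()) {
  outcome <- match.arg(outcome)
  allowed <- c("ep_status", "site", "age_group", "sex", "year", "stage")
  bad <- setdiff(covariates, allowed)
  if (length(bad) > 0) {
    stop_config(sprintf("Unknown covariate(s): %s", paste(bad, collapse = ", ")))
  }
  if ("ep_status" %in% covariates && outcome == "ep") {
    stop_config("ep_status is only a covariate for mortality outcomes.")
  }
  structure(
    list(
      outcome = outcome, covariates = covariates,
      reference_levels = reference_levels,
      stage_adjusted = "stage" %in% covariates
    ),
    class = "model_spec"
  )
}

default_reference <- function(var, values) {
  switch(var,
    site = "colon",
    age_group = "15-64",
    sex = "male",
    ep_status = "FALSE",
    year = as.character(min(as.integer(values))),
    stage = intersect(c("localised", names(table(values))), values)[1]
  )
}

#' Fit a multivariable logistic regression and tidy its odds ratios
#'
#' Maximum-likelihood logistic fit with categorical covariates dummy-coded
#' against their reference levels (colon for site, 15-64 for age group,
#' male for sex, the earliest year; year is treated as categorical). Wald
#' standard errors and symmetric CIs on the log-odds scale. Perfect
#' separation and rank deficiency raise errors rather than returning
#' unusable coefficients.
#'
#' @param data Tibble holding the outcome and covariate columns. Mortality
#'   outcomes are derived from `diagnosis_date`/`death_date` via
#'   [mortality_indicator()] when not already present; the `ep` outcome and
#'   the `ep_status` covariate use the logical `ep` column.
#' @param spec A [model_spec()].
#' @param conf Confidence level for the Wald CIs.
#' @return Tibble of effect estimates, one row per non-reference level:
#'   `term`, `log_or`, `se`, `or`, `ci_low`, `ci_high`, plus `outcome` and
#'   `n`.
#' @export
fit_logistic <- function(data, spec, conf = 0.95) {
  data <- as_tibble(data)
  y <- switch(spec$outcome,
    ep = data$ep,
    death_1m = column_or_derive(data, "death_1m", "1m"),
    death_3m = column_or_derive(data, "death_3m", "3m"),
    death_12m = column_or_derive(data, "death_12m", "12m")
  )
  if (is.null(y)) stop_config("Outcome column not resolvable.")

  df <- tibble(.y = as.logical(y))
  for (v in spec$covariates) {
    vals <- if (v == "ep_status") as.character(data$ep) else as.character(data[[v]])
    ref <- spec$reference_levels[[v]] %||% default_reference(v, vals)
    if (!ref %in% vals) ref <- sort(unique(vals))[1]
    df[[v]] <- stats::relevel(factor(vals), ref = ref)
    if (nlevels(df[[v]]) < 2) {
      stop_validation(sprintf("Covariate '%s' is constant (aliased term).", v))
    }
  }

  form <- stats::as.formula(
    paste(".y ~", paste(spec$covariates, collapse = " + "))
  )
  fit <- suppressWarnings(glm(form, family = binomial(), data = df))
  if (!fit$converged) {
    abort("Logistic fit did not converge (possible separation).",
          class = "eproutes_convergence_error")
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop_validation("Rank-deficient design: aliased term(s) in the model.")
  }
  fitted_p <- fit$fitted.values
  if (any(abs(cf[-1]) > 15) || all(fitted_p > 1 - 1e-8 | fitted_p < 1e-8)) {
    abort("Perfect separation detected in logistic fit.",
          class = "eproutes_convergence_error")
  }
  se <- sqrt(diag(vcov(fit)))
  keep <- names(cf) != "(Intercept)"
  effect_estimate(
    term = names(cf)[keep],
    log_or = unname(cf[keep]),
    se = unname(se[keep]),
    conf = conf,
    outcome = spec$outcome,
    n = nrow(df)
  )
}

column_or_derive <- function(data, col, horizon) {
  if (col %in% names(data)) return(data[[col]])
  mortality_indicator(data$diagnosis_date, data$death_date, horizon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the full per-jurisdiction model battery
#'
#' For each jurisdiction: the two incremental EP-risk models (model 1 with
#' site, age group, sex and year; model 2 additionally with stage), and the
#' EP-mortality models (crude 2x2, adjusted without stage, and
#' stage-adjusted) at each requested horizon. When a jurisdiction lacks
#' usable stage data (stage entirely missing for at least one site),
#' stage-adjusted models are skipped and flagged. Fit failures are recorded
#' per model without aborting the batch.
#'
#' @param data Tibble of included tumour records joined to EP labels, with
#'   a logical `ep` column giving each jurisdiction's operative definition.
#' @param horizons Mortality horizons to fit, subset of c("1m","3m","12m").
#' @param stage_adjusted Whether to attempt stage-adjusted models.
#' @return Tidy tibble of estimates with columns `jurisdiction`, `model`,
#'   `horizon`, `term`, `log_or`, `se`, `or`, `ci_low`, `ci_high`, `n`,
#'   `converged`, plus a `note` for skipped/failed fits.
#' @export
run_jurisdiction_models <- function(data, horizons = "12m",
                                    stage_adjusted = TRUE) {
  data <- as_tibble(data)
  results <- list()
  add <- function(jur, model, horizon, est) {
    results[[length(results) + 1]] <<- est %>%
      mutate(jurisdiction = jur, model = model, horizon = horizon,
             converged = TRUE, note = NA_character_)
  }
  add_failure <- function(jur, model, horizon, msg) {
    results[[length(results) + 1]] <<- tibble(
      jurisdiction = jur, model = model, horizon = horizon,
      term = NA_character_, log_or = NA_real_, se = NA_real_, or = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, outcome = NA_character_,
      n = NA_integer_, converged = FALSE, note = msg
    )
  }
  try_fit <- function(jur, model, horizon, expr) {
    tryCatch(add(jur, model, horizon, expr()),
             error = function(e) add_failure(jur, model, horizon,
                                             conditionMessage(e)))
  }

  for (jur in unique(data$jurisdiction)) {
    d <- data %>% filter(.data$jurisdiction == jur)
    stage_usable <- stage_adjusted && has_full_stage(d)

    try_fit(jur, "ep_risk_1", NA_character_, function() {
      fit_logistic(d, model_spec("ep", c("site", "age_group", "sex", "year")))
    })
    if (stage_usable) {
      try_fit(jur, "ep_risk_2", NA_character_, function() {
        fit_logistic(d, model_spec("ep", c("site", "age_group", "sex",
                                           "year", "stage")))
      })
    } else if (stage_adjusted) {
      add_failure(jur, "ep_risk_2", NA_character_,
                  "stage data unavailable for all sites; model skipped")
    }

    for (h in horizons) {
      outcome <- paste0("death_", h)
      dead <- mortality_indicator(d$diagnosis_date, d$death_date, h)
      try_fit(jur, "mortality_crude", h, function() {
        crude_or(sum(d$ep & dead), sum(d$ep & !dead),
                 sum(!d$ep & dead), sum(!d$ep & !dead))
      })
      try_fit(jur, "mortality_adjusted", h, function() {
        fit_logistic(d, model_spec(outcome, c("ep_status", "site",
                                              "age_group", "sex", "year")))
      })
      if (stage_usable) {
        try_fit(jur, "mortality_stage_adjusted", h, function() {
          fit_logistic(d, model_spec(outcome, c("ep_status", "site",
                                                "age_group", "sex", "year",
                                                "stage")))
        })
      } else if (stage_adjusted) {
        add_failure(jur, "mortality_stage_adjusted", h,
                    "stage data unavailable for all sites; model skipped")
      }
    }
  }
  bind_rows(results)
}

has_full_stage <- function(d) {
  by_site <- d %>%
    group_by(.data$site) %>%
    summarise(any_staged = any(.data$stage != "missing", na.rm = TRUE),
              .groups = "drop")
  all(by_site$any_staged)
}
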