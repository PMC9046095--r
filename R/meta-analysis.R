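#' Back-derive a log-OR standard error from a printed confidence interval
#'
#' For an OR with a symmetric-on-the-log-scale CI,
#' \eqn{se = (\ln U - \ln L) / (2 z)}. Used to pool published tables that
#' print ORs with CIs but not standard errors.
#'
#' @param or_ Odds ratio (point estimate).
#' @param ci_low,ci_high CI bounds, `0 < ci_low <= or_ <= ci_high`.
#' @param conf Confidence level the printed interval refers to.
#' @return Positive standard error of the log-OR.
#' @examples
#' se_from_ci(3.88, 3.72, 4.05)
#' @export
se_from_ci <- function(or_, ci_low, ci_high, conf = 0.95) {
  if (any(ci_low <= 0) || any(ci_high <= 0)) {
    stop_validation("CI bounds must be positive.")
  }
  if (any(ci_low > or_) || any(ci_high < or_)) {
    stop_validation("Require ci_low <= or <= ci_high.")
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * z_value(conf))
  if (any(se <= 0)) {
    stop_validation("Degenerate CI (zero width) gives se = 0.")
  }
  se
}

#' Random-effects pooling of jurisdiction log-ORs
#'
#' Pools study (jurisdiction) log-odds-ratios by inverse-variance
#' random-effects meta-analysis, optionally as a meta-regression with the
#' operational definition type (broad vs narrow) as a moderator. With the
#' moderator on, per-definition pooled ORs are the fitted values at each
#' moderator level. Between-study variance is estimated by REML (default)
#' or DerSimonian-Laird; `method = "FE"` forces \eqn{\tau^2 = 0}
#' (fixed-effect inverse-variance weighting). No Knapp-Hartung adjustment
#' is applied.
#'
#' Two I-squared figures are reported: `i2` is the Cochran-Q form
#' \eqn{\max(0, (Q - df)/Q) \times 100} for the fitted model, and
#' `i2_unmoderated` the same computed without the moderator, since a
#' moderated model's residual heterogeneity and the total heterogeneity
#' answer different questions.
#'
#' @param estimates Tibble with columns `log_or`, `se` (> 0), and, when
#'   `moderator = TRUE`, `definition_type` ("broad"/"narrow"); a
#'   `jurisdiction` column is carried through when present.
#' @param moderator Include the narrow-definition indicator?
#' @param method tau-squared estimator: "REML" (default), "DL", or "FE".
#' @param conf Confidence level.
#' @param min_k Minimum number of studies; defaults to 2 (3 with the
#'   moderator, to leave residual degrees of freedom). May be relaxed
#'   explicitly, e.g. for the single-study identity check.
#' @return A `meta_result` list: `pooled` (tibble of pooled ORs overall or
#'   per definition type), `tau2`, `Q`, `df`, `i2`, `i2_unmoderated`,
#'   `moderator_coef`, `k`, `method`, and the underlying `rma` fit.
#' @export
pool_random_effects <- function(estimates, moderator = FALSE,
                                method = c("REML", "DL", "FE"),
                                conf = 0.95, min_k = NULL) {
  method <- match.arg(method)
  estimates <- as_tibble(estimates)
  if (any(!is.finite(estimates$se)) || any(estimates$se <= 0)) {
    stop_validation("All standard errors must be positive.")
  }
  k <- nrow(estimates)
  min_k <- min_k %||% if (moderator) 3L else 2L
  if (k < min_k) {
    abort(sprintf("Need at least %d studies (got %d).", min_k, k),
          class = "eproutes_insufficient_studies_error")
  }
  level <- conf * 100

  if (moderator) {
    if (!"definition_type" %in% names(estimates)) {
      stop_config("moderator = TRUE requires a definition_type column.")
    }
    narrow <- as.integer(estimates$definition_type == "narrow")
    fit <- metafor::rma(yi = estimates$log_or, sei = estimates$se,
                        mods = ~narrow, method = method, level = level)
    pred <- metafor::predict.rma(fit, newmods = c(0, 1))
    pooled <- tibble(
      definition_type = c("broad", "narrow"),
      log_or = as.numeric(pred$pred),
      se = as.numeric(pred$se),
      or = exp(as.numeric(pred$pred)),
      ci_low = exp(as.numeric(pred$ci.lb)),
      ci_high = exp(as.numeric(pred$ci.ub))
    )
    moderator_coef <- tibble(
      term = "definition_typenarrow",
      estimate = as.numeric(coef(fit)["narrow"]),
      se = fit$se[rownames(fit$beta) == "narrow"]
    )
    fit0 <- metafor::rma(yi = estimates$log_or, sei = estimates$se,
                         method = method, level = level)
  } else {
    fit <- metafor::rma(yi = estimates$log_or, sei = estimates$se,
                        method = method, level = level)
    pooled <- tibble(
      definition_type = "overall",
      log_or = as.numeric(fit$beta),
      se = fit$se,
      or = exp(as.numeric(fit$beta)),
      ci_low = exp(fit$ci.lb),
      ci_high = exp(fit$ci.ub)
    )
    moderator_coef <- NULL
    fit0 <- fit
  }

  i2_from_q <- function(Q, df) if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  df <- k - fit$p
  structure(
    list(
      pooled = pooled,
      tau2 = fit$tau2,
      Q = as.numeric(fit$QE),
      df = df,
      i2 = i2_from_q(as.numeric(fit$QE), df),
      i2_unmoderated = i2_from_q(as.numeric(fit0$QE), k - 1),
      i2_tau2 = as.numeric(fit$I2),
      moderator_coef = moderator_coef,
      k = k,
      method = method,
      fit = fit
    ),
    class = "meta_result"
  )
}

#' @method print meta_result
#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (%s), k = %d\n", x$method, x$k))
  for (i in seq_len(nrow(x$pooled))) {
    cat(sprintf("  %-8s OR %.3f (%.3f-%.3f)\n",
                x$pooled$definition_type[i], x$pooled$or[i],
                x$pooled$ci_low[i], x$pooled$ci_high[i]))
  }
  cat(sprintf("  tau2 = %.4f, Q = %.2f (df %d), I2 = %.1f%%\n",
              x$tau2, x$Q, x$df, x$i2))
  invisible(x)
}

#' Pool the published stage-adjusted 12-month mortality odds ratios
#'
#' Convenience wrapper: takes the published jurisdiction table
#' ([icbp_mortality_table()]), restricts to the jurisdictions with stage
#' data for all sites, back-derives standard errors from the printed CIs,
#' and runs the definition-type-moderated REML meta-regression.
#'
#' @param table A tibble in the shape of [icbp_mortality_table()].
#' @param method tau-squared estimator passed through.
#' @return A `meta_result`.
#' @export
pool_published_stage_adjusted <- function(table = icbp_mortality_table(),
                                          method = "REML") {
  studies <- table %>%
    filter(.data$has_full_stage) %>%
    mutate(
      log_or = log(.data$stageadj_or),
      se = se_from_ci(.data$stageadj_or, .data$stageadj_lo, .data$stageadj_hi)
    ) %>%
    select("jurisdiction", "definition_type", "log_or", "se")
  pool_random_effects(studies, moderator = TRUE, method = method)
}
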