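test_that("mortality indicator applies horizons and the censoring rule", {
  diag <- as.Date("2015-01-01")
  expect_true(mortality_indicator(diag, diag + 300, "12m"))
  expect_false(mortality_indicator(diag, diag + 400, "12m"))
  # censored before horizon: assumed to have survived
  expect_false(mortality_indicator(diag, as.Date(NA), "12m"))
  # threshold ordering for one death at 40 days
  expect_false(mortality_indicator(diag, diag + 40, "1m"))
  expect_true(mortality_indicator(diag, diag + 40, "3m"))
  expect_true(mortality_indicator(diag, diag + 40, "12m"))
  # boundary days are inclusive
  expect_true(mortality_indicator(diag, diag + 30, "1m"))
  expect_true(mortality_indicator(diag, diag + 365, "12m"))
  expect_error(mortality_indicator(diag, diag - 1, "12m"),
               class = "eproutes_validation_error")
})

test_that("mortality is monotone in the horizon for random records", {
  set.seed(61)
  diag <- as.Date("2015-01-01") + sample(0:700, 300, TRUE)
  death <- diag + sample(0:500, 300, TRUE)
  death[sample(300, 80)] <- NA
  m1 <- mortality_indicator(diag, death, "1m")
  m3 <- mortality_indicator(diag, death, "3m")
  m12 <- mortality_indicator(diag, death, "12m")
  expect_true(all(m1 <= m3))
  expect_true(all(m3 <= m12))
})

test_that("crude odds ratios reproduce closed-form values", {
  est <- crude_or(8597, 5602, 9013, 22791)
  expect_equal(est$or, (8597 * 22791) / (5602 * 9013), tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 8597 + 1 / 5602 + 1 / 9013 + 1 / 22791))
  expect_true(est$ci_low < est$or && est$or < est$ci_high)
  # identity when all cells equal
  expect_equal(crude_or(7, 7, 7, 7)$or, 1)
  expect_error(crude_or(0, 5, 5, 5), class = "eproutes_validation_error")
  expect_error(crude_or(-1, 5, 5, 5), class = "eproutes_validation_error")
})

test_that("saturated logistic fit equals the 2x2 crude OR", {
  d <- expand_2x2(8597, 5602, 9013, 22791)
  fit <- fit_logistic(d, model_spec("death_12m", "ep_status"))
  oracle <- crude_or(8597, 5602, 9013, 22791)
  expect_equal(fit$log_or, oracle$log_or, tolerance = 1e-7)
  expect_equal(fit$se, oracle$se, tolerance = 1e-6)
})

test_that("a null synthetic model yields odds ratios near one", {
  set.seed(71)
  n <- 5000
  d <- tibble::tibble(
    ep = sample(c(TRUE, FALSE), n, TRUE),
    site = sample(ep_sites()[1:4], n, TRUE),
    age_group = sample(ep_age_groups(), n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    year = sample(2012:2017, n, TRUE),
    death_12m = sample(c(TRUE, FALSE), n, TRUE)
  )
  fit <- fit_logistic(d, model_spec("death_12m",
                                    c("ep_status", "site", "age_group",
                                      "sex", "year")))
  expect_true(all(abs(fit$log_or) < 3 * fit$se))
})

test_that("reference levels follow the documented defaults", {
  set.seed(73)
  n <- 3000
  d <- tibble::tibble(
    ep = runif(n) < 0.3,
    site = sample(ep_sites(), n, TRUE),
    age_group = sample(ep_age_groups(), n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    year = sample(2012:2017, n, TRUE)
  )
  fit <- fit_logistic(d, model_spec("ep", c("site", "age_group", "sex",
                                            "year")))
  expect_false(any(grepl("sitecolon", fit$term)))     # colon is reference
  expect_false(any(grepl("age_group15-64", fit$term)))
  expect_false(any(grepl("year2012", fit$term)))      # earliest year
  expect_true(any(grepl("sitepancreatic", fit$term)))
})

test_that("changing the reference level rescales odds ratios consistently", {
  set.seed(79)
  n <- 4000
  d <- tibble::tibble(
    ep = runif(n) < (0.2 + 0.2 * (sample(c("colon", "lung", "rectal"), n,
                                         TRUE) == "lung")),
    site = sample(c("colon", "lung", "rectal"), n, TRUE)
  )
  d$ep <- runif(n) < (0.2 + 0.25 * (d$site == "lung"))
  f_colon <- fit_logistic(d, model_spec("ep", "site"))
  f_lung <- fit_logistic(d, model_spec("ep", "site",
                                       reference_levels = list(site = "lung")))
  or_lung_vs_colon <- f_colon$or[f_colon$term == "sitelung"]
  or_colon_vs_lung <- f_lung$or[f_lung$term == "sitecolon"]
  expect_equal(or_lung_vs_colon, 1 / or_colon_vs_lung, tolerance = 1e-8)
  # ratio identity for a third level
  expect_equal(
    f_colon$or[f_colon$term == "siterectal"] / or_lung_vs_colon,
    f_lung$or[f_lung$term == "siterectal"],
    tolerance = 1e-8
  )
})

test_that("degenerate designs raise informative errors", {
  d <- tibble::tibble(ep = c(TRUE, FALSE, TRUE, FALSE),
                      site = rep("colon", 4))
  expect_error(fit_logistic(d, model_spec("ep", "site")),
               class = "eproutes_validation_error")
  # perfect separation
  d2 <- tibble::tibble(
    ep = rep(c(TRUE, FALSE), each = 50),
    death_12m = rep(c(TRUE, FALSE), each = 50)
  )
  expect_error(fit_logistic(d2, model_spec("death_12m", "ep_status")),
               class = "eproutes_convergence_error")
  expect_error(model_spec("ep", c("ep_status", "site")),
               class = "eproutes_config_error")
})

test_that("the jurisdiction model battery is complete and flags missing stage", {
  cfg <- two_jurisdiction_config(n = 3000, seed = 83)
  co <- generate_cohort(cfg)
  labels <- classify_cohort(co$tumours, co$admissions)
  d <- dplyr::left_join(co$tumours, labels, by = "patient_id") %>%
    dplyr::mutate(ep = .data$broad)
  res <- run_jurisdiction_models(d, horizons = "12m")
  for (jur in c("Arden", "Brightwater")) {
    stage_adj <- res %>%
      dplyr::filter(jurisdiction == jur, model == "mortality_stage_adjusted",
                    term == "ep_statusTRUE")
    expect_equal(nrow(stage_adj), 1)
    expect_true(stage_adj$converged)
  }

  # a jurisdiction with no stage for one site: stage models skipped, flagged
  d2 <- d %>%
    dplyr::mutate(stage = dplyr::if_else(
      .data$jurisdiction == "Arden" & .data$site == "lung",
      "missing", .data$stage
    ))
  res2 <- run_jurisdiction_models(d2, horizons = "12m")
  skipped <- res2 %>%
    dplyr::filter(jurisdiction == "Arden",
                  model == "mortality_stage_adjusted")
  expect_false(any(skipped$converged))
  expect_match(skipped$note, "stage")
  still_there <- res2 %>%
    dplyr::filter(jurisdiction == "Brightwater",
                  model == "mortality_stage_adjusted",
                  term == "ep_statusTRUE")
  expect_equal(nrow(still_there), 1)
})

test_that("adjusted estimates approach crude when covariates are independent of EP", {
  set.seed(89)
  n <- 50000
  d <- tibble::tibble(
    ep = runif(n) < 0.3,
    site = sample(ep_sites(), n, TRUE),
    age_group = sample(ep_age_groups(), n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    year = sample(2012:2017, n, TRUE)
  )
  p <- plogis(-1.2 + log(3) * d$ep) # death independent of covariates
  d$death_12m <- runif(n) < p
  crude <- crude_or(
    sum(d$ep & d$death_12m), sum(d$ep & !d$death_12m),
    sum(!d$ep & d$death_12m), sum(!d$ep & !d$death_12m)
  )
  adj <- fit_logistic(d, model_spec("death_12m",
                                    c("ep_status", "site", "age_group",
                                      "sex", "year")))
  adj_ep <- adj %>% dplyr::filter(term == "ep_statusTRUE")
  expect_lt(abs(adj_ep$log_or - crude$log_or), 0.02)
})
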