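#' Simulation configuration for a synthetic linked registry
#'
#' Defines the multi-jurisdiction study conditions under which
#' [generate_cohort()] draws linked tumour and admission tables. Defaults
#' emulate a population-based cancer cohort diagnosed 2012-2017 in which
#' roughly three in ten diagnoses follow an emergency hospital admission,
#' EP risk rises with age and stage and is highest for pancreatic and liver
#' cancer and lowest for rectal cancer, and emergency presenters carry a
#' roughly three-fold 12-month mortality odds ratio after stage adjustment.
#'
#' Covariates (site, age group, sex, stage) are drawn independently within
#' each jurisdiction: the joint covariate distribution of real registries is
#' not emulated.
#'
#' @param jurisdictions Tibble or data frame with columns `name`,
#'   `definition_type` ("broad" or "narrow") and `n_patients`.
#' @param site_mix,age_mix,sex_mix,stage_mix Named probability vectors over
#'   cancer sites, age bands, sexes and (non-missing) stage categories; each
#'   must sum to 1 within 1e-9.
#' @param stage_missing_prob Fraction of records whose stage is recorded as
#'   missing (replacing the drawn stage).
#' @param ep_model List with `intercept` (log-odds) and named log-odds
#'   coefficient vectors `site`, `age_group`, `sex`, `stage` (reference
#'   levels implicitly 0; a `"missing"` stage coefficient may be supplied).
#' @param narrow_discordance Probability that a broad-EP case has an
#'   intervening elective admission (and so is not narrow-EP). The default
#'   0.15, with a marginal broad EP fraction near 33%, yields a broad-minus-
#'   narrow gap of about 5 percentage points.
#' @param mortality_model Like `ep_model`, for the 12-month death indicator,
#'   plus `ep_log_or`: the log-odds-ratio attached to EP status (default
#'   `log(3)`).
#' @param diagnosis_period Integer vector `c(first, last)` of diagnosis
#'   years; default `c(2012, 2017)`.
#' @param nonep_elective_prob Probability that a non-EP patient has an
#'   elective admission inside the pre-diagnosis window, exercising the
#'   emergency/elective distinction.
#' @param nonep_prior_emergency_prob Probability that a non-EP patient has
#'   an emergency admission well before the window (45-365 days
#'   pre-diagnosis).
#' @param seed Integer random seed; generation is deterministic given it.
#'
#' @return An object of class `ep_sim_config`.
#' @seealso [generate_cohort()], [generate_net_survival_table()]
#' @export
sim_config <- function(jurisdictions = default_jurisdictions(),
                       site_mix = c(
                         oesophageal = 0.07, stomach = 0.06, colon = 0.22,
                         rectal = 0.10, liver = 0.05, pancreatic = 0.08,
                         lung = 0.33, ovarian = 0.09
                       ),
                       age_mix = c("15-64" = 0.35, "65-74" = 0.27,
                                   "75-84" = 0.25, "85+" = 0.13),
                       sex_mix = c(male = 0.54, female = 0.46),
                       stage_mix = c(localised = 0.25, regional = 0.30,
                                     distant = 0.45),
                       stage_missing_prob = 0.08,
                       ep_model = default_ep_model(),
                       narrow_discordance = 0.15,
                       mortality_model = default_mortality_model(),
                       diagnosis_period = c(2012L, 2017L),
                       nonep_elective_prob = 0.01,
                       nonep_prior_emergency_prob = 0.02,
                       seed = 20120101L) {
  jurisdictions <- as_tibble(jurisdictions)
  required <- c("name", "definition_type", "n_patients")
  if (!all(required %in% names(jurisdictions))) {
    stop_config("`jurisdictions` needs columns name, definition_type, n_patients.")
  }
  if (any(!jurisdictions$definition_type %in% c("broad", "narrow"))) {
    stop_config("definition_type must be 'broad' or 'narrow'.")
  }
  if (any(jurisdictions$n_patients < 1)) {
    stop_config("n_patients must be >= 1 for every jurisdiction.")
  }
  check_prob_vector(site_mix, "site_mix")
  check_prob_vector(age_mix, "age_mix")
  check_prob_vector(sex_mix, "sex_mix")
  check_prob_vector(stage_mix, "stage_mix")
  if (!is.numeric(narrow_discordance) || narrow_discordance < 0 ||
      narrow_discordance > 1) {
    stop_config("narrow_discordance must lie in [0, 1].")
  }
  if (stage_missing_prob < 0 || stage_missing_prob > 1) {
    stop_config("stage_missing_prob must lie in [0, 1].")
  }
  if (length(diagnosis_period) != 2 ||
      diagnosis_period[1] > diagnosis_period[2]) {
    stop_config("diagnosis_period must be c(first_year, last_year).")
  }
  structure(
    list(
      jurisdictions = jurisdictions,
      site_mix = site_mix, age_mix = age_mix, sex_mix = sex_mix,
      stage_mix = stage_mix, stage_missing_prob = stage_missing_prob,
      ep_model = ep_model, narrow_discordance = narrow_discordance,
      mortality_model = mortality_model,
      diagnosis_period = as.integer(diagnosis_period),
      nonep_elective_prob = nonep_elective_prob,
      nonep_prior_emergency_prob = nonep_prior_emergency_prob,
      seed = as.integer(seed)
    ),
    class = "ep_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_jurisdictions <- function() {
  tibble(
    name = c("Arden", "Brightwater", "Caldera"),
    definition_type = c("narrow", "broad", "broad"),
    n_patients = c(20000L, 20000L, 20000L)
  )
}

#' @rdname sim_config
#' @export
default_ep_model <- function() {
  list(
    intercept = -1.65,
    site = c(oesophageal = -0.35, stomach = 0.10, colon = 0, rectal = -1.00,
             liver = 0.60, pancreatic = 0.80, lung = 0.30, ovarian = -0.10),
    age_group = c("15-64" = 0, "65-74" = -0.10, "75-84" = 0.35, "85+" = 0.90),
    sex = c(male = 0, female = 0.05),
    stage = c(localised = 0, regional = 0.35, distant = 1.00, missing = 0.35)
  )
}

#' @rdname sim_config
#' @export
default_mortality_model <- function() {
  list(
    intercept = -2.20,
    site = c(oesophageal = 1.20, stomach = 0.90, colon = 0, rectal = -0.15,
             liver = 1.40, pancreatic = 1.90, lung = 1.50, ovarian = -0.10),
    age_group = c("15-64" = 0, "65-74" = 0.30, "75-84" = 0.70, "85+" = 1.20),
    sex = c(male = 0, female = -0.05),
    stage = c(localised = 0, regional = 0.70, distant = 1.90, missing = 0.70),
    ep_log_or = log(3)
  )
}

model_eta <- function(model, data) {
  eta <- rep(model$intercept, nrow(data))
  for (v in c("site", "age_group", "sex", "stage")) {
    coefs <- model[[v]]
    if (is.null(coefs)) next
    x <- as.character(data[[v]])
    contrib <- unname(coefs[x])
    contrib[is.na(contrib)] <- 0
    eta <- eta + contrib
  }
  eta
}

# representative topography codes per site; ovarian includes the
# 4-character peritoneal/fallopian-tube codes
site_icd10_pool <- function(site) {
  switch(site,
    oesophageal = c("C15", "C15.3", "C15.5"),
    stomach = c("C16", "C16.0", "C16.9"),
    colon = c("C18", "C18.2", "C18.7", "C19"),
    rectal = c("C20"),
    liver = c("C22", "C22.0"),
    pancreatic = c("C25", "C25.0", "C25.9"),
    lung = c("C34", "C34.1", "C34.9"),
    ovarian = c("C56", "C48.1", "C48.2", "C57.0")
  )
}

#' Generate a synthetic linked tumour and admission cohort
#'
#' Draws, per jurisdiction, patient covariates from the configured mixes, a
#' latent EP status from the EP log-odds model, an admission history
#' consistent with that status, and a 12-month death indicator from the
#' mortality model. Broad-EP patients receive one emergency admission 0-30
#' days before diagnosis (inclusive); with probability `narrow_discordance`
#' the emergency admission is placed 2-30 days before diagnosis and an
#' elective admission is inserted strictly between it and the diagnosis, so
#' the case is broad- but not narrow-EP. Deaths within 12 months occur at a
#' date uniform in (diagnosis, diagnosis + 365]; survivors are censored at
#' diagnosis + 400 days.
#'
#' @param config An [sim_config()] object.
#' @return A list with tibbles `tumours` (one row per diagnosis, including
#'   the latent `ep_true` and `broad_only_true` indicators used in
#'   parameter-recovery checks) and `admissions` (patient_id,
#'   admission_date, admission_type).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "ep_sim_config")) {
    stop_config("`config` must be created by sim_config().")
  }
  set.seed(config$seed)
  period_start <- as.Date(sprintf("%d-01-01", config$diagnosis_period[1]))
  period_end <- as.Date(sprintf("%d-12-31", config$diagnosis_period[2]))
  n_days <- as.integer(period_end - period_start)

  out_t <- vector("list", nrow(config$jurisdictions))
  out_a <- vector("list", nrow(config$jurisdictions))

  for (j in seq_len(nrow(config$jurisdictions))) {
    jur <- config$jurisdictions$name[j]
    n <- config$jurisdictions$n_patients[j]

    site <- sample(names(config$site_mix), n, TRUE, config$site_mix)
    age_group <- sample(names(config$age_mix), n, TRUE, config$age_mix)
    sex <- sample(names(config$sex_mix), n, TRUE, config$sex_mix)
    stage <- sample(names(config$stage_mix), n, TRUE, config$stage_mix)
    stage[runif(n) < config$stage_missing_prob] <- "missing"

    diagnosis_date <- period_start + sample.int(n_days + 1L, n, TRUE) - 1L
    icd10 <- vapply(site, function(s) sample(site_icd10_pool(s), 1L), "")

    covar <- tibble(site = site, age_group = age_group, sex = sex,
                    stage = stage)
    p_ep <- plogis(model_eta(config$ep_model, covar))
    ep <- runif(n) < p_ep
    broad_only <- ep & (runif(n) < config$narrow_discordance)

    p_death <- plogis(
      model_eta(config$mortality_model, covar) +
        config$mortality_model$ep_log_or * ep
    )
    dead12 <- runif(n) < p_death
    death_offset <- sample.int(365L, n, TRUE)
    death_date <- as.Date(ifelse(dead12, diagnosis_date + death_offset, NA),
                          origin = "1970-01-01")
    censor_date <- as.Date(ifelse(dead12, NA, diagnosis_date + 400L),
                           origin = "1970-01-01")

    # jurisdiction index keeps ids unique even when names share a prefix
    patient_id <- sprintf("%s%02d-%06d",
                          toupper(substr(gsub("[^A-Za-z]", "", jur), 1, 3)),
                          j, seq_len(n))

    tum <- tibble(
      patient_id = patient_id, jurisdiction = jur,
      icd10 = unname(icd10), histology = 8140L, behaviour = 3L,
      diagnosis_date = diagnosis_date,
      age_group = age_group, sex = sex, site = site, stage = stage,
      year = as.integer(format(diagnosis_date, "%Y")),
      death_date = death_date, censor_date = censor_date,
      ep_true = ep, broad_only_true = broad_only
    )

    # emergency admissions for EP cases; concordant cases may sit on the
    # window boundary (offset 0 or 30), discordant cases need room for a
    # strictly-intervening elective admission (offset >= 2)
    emerg_offset <- integer(n)
    emerg_offset[ep & !broad_only] <- sample(0:30, sum(ep & !broad_only), TRUE)
    emerg_offset[broad_only] <- sample(2:30, sum(broad_only), TRUE)

    adm_list <- list()
    if (any(ep)) {
      adm_list$emergency <- tibble(
        patient_id = patient_id[ep],
        admission_date = diagnosis_date[ep] - emerg_offset[ep],
        admission_type = "emergency"
      )
    }
    if (any(broad_only)) {
      # elective strictly between the emergency admission and diagnosis
      gap <- emerg_offset[broad_only]
      elec_offset <- vapply(gap, function(g) sample.int(g - 1L, 1L), 1L)
      adm_list$intervening <- tibble(
        patient_id = patient_id[broad_only],
        admission_date = diagnosis_date[broad_only] - elec_offset,
        admission_type = "elective"
      )
    }
    non_ep <- !ep
    noise_elec <- non_ep & (runif(n) < config$nonep_elective_prob)
    if (any(noise_elec)) {
      adm_list$noise_elective <- tibble(
        patient_id = patient_id[noise_elec],
        admission_date = diagnosis_date[noise_elec] -
          sample(0:30, sum(noise_elec), TRUE),
        admission_type = "elective"
      )
    }
    prior_emerg <- non_ep & (runif(n) < config$nonep_prior_emergency_prob)
    if (any(prior_emerg)) {
      adm_list$prior_emergency <- tibble(
        patient_id = patient_id[prior_emerg],
        admission_date = diagnosis_date[prior_emerg] -
          sample(45:365, sum(prior_emerg), TRUE),
        admission_type = "emergency"
      )
    }

    out_t[[j]] <- tum
    out_a[[j]] <- bind_rows(adm_list)
  }

  list(
    tumours = bind_rows(out_t),
    admissions = bind_rows(out_a) %>% arrange(.data$patient_id, .data$admission_date)
  )
}

#' Marginal EP probability implied by a simulation configuration
#'
#' Computes the exact marginal broad-EP probability under independent
#' covariate draws, by summing the EP-model probability over the full
#' covariate grid weighted by the mixes.
#'
#' @param config An [sim_config()] object.
#' @return A single probability.
#' @export
implied_ep_fraction <- function(config) {
  stage_levels <- c(names(config$stage_mix), "missing")
  stage_probs <- c(config$stage_mix * (1 - config$stage_missing_prob),
                   missing = config$stage_missing_prob)
  grid <- expand.grid(
    site = names(config$site_mix), age_group = names(config$age_mix),
    sex = names(config$sex_mix), stage = stage_levels,
    stringsAsFactors = FALSE
  )
  w <- config$site_mix[grid$site] * config$age_mix[grid$age_group] *
    config$sex_mix[grid$sex] * stage_probs[grid$stage]
  sum(w * plogis(model_eta(config$ep_model, grid)))
}

#' Marginal crude EP-mortality odds ratio implied by a configuration
#'
#' The crude (unadjusted) 12-month mortality odds ratio comparing EP with
#' non-EP patients that the generative model implies at the population
#' level, computed exactly over the covariate grid. Because EP risk and
#' mortality risk share covariates (site, age, stage), this marginal odds
#' ratio exceeds the conditional `ep_log_or`: the crude association is
#' confounded upwards, as in real registry data.
#'
#' @param config An [sim_config()] object.
#' @return The implied crude odds ratio (scalar).
#' @export
implied_marginal_mortality_or <- function(config) {
  stage_levels <- c(names(config$stage_mix), "missing")
  stage_probs <- c(config$stage_mix * (1 - config$stage_missing_prob),
                   missing = config$stage_missing_prob)
  grid <- expand.grid(
    site = names(config$site_mix), age_group = names(config$age_mix),
    sex = names(config$sex_mix), stage = stage_levels,
    stringsAsFactors = FALSE
  )
  w <- config$site_mix[grid$site] * config$age_mix[grid$age_group] *
    config$sex_mix[grid$sex] * stage_probs[grid$stage]
  p_ep <- plogis(model_eta(config$ep_model, grid))
  eta_m <- model_eta(config$mortality_model, grid)
  p_dead_ep <- plogis(eta_m + config$mortality_model$ep_log_or)
  p_dead_nonep <- plogis(eta_m)
  a <- sum(w * p_ep * p_dead_ep)
  b <- sum(w * p_ep * (1 - p_dead_ep))
  cc <- sum(w * (1 - p_ep) * p_dead_nonep)
  d <- sum(w * (1 - p_ep) * (1 - p_dead_nonep))
  (a * d) / (b * cc)
}

#' Generate a jurisdiction-level net-survival table (synthetic)
#'
#' Builds a test bed for the ecological regression: one row per
#' jurisdiction, with its all-site EP percentage (from a simulated cohort,
#' or supplied directly), its definition type, and a synthetic 1-year net
#' survival generated as a linear function of EP percentage plus Gaussian
#' noise. The slope is expressed per 10 percentage points of EP, matching
#' how ecological coefficients are reported.
#'
#' @param config An [sim_config()] object (used for jurisdictions and, when
#'   `ep_pct` is not supplied, to simulate the cohort; its seed governs the
#'   noise draw).
#' @param ep_slope Change in net survival (percentage points) per 10
#'   percentage-point increase in EP.
#' @param noise_sd Standard deviation of the Gaussian noise, in percentage
#'   points of net survival.
#' @param intercept Net survival at 0% EP, percentage points.
#' @param ep_pct Optional numeric vector of EP percentages (one per
#'   jurisdiction) bypassing cohort simulation.
#' @param window_days Classification window used when simulating.
#' @return Tibble: `jurisdiction`, `definition_type`, `ep_pct`,
#'   `net_survival_1yr`.
#' @export
generate_net_survival_table <- function(config, ep_slope = -4, noise_sd = 3,
                                        intercept = 75, ep_pct = NULL,
                                        window_days = 30L) {
  if (!is.finite(ep_slope)) stop_config("ep_slope must be finite.")
  jd <- config$jurisdictions
  if (is.null(ep_pct)) {
    cohort <- generate_cohort(config)
    labels <- classify_cohort(cohort$tumours, cohort$admissions,
                              window_days = window_days)
    tab <- cohort$tumours %>%
      left_join(labels, by = "patient_id") %>%
      group_by(.data$jurisdiction) %>%
      summarise(ep_pct = 100 * mean(.data$broad), .groups = "drop")
    ep_pct <- tab$ep_pct[match(jd$name, tab$jurisdiction)]
  } else {
    if (length(ep_pct) != nrow(jd)) {
      stop_config("ep_pct must have one value per jurisdiction.")
    }
    set.seed(config$seed)
  }
  tibble(
    jurisdiction = jd$name,
    definition_type = jd$definition_type,
    ep_pct = ep_pct,
    net_survival_1yr = intercept + ep_slope * ep_pct / 10 +
      rnorm(nrow(jd), 0, noise_sd)
  )
}

#' Write a simulated cohort to CSV files
#'
#' Writes `tumours.csv` and `admissions.csv` with ISO-8601 dates into `dir`.
#'
#' @param cohort List returned by [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("tumours.csv", "admissions.csv"))
  write.csv(cohort$tumours, paths[1], row.names = FALSE, na = "")
  write.csv(cohort$admissions, paths[2], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a simulated cohort from CSV files
#'
#' @param dir Directory containing `tumours.csv` and `admissions.csv`.
#' @return A list with tibbles `tumours` and `admissions`, date columns
#'   parsed as `Date`.
#' @export
read_cohort_csv <- function(dir) {
  tum <- as_tibble(read.csv(file.path(dir, "tumours.csv"),
                            stringsAsFactors = FALSE))
  adm <- as_tibble(read.csv(file.path(dir, "admissions.csv"),
                            stringsAsFactors = FALSE))
  for (col in c("diagnosis_date", "death_date", "censor_date")) {
    if (col %in% names(tum)) tum[[col]] <- as.Date(tum[[col]])
  }
  adm$admission_date <- as.Date(adm$admission_date)
  list(tumours = tum, admissions = adm)
}
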