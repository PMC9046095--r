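#' Configuration for one jurisdiction's federated run
#'
#' @param jurisdiction Jurisdiction name.
#' @param definition_type Operative EP definition, "broad" or "narrow".
#' @param window_days Classification window (days), default 30.
#' @param suppression_threshold Counts below this are masked in aggregate
#'   outputs (default 5, the usual registry disclosure floor; 0 disables,
#'   appropriate for synthetic data).
#' @param study_years Eligible diagnosis years.
#' @param horizons Mortality horizons for the association models.
#' @param seed Seed recorded in provenance (the run itself is
#'   deterministic).
#' @return A `jurisdiction_config` list.
#' @export
jurisdiction_config <- function(jurisdiction,
                                definition_type = c("broad", "narrow"),
                                window_days = 30L,
                                suppression_threshold = 5L,
                                study_years = 2012:2017,
                                horizons = "12m",
                                seed = NA_integer_) {
  definition_type <- match.arg(definition_type)
  if (window_days <= 0) stop_config("window_days must be positive.")
  if (suppression_threshold < 0) {
    stop_config("suppression_threshold must be >= 0.")
  }
  structure(
    list(
      jurisdiction = jurisdiction, definition_type = definition_type,
      window_days = as.integer(window_days),
      suppression_threshold = as.integer(suppression_threshold),
      study_years = study_years, horizons = horizons, seed = seed
    ),
    class = "jurisdiction_config"
  )
}

BUNDLE_SCHEMA_VERSION <- "1.0"

mask_small_cells <- function(summaries, threshold) {
  small <- summaries$n < threshold |
    summaries$k < threshold |
    (summaries$n - summaries$k) < threshold
  summaries %>%
    mutate(
      masked = small,
      n = if_else(small, NA_integer_, as.integer(.data$n)),
      k = if_else(small, NA_integer_, as.integer(.data$k)),
      pct = if_else(small, NA_real_, .data$pct),
      ci_low = if_else(small, NA_real_, .data$ci_low),
      ci_high = if_else(small, NA_real_, .data$ci_high)
    )
}

#' Run the full pipeline for one jurisdiction, emitting aggregates only
#'
#' Applies eligibility rules, classifies EP status under the jurisdiction's
#' operative definition, tabulates EP percentages by site, age group, sex,
#' stage and year (plus the all-patients total), fits the association
#' models, and packages everything as an aggregate bundle. No patient-level
#' rows leave this function: the bundle carries only stratum counts (with
#' small cells masked below the suppression threshold) and model estimates,
#' mirroring a federated analysis in which only group-level outputs are
#' shared centrally.
#'
#' @param tumours,admissions Patient-level input tables (see
#'   [generate_cohort()] for the schema).
#' @param config A [jurisdiction_config()].
#' @return An `aggregate_bundle` list: `jurisdiction`, `definition_type`,
#'   `window_days`, `stratum_summaries`, `estimates`, `eligibility`,
#'   `schema_version`, `provenance`.
#' @export
run_jurisdiction <- function(tumours, admissions, config) {
  if (!inherits(config, "jurisdiction_config")) {
    stop_config("`config` must be a jurisdiction_config().")
  }
  required <- c("patient_id", "icd10", "behaviour", "diagnosis_date",
                "age_group", "sex", "histology")
  missing_cols <- setdiff(required, names(tumours))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("Tumour table lacks field(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }

  elig <- apply_inclusion_criteria(tumours, study_years = config$study_years)
  included <- elig$included
  labels <- classify_cohort(included, admissions,
                            window_days = config$window_days)
  dat <- included %>%
    left_join(labels, by = "patient_id") %>%
    mutate(ep = .data[[config$definition_type]])

  strata_vars <- list("site", "age_group", "sex", "stage", "year")
  summaries <- bind_rows(
    ep_percentage_by_stratum(dat, character()) %>%
      mutate(stratum_var = "all", stratum_level = "all"),
    bind_rows(lapply(strata_vars, function(v) {
      if (!v %in% names(dat)) return(NULL)
      ep_percentage_by_stratum(dat, v) %>%
        mutate(stratum_var = v, stratum_level = as.character(.data[[v]])) %>%
        select(-all_of(v))
    }))
  ) %>%
    select("stratum_var", "stratum_level", "n", "k", "pct",
           "ci_low", "ci_high", "definition") %>%
    mask_small_cells(config$suppression_threshold)

  estimates <- run_jurisdiction_models(
    dat %>% mutate(jurisdiction = config$jurisdiction),
    horizons = config$horizons
  )

  bundle <- structure(
    list(
      jurisdiction = config$jurisdiction,
      definition_type = config$definition_type,
      window_days = config$window_days,
      stratum_summaries = summaries,
      estimates = estimates,
      eligibility = elig$report,
      schema_version = BUNDLE_SCHEMA_VERSION,
      provenance = list(
        config_hash = rlang::hash(unclass(config)),
        seed = config$seed
      )
    ),
    class = "aggregate_bundle"
  )
  assert_aggregate_only(bundle)
  bundle
}

assert_aggregate_only <- function(bundle) {
  banned <- c("patient_id", "diagnosis_date", "death_date", "censor_date")
  for (tab in list(bundle$stratum_summaries, bundle$estimates)) {
    hit <- intersect(banned, names(tab))
    if (length(hit) > 0) {
      stop_validation(sprintf(
        "Bundle contains patient-level field(s): %s",
        paste(hit, collapse = ", ")
      ))
    }
  }
  invisible(bundle)
}

#' Write an aggregate bundle to a directory
#'
#' One directory per bundle: `stratum_summaries.csv`, `estimates.csv`, and
#' `manifest.json` carrying the schema version, jurisdiction metadata,
#' eligibility report and provenance.
#'
#' @param bundle An `aggregate_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  assert_aggregate_only(bundle)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$stratum_summaries,
            file.path(dir, "stratum_summaries.csv"), row.names = FALSE,
            na = "")
  write.csv(bundle$estimates, file.path(dir, "estimates.csv"),
            row.names = FALSE, na = "")
  manifest <- list(
    schema_version = bundle$schema_version,
    jurisdiction = bundle$jurisdiction,
    definition_type = bundle$definition_type,
    window_days = bundle$window_days,
    eligibility = unclass(bundle$eligibility),
    provenance = bundle$provenance
  )
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA),
    file.path(dir, "manifest.json")
  )
  invisible(dir)
}

#' Read an aggregate bundle from a directory
#'
#' @param dir Directory written by [write_bundle()].
#' @return An `aggregate_bundle`.
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  if (!identical(manifest$schema_version, BUNDLE_SCHEMA_VERSION)) {
    stop_validation(sprintf("Unrecognised bundle schema version: %s",
                            manifest$schema_version))
  }
  summaries <- as_tibble(read.csv(file.path(dir, "stratum_summaries.csv"),
                                  stringsAsFactors = FALSE,
                                  colClasses = c(stratum_level = "character"))) %>%
    mutate(n = as.integer(.data$n), k = as.integer(.data$k))
  estimates <- as_tibble(read.csv(file.path(dir, "estimates.csv"),
                                  stringsAsFactors = FALSE))
  for (col in c("horizon", "term", "outcome", "note")) {
    if (col %in% names(estimates)) {
      v <- as.character(estimates[[col]])
      v[!is.na(v) & v == ""] <- NA_character_
      estimates[[col]] <- v
    }
  }
  structure(
    list(
      jurisdiction = manifest$jurisdiction,
      definition_type = manifest$definition_type,
      window_days = as.integer(manifest$window_days),
      stratum_summaries = summaries,
      estimates = estimates,
      eligibility = structure(manifest$eligibility,
                              class = "eligibility_report"),
      schema_version = manifest$schema_version,
      provenance = manifest$provenance
    ),
    class = "aggregate_bundle"
  )
}

#' Collate jurisdiction bundles into central tables
#'
#' Merges aggregate bundles into: a jurisdiction-by-site EP-percentage
#' matrix; a 12-month mortality table (counts by EP status plus the crude,
#' adjusted and stage-adjusted ORs); and a meta-analysis-ready estimate
#' table for the requested model. Internal consistency of each bundle
#' (site-stratum patient counts against its all-patients total) is checked
#' and reported; masked cells are excluded from collated sums and flagged.
#' Bundles classified under different windows cannot be pooled.
#'
#' @param bundles List of `aggregate_bundle` objects.
#' @param meta_model Which model's EP estimate feeds the meta table.
#' @param meta_horizon Horizon for the meta table.
#' @return List: `ep_matrix` (tibble, jurisdictions x sites),
#'   `mortality_table`, `meta_estimates`, `consistency`.
#' @export
collate <- function(bundles, meta_model = "mortality_stage_adjusted",
                    meta_horizon = "12m") {
  if (length(bundles) < 1) stop_validation("Need at least one bundle.")
  versions <- unique(vapply(bundles, function(b) b$schema_version, ""))
  if (length(versions) != 1) {
    stop_validation("Incompatible bundle schema versions.")
  }
  windows <- unique(vapply(bundles, function(b) b$window_days, 1L))
  if (length(windows) != 1) {
    stop_validation(sprintf(
      "Refusing to pool bundles with mixed windows (%s days).",
      paste(windows, collapse = ", ")
    ))
  }

  site_rows <- bind_rows(lapply(bundles, function(b) {
    b$stratum_summaries %>%
      filter(.data$stratum_var == "site") %>%
      mutate(jurisdiction = b$jurisdiction,
             definition_type = b$definition_type)
  }))
  ep_matrix <- site_rows %>%
    select("jurisdiction", "definition_type",
           site = "stratum_level", "pct") %>%
    tidyr::pivot_wider(names_from = "site", values_from = "pct")

  consistency <- bind_rows(lapply(bundles, function(b) {
    s <- b$stratum_summaries
    total <- s$n[s$stratum_var == "all"]
    site_n <- s %>% filter(.data$stratum_var == "site")
    any_masked <- any(site_n$masked) || any(s$masked[s$stratum_var == "all"])
    tibble(
      jurisdiction = b$jurisdiction,
      total_n = if (length(total) == 1) total else NA_integer_,
      site_sum_n = sum(site_n$n, na.rm = TRUE),
      has_masked_cells = any_masked,
      consistent = any_masked ||
        (length(total) == 1 && !is.na(total) &&
           sum(site_n$n, na.rm = TRUE) == total)
    )
  }))

  mortality_table <- bind_rows(lapply(bundles, function(b) {
    est <- b$estimates %>%
      filter(.data$horizon %in% meta_horizon | is.na(.data$horizon))
    pick <- function(model) {
      row <- est %>%
        filter(.data$model == !!model,
               .data$term == "ep_statusTRUE" | !.data$converged)
      if (nrow(row) == 0) return(tibble(or = NA_real_, ci_low = NA_real_,
                                        ci_high = NA_real_))
      row %>% select("or", "ci_low", "ci_high") %>% utils::head(1)
    }
    tibble(
      jurisdiction = b$jurisdiction,
      definition_type = b$definition_type,
      crude = pick("mortality_crude"),
      adjusted = pick("mortality_adjusted"),
      stage_adjusted = pick("mortality_stage_adjusted")
    ) %>% tidyr::unpack(c("crude", "adjusted", "stage_adjusted"),
                        names_sep = "_")
  }))

  meta_estimates <- bind_rows(lapply(bundles, function(b) {
    b$estimates %>%
      filter(.data$model == meta_model,
             .data$term == "ep_statusTRUE",
             .data$horizon %in% meta_horizon,
             .data$converged) %>%
      mutate(jurisdiction = b$jurisdiction,
             definition_type = b$definition_type) %>%
      select("jurisdiction", "definition_type", "log_or", "se")
  }))

  list(
    ep_matrix = ep_matrix,
    mortality_table = mortality_table,
    meta_estimates = meta_estimates,
    consistency = consistency
  )
}
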