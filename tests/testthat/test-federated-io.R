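make_bundle <- function(name = "Arden", n = 5000, seed = 201,
                        definition = "broad", threshold = 0L,
                        window = 30L) {
  cfg <- sim_config(
    jurisdictions = tibble::tibble(
      name = name, definition_type = definition, n_patients = n
    ),
    seed = seed
  )
  co <- generate_cohort(cfg)
  run_jurisdiction(
    co$tumours, co$admissions,
    jurisdiction_config(name, definition, window_days = window,
                        suppression_threshold = threshold, seed = seed)
  )
}

test_that("a jurisdiction run yields a complete aggregate bundle", {
  b <- make_bundle(n = 5000)
  site_rows <- b$stratum_summaries %>%
    dplyr::filter(stratum_var == "site")
  expect_setequal(site_rows$stratum_level, ep_sites())
  mort <- b$estimates %>%
    dplyr::filter(grepl("mortality", model), term == "ep_statusTRUE")
  expect_gte(nrow(mort), 1)
  expect_equal(b$schema_version, "1.0")
  expect_false(is.null(b$provenance$config_hash))
})

test_that("bundles never carry patient-level fields", {
  b <- make_bundle(n = 1000, seed = 207)
  for (tab in list(b$stratum_summaries, b$estimates)) {
    expect_false(any(c("patient_id", "diagnosis_date", "death_date") %in%
                       names(tab)))
  }
  fake <- b
  fake$estimates$patient_id <- "oops"
  expect_error(write_bundle(fake, withr::local_tempdir()),
               class = "eproutes_validation_error")
})

test_that("bundle serialisation round-trips byte-identically", {
  b <- make_bundle(n = 2000, seed = 211)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b, d1)
  b2 <- read_bundle(d1)
  write_bundle(b2, d2)
  for (f in c("stratum_summaries.csv", "estimates.csv", "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_equal(b2$stratum_summaries$k, b$stratum_summaries$k)
})

test_that("small cells are masked at the suppression threshold", {
  b <- make_bundle(n = 400, seed = 213, threshold = 20L)
  s <- b$stratum_summaries
  expect_true(any(s$masked))
  expect_true(all(is.na(s$n[s$masked])))
  expect_true(all(is.na(s$pct[s$masked])))
  unmasked <- s[!s$masked, ]
  expect_true(all(unmasked$n >= 20 & unmasked$k >= 20 &
                    unmasked$n - unmasked$k >= 20))
})

test_that("collation merges bundles and is order-invariant", {
  bundles <- list(
    make_bundle("Arden", 4000, 217, "narrow"),
    make_bundle("Brightwater", 4000, 219, "broad"),
    make_bundle("Caldera", 4000, 223, "broad")
  )
  cen <- collate(bundles)
  expect_equal(nrow(cen$ep_matrix), 3)
  expect_true(all(ep_sites() %in% names(cen$ep_matrix)))
  expect_true(all(cen$consistency$consistent))
  expect_equal(nrow(cen$meta_estimates), 3)

  cen_rev <- collate(rev(bundles))
  expect_equal(
    dplyr::arrange(cen$ep_matrix, jurisdiction),
    dplyr::arrange(cen_rev$ep_matrix, jurisdiction)
  )
  expect_equal(
    dplyr::arrange(cen$meta_estimates, jurisdiction),
    dplyr::arrange(cen_rev$meta_estimates, jurisdiction)
  )
})

test_that("an injected stratum-sum fault is flagged at collation", {
  b <- make_bundle(n = 3000, seed = 227)
  b$stratum_summaries$n[b$stratum_summaries$stratum_var == "all"] <-
    b$stratum_summaries$n[b$stratum_summaries$stratum_var == "all"] + 5L
  cen <- collate(list(b))
  expect_false(cen$consistency$consistent[1])
})

test_that("bundles with mixed windows refuse to pool", {
  b30 <- make_bundle("Arden", 1000, 229, window = 30L)
  b60 <- make_bundle("Brightwater", 1000, 231, window = 60L)
  expect_error(collate(list(b30, b60)),
               class = "eproutes_validation_error")
})

test_that("end-to-end pipeline equals stage-by-stage composition", {
  cfg <- sim_config(
    jurisdictions = tibble::tibble(
      name = c("Arden", "Brightwater", "Caldera"),
      definition_type = c("narrow", "broad", "broad"),
      n_patients = 4000L
    ),
    seed = 233
  )
  co <- generate_cohort(cfg)

  bundles <- lapply(seq_len(3), function(j) {
    jur <- cfg$jurisdictions$name[j]
    tum <- co$tumours %>% dplyr::filter(jurisdiction == jur)
    adm <- co$admissions %>% dplyr::semi_join(tum, by = "patient_id")
    run_jurisdiction(
      tum, adm,
      jurisdiction_config(jur, cfg$jurisdictions$definition_type[j],
                          suppression_threshold = 0L)
    )
  })
  cen <- collate(bundles)
  pooled_federated <- pool_random_effects(cen$meta_estimates,
                                          moderator = TRUE)

  # stagewise: classify + model directly on the pooled patient-level table
  elig <- apply_inclusion_criteria(co$tumours)
  labels <- classify_cohort(elig$included, co$admissions)
  dat <- elig$included %>%
    dplyr::left_join(labels, by = "patient_id") %>%
    dplyr::left_join(cfg$jurisdictions %>%
                       dplyr::select(jurisdiction = name, definition_type),
                     by = "jurisdiction") %>%
    dplyr::mutate(ep = dplyr::if_else(definition_type == "narrow",
                                      narrow, broad))
  direct <- run_jurisdiction_models(dat, horizons = "12m") %>%
    dplyr::filter(model == "mortality_stage_adjusted",
                  term == "ep_statusTRUE") %>%
    dplyr::left_join(cfg$jurisdictions %>%
                       dplyr::select(jurisdiction = name, definition_type),
                     by = "jurisdiction") %>%
    dplyr::select(jurisdiction, definition_type, log_or, se)
  pooled_direct <- pool_random_effects(direct, moderator = TRUE)

  expect_equal(
    dplyr::arrange(cen$meta_estimates, jurisdiction) %>% as.data.frame(),
    dplyr::arrange(direct, jurisdiction) %>% as.data.frame(),
    tolerance = 1e-10
  )
  expect_equal(pooled_federated$pooled$or, pooled_direct$pooled$or,
               tolerance = 1e-10)
})
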