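adm_tbl <- function(dates, types) {
  tibble::tibble(
    admission_date = as.Date(dates), admission_type = types
  )
}

d0 <- as.Date("2015-06-01")

test_that("broad definition honours the inclusive 30-day window", {
  # emergency exactly window_days before diagnosis qualifies
  expect_true(classify_broad(d0 + 30, adm_tbl(d0, "emergency"))$broad)
  # one day outside does not
  expect_false(classify_broad(d0 + 31, adm_tbl(d0, "emergency"))$broad)
  # same-day admission and diagnosis counts
  expect_true(classify_broad(d0, adm_tbl(d0, "emergency"))$broad)
  # elective admissions alone never qualify
  expect_false(classify_broad(d0 + 10, adm_tbl(d0, "elective"))$broad)
  # admissions after diagnosis never qualify
  expect_false(classify_broad(d0 - 1, adm_tbl(d0, "emergency"))$broad)
  expect_false(classify_broad(d0, adm_tbl(character(0), character(0)))$broad)
})

test_that("anchor is the latest qualifying emergency admission", {
  res <- classify_broad(
    d0 + 20, adm_tbl(c(d0, d0 + 15), c("emergency", "emergency"))
  )
  expect_equal(res$anchor, d0 + 15)
})

test_that("narrow definition requires no intervening elective admission", {
  # elective strictly between emergency and diagnosis breaks narrow
  adm <- adm_tbl(c(d0, d0 + 10), c("emergency", "elective"))
  expect_true(classify_broad(d0 + 20, adm)$broad)
  expect_false(classify_narrow(d0 + 20, adm))
  # elective before the emergency admission is not intervening
  adm2 <- adm_tbl(c(d0, d0 - 5), c("emergency", "elective"))
  expect_true(classify_narrow(d0 + 20, adm2))
  # a later emergency can rescue narrow status
  adm3 <- adm_tbl(c(d0, d0 + 15, d0 + 5),
                  c("emergency", "emergency", "elective"))
  expect_true(classify_narrow(d0 + 20, adm3))
  # same-day elective (with the emergency, or with diagnosis) is ignored
  adm4 <- adm_tbl(c(d0, d0), c("emergency", "elective"))
  expect_true(classify_narrow(d0 + 20, adm4))
  adm5 <- adm_tbl(c(d0, d0 + 20), c("emergency", "elective"))
  expect_true(classify_narrow(d0 + 20, adm5))
})

test_that("classification matches a brute-force oracle on all small histories", {
  # exhaustive sweep: up to 3 admissions over a coarse offset grid, both
  # types, checked against the enumerate-all-anchors oracle
  offsets <- c(-5, 0, 5, 15, 30, 31, 40)
  types <- c("emergency", "elective")
  singles <- expand.grid(o1 = offsets, t1 = types,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(singles))) {
    adm <- adm_tbl(d0 - singles$o1[i], singles$t1[i])
    expect_equal(classify_broad(d0, adm)$broad, oracle_broad(d0, adm)$broad)
    expect_equal(classify_narrow(d0, adm), oracle_narrow(d0, adm))
  }
  pairs <- expand.grid(o1 = offsets, o2 = offsets, t1 = types, t2 = types,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    adm <- adm_tbl(d0 - c(pairs$o1[i], pairs$o2[i]),
                   c(pairs$t1[i], pairs$t2[i]))
    expect_equal(classify_broad(d0, adm)$broad, oracle_broad(d0, adm)$broad)
    expect_equal(classify_broad(d0, adm)$anchor, oracle_broad(d0, adm)$anchor)
    expect_equal(classify_narrow(d0, adm), oracle_narrow(d0, adm))
  }
  set.seed(404)
  triple_off <- matrix(sample(offsets, 3 * 200, TRUE), ncol = 3)
  triple_type <- matrix(sample(types, 3 * 200, TRUE), ncol = 3)
  for (i in 1:200) {
    adm <- adm_tbl(d0 - triple_off[i, ], triple_type[i, ])
    expect_equal(classify_narrow(d0, adm), oracle_narrow(d0, adm))
  }
})

test_that("vectorised cohort classification equals per-patient classification", {
  set.seed(42)
  tumours <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:300),
    diagnosis_date = as.Date("2015-06-01") + sample(0:100, 300, TRUE)
  )
  admissions <- dplyr::bind_rows(lapply(1:300, function(i) {
    h <- random_admission_history()
    h$admission_date <- tumours$diagnosis_date[i] + sample(-45:10, nrow(h),
                                                           TRUE)
    h$patient_id <- tumours$patient_id[i]
    h
  }))
  labels <- classify_cohort(tumours, admissions)
  for (i in seq_len(nrow(tumours))) {
    adm <- admissions[admissions$patient_id == tumours$patient_id[i], ]
    expect_equal(labels$broad[i],
                 oracle_broad(tumours$diagnosis_date[i], adm)$broad)
    expect_equal(labels$narrow[i],
                 oracle_narrow(tumours$diagnosis_date[i], adm))
  }
})

test_that("narrow implies broad and windows are monotone", {
  set.seed(99)
  tumours <- tibble::tibble(
    patient_id = sprintf("P%04d", 1:500),
    diagnosis_date = as.Date("2016-01-01") + sample(0:300, 500, TRUE)
  )
  admissions <- dplyr::bind_rows(lapply(seq_len(500), function(i) {
    h <- random_admission_history()
    h$patient_id <- tumours$patient_id[i]
    h$admission_date <- tumours$diagnosis_date[i] + sample(-70:5, nrow(h),
                                                           TRUE)
    h
  }))
  l30 <- classify_cohort(tumours, admissions, window_days = 30)
  l60 <- classify_cohort(tumours, admissions, window_days = 60)
  expect_true(all(l30$narrow <= l30$broad))
  expect_true(all(l60$narrow <= l60$broad))
  expect_true(all(l30$broad <= l60$broad)) # enlarging never removes a label

  # translation invariance: shifting every date leaves labels unchanged
  shift <- 1234L
  l30s <- classify_cohort(
    dplyr::mutate(tumours, diagnosis_date = diagnosis_date + shift),
    dplyr::mutate(admissions, admission_date = admission_date + shift),
    window_days = 30
  )
  expect_identical(l30$broad, l30s$broad)
  expect_identical(l30$narrow, l30s$narrow)
})

test_that("admissions for unknown patients warn and are ignored", {
  tumours <- tibble::tibble(patient_id = "A", diagnosis_date = d0)
  admissions <- adm_tbl(c(d0 - 5, d0 - 5), c("emergency", "emergency"))
  admissions$patient_id <- c("A", "GHOST")
  expect_warning(labels <- classify_cohort(tumours, admissions), "unknown")
  expect_true(labels$broad)
  expect_equal(nrow(labels), 1)
})

test_that("labels are invariant to admission diagnosis-code content", {
  # classification is contextual: extra columns on admissions are inert
  adm <- adm_tbl(d0 - 3, "emergency")
  adm$diagnosis_code <- "R10"
  expect_true(classify_broad(d0, adm)$broad)
})
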