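# Shared fixtures and independent oracles for the test suite.

two_jurisdiction_config <- function(n = 4000, seed = 101, ...) {
  sim_config(
    jurisdictions = tibble::tibble(
      name = c("Arden", "Brightwater"),
      definition_type = c("narrow", "broad"),
      n_patients = c(n, n)
    ),
    seed = seed,
    ...
  )
}

# brute-force EP oracles: literal restatement of the definitions, kept
# independent of the vectorised implementation
oracle_broad <- function(diagnosis_date, adm, window = 30) {
  off <- as.numeric(diagnosis_date - adm$admission_date)
  q <- adm$admission_type == "emergency" & off >= 0 & off <= window
  if (!any(q)) return(list(broad = FALSE, anchor = as.Date(NA)))
  list(broad = TRUE, anchor = max(adm$admission_date[q]))
}

oracle_narrow <- function(diagnosis_date, adm, window = 30) {
  off <- as.numeric(diagnosis_date - adm$admission_date)
  anchors <- adm$admission_date[adm$admission_type == "emergency" &
                                  off >= 0 & off <= window]
  electives <- adm$admission_date[adm$admission_type == "elective"]
  for (a in anchors) {
    if (!any(electives > a & electives < diagnosis_date)) return(TRUE)
  }
  FALSE
}

random_admission_history <- function(n_max = 5) {
  n <- sample(0:n_max, 1)
  tibble::tibble(
    admission_date = as.Date("2015-06-01") + sample(-60:20, n, replace = TRUE),
    admission_type = sample(c("emergency", "elective"), n, replace = TRUE)
  )
}

# expand a 2x2 EP-by-death table into patient-level records
expand_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    ep = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
    death_12m = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d))
  )
}

# DerSimonian-Laird pooling from first principles (textbook arithmetic)
dl_pool <- function(yi, sei) {
  wi <- 1 / sei^2
  ybar <- sum(wi * yi) / sum(wi)
  Q <- sum(wi * (yi - ybar)^2)
  df <- length(yi) - 1
  C <- sum(wi) - sum(wi^2) / sum(wi)
  tau2 <- max(0, (Q - df) / C)
  wstar <- 1 / (sei^2 + tau2)
  list(
    tau2 = tau2, Q = Q,
    pooled = sum(wstar * yi) / sum(wstar),
    se = sqrt(1 / sum(wstar))
  )
}
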