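#' Classify one diagnosis as a broad emergency presentation
#'
#' A diagnosis is a broad emergency presentation (EP) when at least one
#' emergency hospital admission occurred within `window_days` days before
#' the diagnosis, both bounds inclusive: an admission on the diagnosis day
#' itself qualifies (offset 0), as does one exactly `window_days` days
#' before. Only inpatient admissions flagged emergency count; elective
#' admissions and (by construction of the input data) emergency-department
#' attendances without admission do not. The classification is contextual:
#' it uses only dates and admission type, never admission diagnosis codes.
#'
#' @param diagnosis_date A `Date` scalar.
#' @param admissions Tibble/data frame of this patient's admissions with
#'   columns `admission_date` (`Date`) and `admission_type`
#'   ("emergency"/"elective"). May have zero rows.
#' @param window_days Positive integer window, default 30.
#' @return A list: `broad` (logical) and `anchor` (the latest qualifying
#'   emergency admission date, or `NA` when not broad-EP).
#' @export
classify_broad <- function(diagnosis_date, admissions, window_days = 30L) {
  if (window_days <= 0) stop_config("window_days must be positive.")
  adm <- as_tibble(admissions)
  if (nrow(adm) == 0) return(list(broad = FALSE, anchor = as.Date(NA)))
  offset <- as.numeric(diagnosis_date - adm$admission_date)
  qualifying <- adm$admission_type == "emergency" &
    offset >= 0 & offset <= window_days
  if (!any(qualifying)) return(list(broad = FALSE, anchor = as.Date(NA)))
  list(broad = TRUE, anchor = max(adm$admission_date[qualifying]))
}

#' Classify one diagnosis as a narrow emergency presentation
#'
#' The narrow definition additionally requires that some qualifying
#' emergency admission has no elective admission dated strictly between it
#' and the diagnosis. Same-day events do not "intervene": an elective
#' admission on the day of the emergency admission, or on the diagnosis
#' day, is ignored (day-granularity data cannot order same-day events).
#' Narrow-EP implies broad-EP.
#'
#' @inheritParams classify_broad
#' @return Logical scalar.
#' @export
classify_narrow <- function(diagnosis_date, admissions, window_days = 30L) {
  b <- classify_broad(diagnosis_date, admissions, window_days)
  if (!b$broad) return(FALSE)
  adm <- as_tibble(admissions)
  elective <- adm$admission_date[adm$admission_type == "elective"]
  # the latest qualifying emergency admission is the best candidate: any
  # elective that intervenes for it intervenes for all earlier anchors too
  anchor <- b$anchor
  !any(elective > anchor & elective < diagnosis_date)
}

#' Classify a whole cohort under both EP definitions
#'
#' Vectorised equivalent of applying [classify_broad()] and
#' [classify_narrow()] per patient. Admissions referencing a patient absent
#' from the tumour table are ignored with a warning.
#'
#' @param tumours Tumour tibble with `patient_id` and `diagnosis_date`.
#' @param admissions Admission tibble with `patient_id`, `admission_date`,
#'   `admission_type`.
#' @param window_days Positive integer window, default 30.
#' @return Tibble with one row per tumour record: `patient_id`, `broad`,
#'   `narrow`, `anchor_admission_date`, `window_days`.
#' @export
classify_cohort <- function(tumours, admissions, window_days = 30L) {
  if (window_days <= 0) stop_config("window_days must be positive.")
  tumours <- as_tibble(tumours)
  admissions <- as_tibble(admissions)

  unknown <- anti_join(admissions, tumours, by = "patient_id")
  if (nrow(unknown) > 0) {
    warn(sprintf(
      "%d admission(s) reference unknown patients and were ignored.",
      nrow(unknown)
    ))
  }

  joined <- inner_join(
    admissions,
    tumours %>% select("patient_id", "diagnosis_date"),
    by = "patient_id"
  ) %>%
    mutate(offset = as.numeric(.data$diagnosis_date - .data$admission_date))

  per_patient <- joined %>%
    group_by(.data$patient_id) %>%
    summarise(
      anchor_num = suppressWarnings(max(
        as.numeric(.data$admission_date)[
          .data$admission_type == "emergency" &
            .data$offset >= 0 & .data$offset <= window_days
        ]
      )),
      elective_num = suppressWarnings(max(
        as.numeric(.data$admission_date)[
          .data$admission_type == "elective" & .data$offset > 0
        ]
      )),
      .groups = "drop"
    ) %>%
    mutate(
      anchor_admission_date = as.Date(
        ifelse(is.finite(.data$anchor_num), .data$anchor_num, NA),
        origin = "1970-01-01"
      ),
      last_elective_before = as.Date(
        ifelse(is.finite(.data$elective_num), .data$elective_num, NA),
        origin = "1970-01-01"
      )
    )

  tumours %>%
    select("patient_id") %>%
    left_join(per_patient, by = "patient_id") %>%
    mutate(
      broad = !is.na(.data$anchor_admission_date),
      narrow = .data$broad &
        (is.na(.data$last_elective_before) |
           .data$last_elective_before <= .data$anchor_admission_date),
      window_days = as.integer(window_days)
    ) %>%
    select("patient_id", "broad", "narrow", "anchor_admission_date",
           "window_days")
}
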