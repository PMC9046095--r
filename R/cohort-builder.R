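#' Map ICD-10 topography codes to the eight analysed cancer sites
#'
#' Sites and code ranges: oesophageal (C15), stomach (C16), colon (C18-C19),
#' rectal (C20), liver (C22), pancreatic (C25), lung (C34) and ovarian,
#' including peritoneal and fallopian-tube cancers (C48.1, C48.2, C56,
#' C57.0). Both dotted ("C48.1") and undotted ("C481") forms are accepted;
#' three-character codes match whole categories, while the
#' peritoneal/fallopian-tube members of the ovarian grouping require
#' four-character precision (so "C48.3", or a bare "C48", map to no site).
#'
#' @param icd10 Character vector of ICD-10 topography codes.
#' @param strict If `TRUE` (default) a syntactically malformed code raises a
#'   validation error; if `FALSE`, malformed codes yield `NA` (used by
#'   [apply_inclusion_criteria()], which counts them as unmappable).
#' @return Character vector of site names, `NA` where the code falls in
#'   none of the listed ranges.
#' @examples
#' classify_cancer_site(c("C18", "C56", "C25.9", "C48.3"))
#' @export
classify_cancer_site <- function(icd10, strict = TRUE) {
  code <- toupper(gsub(".", "", as.character(icd10), fixed = TRUE))
  ok <- grepl("^[A-Z][0-9]{2}[0-9]?$", code)
  ok[is.na(code)] <- FALSE
  if (strict && any(!ok)) {
    bad <- unique(icd10[!ok])
    stop_validation(sprintf(
      "Malformed ICD-10 code(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  code3 <- substr(code, 1, 3)
  site <- rep(NA_character_, length(code))
  site[code3 == "C15"] <- "oesophageal"
  site[code3 == "C16"] <- "stomach"
  site[code3 %in% c("C18", "C19")] <- "colon"
  site[code3 == "C20"] <- "rectal"
  site[code3 == "C22"] <- "liver"
  site[code3 == "C25"] <- "pancreatic"
  site[code3 == "C34"] <- "lung"
  site[code3 == "C56" | code %in% c("C481", "C482", "C570")] <- "ovarian"
  site[!ok] <- NA_character_
  site
}

BORDERLINE_OVARIAN_MORPHOLOGY <- c(8442L, 8451L, 8462L, 8472L, 8473L)

band_age <- function(age) {
  out <- rep(NA_character_, length(age))
  out[age >= 15 & age <= 64] <- "15-64"
  out[age >= 65 & age <= 74] <- "65-74"
  out[age >= 75 & age <= 84] <- "75-84"
  out[age >= 85 & age <= 99] <- "85+"
  out
}

#' Apply cohort eligibility rules to raw tumour records
#'
#' Keeps records with a mappable cancer site, age 15-99 years (evaluated on
#' the grouped age bands; a raw `age` column, when present, is banded
#' first), invasive behaviour (code 3), diagnosis year inside the study
#' period, and - for ovarian cancer - a morphology outside the borderline
#' set (ICD-O-3 codes 8442, 8451, 8462, 8472, 8473). Records missing a
#' diagnosis date are excluded as record-level validation failures.
#'
#' Exclusion reasons are tallied under a fixed precedence (missing date >
#' unmappable site > age > behaviour > borderline morphology > year), which
#' affects only the reason counts, never the included set.
#'
#' @param tumours Tumour tibble (see [generate_cohort()] for the schema).
#' @param study_years Integer vector of eligible diagnosis years.
#' @return A list: `included` (tibble with a `site` column added) and
#'   `report`, an `eligibility_report` with `n_input`, `n_excluded`,
#'   `n_included` and an `exclusion_reasons` count table.
#' @export
apply_inclusion_criteria <- function(tumours, study_years = 2012:2017) {
  tumours <- as_tibble(tumours)
  n_input <- nrow(tumours)
  site <- classify_cancer_site(tumours$icd10, strict = FALSE)

  if ("age" %in% names(tumours)) {
    age_group <- band_age(tumours$age)
  } else {
    age_group <- tumours$age_group
    age_group[!age_group %in% EP_AGE_GROUPS] <- NA_character_
  }

  year <- if ("year" %in% names(tumours)) {
    tumours$year
  } else {
    as.integer(format(tumours$diagnosis_date, "%Y"))
  }

  reason <- rep(NA_character_, n_input)
  fail <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  fail(is.na(tumours$diagnosis_date), "missing_diagnosis_date")
  fail(is.na(site), "unmappable_site")
  fail(is.na(age_group), "age_out_of_range")
  fail(tumours$behaviour != 3L, "non_invasive_behaviour")
  fail(site == "ovarian" &
         tumours$histology %in% BORDERLINE_OVARIAN_MORPHOLOGY,
       "borderline_ovarian")
  fail(!year %in% study_years, "year_out_of_period")

  keep <- is.na(reason)
  included <- tumours[keep, , drop = FALSE]
  included$site <- site[keep]
  included$age_group <- age_group[keep]

  counts <- table(reason[!keep])
  report <- structure(
    list(
      n_input = n_input,
      n_excluded = sum(!keep),
      n_included = sum(keep),
      exclusion_reasons = as.list(setNames(as.integer(counts), names(counts)))
    ),
    class = "eligibility_report"
  )
  list(included = as_tibble(included), report = report)
}

#' @method print eligibility_report
#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("Eligibility: %d input, %d included, %d excluded\n",
              x$n_input, x$n_included, x$n_excluded))
  for (r in names(x$exclusion_reasons)) {
    cat(sprintf("  %-24s %d\n", r, x$exclusion_reasons[[r]]))
  }
  invisible(x)
}

#' Serialise an eligibility report to JSON
#'
#' @param report An `eligibility_report`.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
eligibility_report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
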