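#' Build a table of maternal profiles
#'
#' A maternal profile holds the history and characteristics that drive the
#' prior risk and the expected-median adjustments. All arguments are
#' recycled to a common length, so a single call can build a whole cohort's
#' worth of profiles.
#'
#' @param age Years.
#' @param weight Kg.
#' @param height Cm.
#' @param parity One of `"nulliparous"`, `"parous_no_pe"`,
#'   `"parous_previous_pe"`.
#' @param chronic_hypertension,diabetes,sle_aps,smoker Logicals.
#' @param conception `"spontaneous"` or `"assisted"`.
#' @param ethnicity Ethnicity tag; the defaults emulate a South Asian
#'   screening population.
#'
#' @return A tibble with one row per woman; `bmi` (kg/m^2) is derived from
#'   weight and height.
#' @export
maternal_profile <- function(age = 30, weight = 63, height = 160,
                             parity = "nulliparous",
                             chronic_hypertension = FALSE, diabetes = FALSE,
                             sle_aps = FALSE, conception = "spontaneous",
                             smoker = FALSE, ethnicity = "south_asian") {
  out <- tibble::tibble(
    age = as.numeric(age),
    weight = as.numeric(weight),
    height = as.numeric(height),
    parity = as.character(parity),
    chronic_hypertension = as.logical(chronic_hypertension),
    diabetes = as.logical(diabetes),
    sle_aps = as.logical(sle_aps),
    conception = as.character(conception),
    smoker = as.logical(smoker),
    ethnicity = as.character(ethnicity)
  )
  out$bmi <- out$weight / (out$height / 100)^2
  validate_profiles(out)
}

PARITY_LEVELS <- c("nulliparous", "parous_no_pe", "parous_previous_pe")
CONCEPTION_LEVELS <- c("spontaneous", "assisted")

validate_profiles <- function(profiles) {
  need <- c(
    "age", "weight", "height", "parity", "chronic_hypertension",
    "diabetes", "sle_aps", "conception", "smoker"
  )
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Profile table is missing column(s): ", toString(missing_cols)),
      class = "pescreen_schema_error"
    )
  }
  if (any(profiles$age <= 0 | profiles$weight <= 0 | profiles$height <= 0, na.rm = TRUE)) {
    abort("age, weight and height must be strictly positive.",
          class = "pescreen_domain_error")
  }
  if (!all(profiles$parity %in% PARITY_LEVELS)) {
    abort(
      paste0("`parity` must be one of: ", toString(PARITY_LEVELS)),
      class = "pescreen_domain_error"
    )
  }
  if (!all(profiles$conception %in% CONCEPTION_LEVELS)) {
    abort(
      paste0("`conception` must be one of: ", toString(CONCEPTION_LEVELS)),
      class = "pescreen_domain_error"
    )
  }
  if (!("bmi" %in% names(profiles))) {
    profiles$bmi <- profiles$weight / (profiles$height / 100)^2
  }
  profiles
}
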