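#' Cohort CSV schema
#'
#' On disk a cohort is a comma-delimited, period-decimal, UTF-8 CSV with
#' "NA" as the missing token and gestational ages in days; in memory
#' gestational ages are weeks. Required columns: `id`, `age_years`,
#' `weight_kg`, `height_cm`, `parity_class`, `chronic_htn`, `diabetes`,
#' `sle_aps`, `conception`, `smoker`, `ga_screen_days`, `outcome`,
#' `ga_delivery_days`, `aspirin`, plus per marker either `<marker>_mom`
#' (precomputed MoM) or a raw-measurement column (`map_raw_mmhg`,
#' `utapi_raw`, `pappa_raw`, `plgf_raw`) converted through the
#' expected-median models at read time.
#'
#' @name cohort_schema
NULL

COHORT_REQUIRED_COLS <- c(
  "id", "age_years", "weight_kg", "height_cm", "parity_class", "chronic_htn",
  "diabetes", "sle_aps", "conception", "smoker", "ga_screen_days",
  "outcome", "ga_delivery_days", "aspirin"
)
RAW_COLS <- c(map = "map_raw_mmhg", utapi = "utapi_raw",
              pappa = "pappa_raw", plgf = "plgf_raw")
OUTCOME_LEVELS <- c("no_pe", "term_pe", "preterm_pe")

#' Read a cohort CSV
#'
#' Parses and validates a cohort file (see [cohort_schema]). Rows that
#' violate record invariants (non-positive sizes, unknown levels, MoMs not
#' positive, or an outcome label inconsistent with the delivery
#' gestational age at the preterm cutoff) are collected into a rejects
#' report -- attached as `attr(result, "rejects")` with file line numbers
#' and reasons -- and dropped, never silently. A missing required column
#' is a fatal schema error.
#'
#' @param path CSV file path.
#' @param median_models Named list of [expected_median_model()]s, used when
#'   a marker arrives as a raw measurement instead of a MoM.
#' @param preterm_cutoff Weeks; used for the outcome/GA consistency check.
#' @return A cohort tibble (gestational ages in weeks) with a `rejects`
#'   attribute.
#' @export
read_cohort <- function(path, median_models = default_median_models(),
                        preterm_cutoff = 37) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "pescreen_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                         na = "NA", progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file is missing required column(s): ",
                 toString(missing_cols)),
          class = "pescreen_schema_error")
  }
  for (mk in PE_MARKERS) {
    if (!mom_col(mk) %in% names(raw) && !RAW_COLS[[mk]] %in% names(raw)) {
      abort(paste0("Marker '", mk, "' needs either column ", mom_col(mk),
                   " or ", RAW_COLS[[mk]]),
            class = "pescreen_schema_error")
    }
  }

  cohort <- tibble::tibble(
    id = raw$id,
    age = as.numeric(raw$age_years),
    weight = as.numeric(raw$weight_kg),
    height = as.numeric(raw$height_cm),
    parity = as.character(raw$parity_class),
    chronic_hypertension = as.logical(raw$chronic_htn),
    diabetes = as.logical(raw$diabetes),
    sle_aps = as.logical(raw$sle_aps),
    conception = as.character(raw$conception),
    smoker = as.logical(raw$smoker),
    ga_screen = as.numeric(raw$ga_screen_days) / 7,
    outcome = as.character(raw$outcome),
    ga_delivery = as.numeric(raw$ga_delivery_days) / 7,
    aspirin = as.logical(raw$aspirin)
  )
  cohort$bmi <- cohort$weight / (cohort$height / 100)^2

  reasons <- rep("", nrow(cohort))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reasons[bad] <<- ifelse(reasons[bad] == "", why, paste0(reasons[bad], "; ", why))
  }
  flag(!(cohort$age > 0 & cohort$weight > 0 & cohort$height > 0),
       "non-positive age/weight/height")
  flag(!(cohort$parity %in% PARITY_LEVELS), "unknown parity class")
  flag(!(cohort$conception %in% CONCEPTION_LEVELS), "unknown conception mode")
  flag(!(cohort$outcome %in% OUTCOME_LEVELS), "unknown outcome")
  flag(is.na(cohort$ga_delivery) | is.na(cohort$ga_screen), "missing gestational age")
  flag(cohort$outcome == "preterm_pe" & cohort$ga_delivery >= preterm_cutoff,
       sprintf("preterm_pe requires delivery before %g weeks", preterm_cutoff))
  flag(cohort$outcome == "term_pe" & cohort$ga_delivery < preterm_cutoff,
       sprintf("term_pe requires delivery at or after %g weeks", preterm_cutoff))

  for (mk in PE_MARKERS) {
    col <- mom_col(mk)
    if (col %in% names(raw)) {
      cohort[[col]] <- as.numeric(raw[[col]])
    } else {
      rv <- as.numeric(raw[[RAW_COLS[[mk]]]])
      model <- median_models[[mk]]
      ok <- is.finite(rv) & rv > 0 & is.finite(cohort$ga_screen) &
        cohort$ga_screen >= model$valid_ga_range[1] &
        cohort$ga_screen <= model$valid_ga_range[2]
      mom <- rep(NA_real_, nrow(cohort))
      if (any(ok)) {
        mom[ok] <- compute_mom(rv[ok], cohort$ga_screen[ok], cohort[ok, ], model)
      }
      cohort[[col]] <- mom
      flag(!ok, paste0("invalid raw ", mk, " measurement"))
    }
    flag(!(is.finite(cohort[[col]]) & cohort[[col]] > 0),
         paste0("non-positive ", mk, " MoM"))
  }

  bad <- reasons != ""
  rejects <- tibble::tibble(
    line = which(bad) + 1L,  # header is line 1
    id = cohort$id[bad],
    reason = reasons[bad]
  )
  if (nrow(rejects) > 0) {
    warn(sprintf("%d row(s) rejected while reading %s; see attr(x, 'rejects').",
                 nrow(rejects), path))
  }
  out <- cohort[!bad, ]
  attr(out, "rejects") <- rejects
  out
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: gestational ages go to disk in days
#' (fractional days are kept so a write/read round trip is lossless).
#' Only schema columns are written.
#'
#' @param cohort Cohort tibble (weeks in memory).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- tibble::tibble(
    id = cohort$id,
    age_years = cohort$age,
    weight_kg = cohort$weight,
    height_cm = cohort$height,
    parity_class = cohort$parity,
    chronic_htn = cohort$chronic_hypertension,
    diabetes = cohort$diabetes,
    sle_aps = cohort$sle_aps,
    conception = cohort$conception,
    smoker = cohort$smoker,
    ga_screen_days = cohort$ga_screen * 7
  )
  for (mk in PE_MARKERS) {
    out[[mom_col(mk)]] <- cohort[[mom_col(mk)]]
  }
  out$outcome <- cohort$outcome
  out$ga_delivery_days <- cohort$ga_delivery * 7
  out$aspirin <- cohort$aspirin
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
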