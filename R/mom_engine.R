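#' Expected-median model for a biomarker
#'
#' Converts a raw biomarker measurement into a multiple of the expected
#' median (MoM): the expected log10 median is a polynomial in gestational
#' age plus additive log10 adjustments for maternal covariates, and
#' `MoM = raw / 10^expected`. Adjustment terms are either shifts attached
#' to logical/level covariates or slopes on continuous covariates around a
#' reference value.
#'
#' @param marker Marker name (one of `r toString(PE_MARKERS)`).
#' @param ga_coefficients Numeric vector `c(b0, b1, b2, b3)` (higher terms
#'   optional, degree <= 3): expected log10 median = `b0 + b1*ga + ...`.
#' @param covariate_adjustments List of terms, each a list with `term` (a
#'   profile column) and either `shift` (applied when the column is `TRUE`
#'   or equals `level`) plus optional `level`, or `slope` and `ref` for
#'   continuous columns (`slope * (x - ref)`).
#' @param valid_ga_range Length-2 numeric, weeks.
#' @return An object of class `pe_median_model`.
#' @export
expected_median_model <- function(marker, ga_coefficients,
                                  covariate_adjustments = list(),
                                  valid_ga_range = c(8, 14)) {
  stopifnot(marker %in% PE_MARKERS, length(ga_coefficients) <= 4)
  structure(
    list(
      marker = marker,
      ga_coefficients = as.numeric(ga_coefficients),
      covariate_adjustments = covariate_adjustments,
      valid_ga_range = as.numeric(valid_ga_range)
    ),
    class = "pe_median_model"
  )
}

#' Synthetic default expected-median models
#'
#' Stand-in expected-median models for the four markers, with plausible
#' first-trimester levels and covariate adjustments (the screening
#' software's internal regressions are proprietary). Only used when raw
#' measurements rather than precomputed MoMs are supplied.
#'
#' @return Named list of [expected_median_model()] objects.
#' @export
default_median_models <- function() {
  list(
    # MAP ~ 85 mmHg, nearly flat in GA, higher with weight
    map = expected_median_model(
      "map", c(log10(85), 0.0005),
      list(list(term = "weight", slope = 0.0012, ref = 63))
    ),
    # UtAPI ~ 1.8 falling with GA
    utapi = expected_median_model(
      "utapi", c(log10(1.8) + 12 * 0.012, -0.012),
      list(list(term = "weight", slope = -0.0008, ref = 63))
    ),
    # PAPP-A rising steeply across the first trimester (IU/L)
    pappa = expected_median_model(
      "pappa", c(-0.3, 0.08),
      list(
        list(term = "weight", slope = -0.004, ref = 63),
        list(term = "smoker", shift = -0.08),
        list(term = "conception", level = "assisted", shift = -0.06),
        list(term = "diabetes", shift = -0.04)
      )
    ),
    # PlGF rising with GA (pg/mL)
    plgf = expected_median_model(
      "plgf", c(1.0, 0.045),
      list(
        list(term = "weight", slope = -0.003, ref = 63),
        list(term = "smoker", shift = 0.05),
        list(term = "conception", level = "assisted", shift = -0.03)
      )
    )
  )
}

#' Convert a raw biomarker value to a MoM
#'
#' @param raw_value Raw measurement in marker units (must be positive).
#' @param ga Gestational age at measurement (weeks), inside the model's
#'   valid range.
#' @param profile A profile table ([maternal_profile()]); recycled against
#'   `raw_value`/`ga` if one row.
#' @param model An [expected_median_model()].
#' @return Numeric vector of MoM values.
#' @export
compute_mom <- function(raw_value, ga, profile, model) {
  stopifnot(inherits(model, "pe_median_model"))
  if (any(!is.finite(raw_value) | raw_value <= 0)) {
    abort("Raw biomarker values must be positive.", class = "pescreen_domain_error")
  }
  if (any(ga < model$valid_ga_range[1] | ga > model$valid_ga_range[2])) {
    abort(
      sprintf("Gestational age outside the model's valid range [%g, %g] weeks.",
              model$valid_ga_range[1], model$valid_ga_range[2]),
      class = "pescreen_range_error"
    )
  }
  profile <- validate_profiles(profile)
  log10_median <- as.numeric(
    cbind(1, ga, ga^2, ga^3)[, seq_along(model$ga_coefficients), drop = FALSE] %*%
      model$ga_coefficients
  )
  for (adj in model$covariate_adjustments) {
    x <- profile[[adj$term]]
    if (is.null(x)) {
      abort(paste0("Adjustment refers to unknown profile column: ", adj$term),
            class = "pescreen_config_error")
    }
    if (!is.null(adj$slope)) {
      log10_median <- log10_median + adj$slope * (as.numeric(x) - adj$ref)
    } else {
      on <- if (!is.null(adj$level)) x == adj$level else as.logical(x)
      log10_median <- log10_median + adj$shift * on
    }
  }
  raw_value / 10^log10_median
}

#' One-sample t-test of log10 MoMs against zero
#'
#' Tests whether a log10 MoM distribution (in unaffected pregnancies)
#' deviates from the expected mean of zero. Either pass the vector of
#' log10 MoM values, or summary statistics (`mean`, `sd`, `n`).
#'
#' @param log10_moms Numeric vector of log10 MoM values (or `NULL` when
#'   using the summary form).
#' @param mean,sd,n Summary-statistic form.
#' @return A one-row tibble: `n`, `mean_log10_mom`, `sd_log10_mom`,
#'   `t_statistic`, `df`, `p_value`, `implied_median` (`10^mean`).
#' @export
one_sample_log_mom_test <- function(log10_moms = NULL, mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(log10_moms)) {
    if (length(log10_moms) < 2 || any(!is.finite(log10_moms))) {
      abort("Need at least two finite log10 MoM values.", class = "pescreen_domain_error")
    }
    if (stats::sd(log10_moms) == 0) {
      abort("Zero variance: the t-statistic is undefined.", class = "pescreen_degenerate_error")
    }
    tt <- t.test(log10_moms, mu = 0)
    m <- base::mean(log10_moms)
    s <- stats::sd(log10_moms)
    n <- length(log10_moms)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    stopifnot(!is.null(mean), !is.null(sd), !is.null(n))
    if (n < 2 || sd <= 0) {
      abort("Summary form needs n >= 2 and sd > 0.", class = "pescreen_degenerate_error")
    }
    m <- mean
    s <- sd
    tstat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  tibble::tibble(
    n = as.integer(n),
    mean_log10_mom = m,
    sd_log10_mom = s,
    t_statistic = tstat,
    df = as.integer(n - 1),
    p_value = p,
    implied_median = 10^m
  )
}

#' Re-center a MoM distribution
#'
#' If the one-sample t-test flags a significant deviation of the log10 MoM
#' mean from zero (`p_value < alpha`), every MoM is divided by the
#' empirical median of the input so the distribution re-centers on 1 MoM.
#' Deviations whose median already lies inside the clinical-irrelevance
#' band are left uncorrected even when statistically significant (a mean
#' can be significantly non-zero at large n while the median sits at 0.99).
#'
#' @param moms Positive numeric vector of MoM values.
#' @param p_value Two-sided p-value from [one_sample_log_mom_test()] on the
#'   corresponding log10 MoMs.
#' @param alpha Significance level (default 0.05).
#' @param band Length-2 numeric: medians inside `[band[1], band[2]]` are not
#'   considered clinically significant deviations (default `c(0.98, 1.02)`).
#' @param marker Optional marker label carried into the report.
#' @return A list: `moms` (re-centered or unchanged) and `report`, a
#'   one-row tibble (`marker`, `n`, `mean_log10_mom`, `sd_log10_mom`,
#'   `t_statistic`, `p_value`, `median_mom`, `recentering_factor`,
#'   `applied`).
#' @export
recenter <- function(moms, p_value, alpha = 0.05, band = c(0.98, 1.02),
                     marker = NA_character_) {
  if (length(moms) == 0) {
    abort("Cannot re-center an empty MoM vector.", class = "pescreen_domain_error")
  }
  if (any(!is.finite(moms) | moms <= 0)) {
    abort("All MoM values must be positive.", class = "pescreen_domain_error")
  }
  med <- median(moms)
  lm10 <- log10(moms)
  apply_it <- p_value < alpha && (med < band[1] || med > band[2])
  factor <- if (apply_it) med else 1
  report <- tibble::tibble(
    marker = marker,
    n = length(moms),
    mean_log10_mom = mean(lm10),
    sd_log10_mom = stats::sd(lm10),
    t_statistic = if (length(moms) > 1 && stats::sd(lm10) > 0) {
      mean(lm10) / (stats::sd(lm10) / sqrt(length(moms)))
    } else NA_real_,
    p_value = p_value,
    median_mom = med,
    recentering_factor = factor,
    applied = apply_it
  )
  list(moms = moms / factor, report = report)
}

#' MoM quality control over a cohort
#'
#' For each marker: run the one-sample t-test of the log10 MoMs in
#' unaffected (no-PE) pregnancies against zero, derive the re-centering
#' factor from the unaffected median, and (when the deviation is both
#' statistically and clinically significant) divide every woman's MoM by
#' it. Mirrors the screening QC convention of testing the mean of the
#' log10 MoMs but correcting by the median of the MoMs; the report carries
#' both statistics so any discrepancy stays visible.
#'
#' @param cohort Cohort tibble with `<marker>_mom` columns and an `outcome`
#'   column (`"no_pe"`, `"term_pe"`, `"preterm_pe"`).
#' @param markers Markers to QC.
#' @param alpha,band See [recenter()].
#' @return An object of class `pe_qc`: list with `cohort` (re-centered) and
#'   `report` (tibble, one row per marker). `tidy()` returns the report.
#' @export
mom_qc <- function(cohort, markers = PE_MARKERS, alpha = 0.05,
                   band = c(0.98, 1.02)) {
  stopifnot("outcome" %in% names(cohort))
  reports <- list()
  for (mk in markers) {
    col <- mom_col(mk)
    if (!col %in% names(cohort)) {
      abort(paste0("Cohort is missing MoM column: ", col),
            class = "pescreen_schema_error")
    }
    unaff <- cohort[[col]][cohort$outcome == "no_pe"]
    test <- one_sample_log_mom_test(log10(unaff))
    rc <- recenter(unaff, test$p_value, alpha = alpha, band = band, marker = mk)
    cohort[[col]] <- cohort[[col]] / rc$report$recentering_factor
    reports[[mk]] <- rc$report
  }
  structure(
    list(cohort = cohort, report = dplyr::bind_rows(reports),
         alpha = alpha, band = band),
    class = "pe_qc"
  )
}

#' @export
print.pe_qc <- function(x, ...) {
  cat("<pe_qc> MoM distribution QC on", sum(x$report$n > 0), "markers\n")
  print(as.data.frame(dplyr::mutate(
    x$report,
    dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 4))
  )))
  invisible(x)
}

#' @rdname mom_qc
#' @param x A `pe_qc` object.
#' @param ... Unused.
#' @export
tidy.pe_qc <- function(x, ...) x$report
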