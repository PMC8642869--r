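#' Prior distribution of gestational age at delivery with PE
#'
#' In the competing-risks screening model every pregnancy has a notional
#' gestational age `g` (weeks) at which delivery with preeclampsia would
#' occur; `g` beyond the delivery horizon means PE never happens. The prior
#' on `g` is Gaussian with a maternal-history-dependent mean and a common
#' SD: each history factor adds a configured shift (weeks) to the mean, and
#' continuous covariates contribute linearly around their reference values.
#'
#' @param profiles A profile table from [maternal_profile()] (one or more rows).
#' @param params A [risk_model_parameters()] object.
#' @return A tibble with columns `mean` and `sd` (weeks), one row per profile.
#' @export
prior_distribution <- function(profiles, params) {
  profiles <- validate_profiles(profiles)
  validate_risk_params(params)
  tibble::tibble(
    mean = prior_mean(profiles, params),
    sd = params$prior_sd
  )
}

prior_mean <- function(profiles, params) {
  e <- params$prior_effects
  eff <- function(key) e[[key]] %||% 0
  params$prior_baseline_mean +
    eff("chronic_hypertension") * profiles$chronic_hypertension +
    eff("diabetes") * profiles$diabetes +
    eff("sle_aps") * profiles$sle_aps +
    eff("conception_assisted") * (profiles$conception == "assisted") +
    eff("smoker") * profiles$smoker +
    eff("parous_no_pe") * (profiles$parity == "parous_no_pe") +
    eff("parous_previous_pe") * (profiles$parity == "parous_previous_pe") +
    eff("age_slope") * (profiles$age - eff("age_ref")) +
    eff("weight_slope") * (profiles$weight - eff("weight_ref")) +
    eff("height_slope") * (profiles$height - eff("height_ref"))
}

#' Prior (history-only) risk of preterm PE
#'
#' The Gaussian prior mass of `g` below the preterm cutoff:
#' `pnorm((preterm_cutoff - mean) / sd)`.
#'
#' @inheritParams prior_distribution
#' @return Numeric vector of probabilities, one per profile.
#' @export
prior_preterm_risk <- function(profiles, params) {
  pr <- prior_distribution(profiles, params)
  pnorm((params$preterm_cutoff - pr$mean) / pr$sd)
}

# Broken-stick conditional means of the log10 MoMs at gestational ages g:
# intercept + slope * max(0, knot - g) per marker. Rows: g, cols: markers.
marker_mean_matrix <- function(g, markers, params) {
  m <- vapply(markers, function(mk) {
    params$marker_intercepts[[mk]] +
      params$marker_slopes[[mk]] * pmax(0, params$marker_knots[[mk]] - g)
  }, numeric(length(g)))
  matrix(m, nrow = length(g), ncol = length(markers),
         dimnames = list(NULL, markers))
}

marker_subcov <- function(markers, params) {
  cov <- params$marker_covariance[markers, markers, drop = FALSE]
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    abort("Covariance sub-matrix for the requested markers is not positive definite.",
          class = "pescreen_config_error")
  }
  cov
}

#' Marker log-likelihood at a gestational age
#'
#' Multivariate Gaussian log-density of the observed log10 MoMs given that
#' delivery with PE would occur at gestational age `g`, using the
#' broken-stick mean model and the covariance sub-matrix of the available
#' markers (missing markers are marginalized out, not imputed).
#'
#' @param log10_moms Named numeric vector of log10 MoM values; names are the
#'   available markers (a subset of `r toString(PE_MARKERS)`).
#' @param g Numeric vector of gestational ages (weeks).
#' @param params A [risk_model_parameters()] object.
#' @return Numeric vector of log-densities, one per element of `g`.
#' @export
marker_log_likelihood <- function(log10_moms, g, params) {
  validate_risk_params(params)
  markers <- names(log10_moms)
  if (length(markers) == 0) {
    abort("`log10_moms` must name at least one marker.", class = "pescreen_domain_error")
  }
  if (!all(markers %in% PE_MARKERS)) {
    abort(
      paste0("Unknown marker(s): ", toString(setdiff(markers, PE_MARKERS))),
      class = "pescreen_config_error"
    )
  }
  if (any(!is.finite(log10_moms))) {
    abort("All log10 MoM values must be finite.", class = "pescreen_domain_error")
  }
  cov <- marker_subcov(markers, params)
  prec <- solve(cov)
  mu <- marker_mean_matrix(g, markers, params)
  resid <- sweep(-mu, 2, log10_moms, FUN = "+")  # x - mu(g), rows over g
  quad <- rowSums((resid %*% prec) * resid)
  as.numeric(-0.5 * (length(markers) * log(2 * pi) + determinant(cov)$modulus + quad))
}

# Trapezoid weights for the full grid and for the sub-interval
# [g_min, cutoff]; the cutoff need not land on a grid point (the last
# partial segment uses linear interpolation of the integrand).
trapezoid_weights <- function(g, cutoff = NULL) {
  n <- length(g)
  h <- g[2] - g[1]
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  if (is.null(cutoff)) {
    return(w)
  }
  wb <- numeric(n)
  k <- findInterval(cutoff, g)
  if (k >= 1) {
    wb[seq_len(k)] <- h
    wb[1] <- h / 2
    wb[k] <- wb[k] - h / 2
    if (g[k] < cutoff && k < n) {
      a <- (cutoff - g[k]) / h
      wb[k] <- wb[k] + a * h / 2 * (2 - a)
      wb[k + 1] <- wb[k + 1] + a^2 * h / 2
    }
  }
  wb
}

#' Posterior risk of preterm PE given history and biomarkers
#'
#' Bayes update of the history prior on `g` by the biomarker likelihood,
#' integrated numerically over the gestational-age grid. The risk is the
#' normalized posterior mass below the preterm cutoff; prior mass at and
#' beyond the no-PE boundary (the competing "PE never occurs" outcome)
#' stays in the normalization.
#'
#' @param profile A one-row profile table from [maternal_profile()].
#' @param log10_moms Named numeric vector of log10 MoM values (may be empty:
#'   the result then equals the prior risk up to quadrature error).
#' @param params A [risk_model_parameters()] object.
#' @return A one-row tibble: `preterm_pe_probability`, `one_in_n` (display
#'   string), `prior_probability`, `markers_used`.
#' @export
posterior_preterm_risk <- function(profile, log10_moms = numeric(0), params) {
  stopifnot(nrow(profile) == 1)
  markers <- names(log10_moms)
  cohort <- profile
  for (mk in markers) cohort[[mom_col(mk)]] <- 10^log10_moms[[mk]]
  risk <- compute_risks(cohort, params, markers = markers %||% character(0))$risk
  tibble::tibble(
    preterm_pe_probability = risk,
    one_in_n = risk_to_one_in_n(risk),
    prior_probability = prior_preterm_risk(profile, params),
    markers_used = list(markers %||% character(0))
  )
}

#' Normalized posterior density of `g`
#'
#' The posterior density of the gestational age at delivery with PE over
#' the integration grid, normalized so its trapezoid integral is 1. Mainly
#' useful for plotting and for quadrature checks.
#'
#' @inheritParams posterior_preterm_risk
#' @return A tibble with columns `g` (weeks) and `density`.
#' @export
posterior_density <- function(profile, log10_moms = numeric(0), params) {
  stopifnot(nrow(profile) == 1)
  validate_risk_params(params)
  profile <- validate_profiles(profile)
  g <- g_grid(params)
  logw <- dnorm(g, mean = prior_mean(profile, params), sd = params$prior_sd, log = TRUE)
  if (length(log10_moms) > 0) {
    logw <- logw + marker_log_likelihood(log10_moms, g, params)
  }
  w <- exp(logw - max(logw))
  total <- sum(w * trapezoid_weights(g))
  if (!is.finite(total) || total <= 0) {
    abort("Posterior normalizer below machine tolerance (grid too narrow or extreme MoMs).",
          class = "pescreen_numeric_error")
  }
  tibble::tibble(g = g, density = w / total)
}

#' Compute posterior preterm-PE risks for a cohort
#'
#' Vectorized Bayes update for every woman in a cohort table. The cohort
#' must carry the profile columns (see [maternal_profile()]) and, for each
#' requested marker, a `<marker>_mom` column on the MoM scale (log10 is
#' taken internally).
#'
#' @param cohort A cohort tibble.
#' @param params A [risk_model_parameters()] object.
#' @param markers Character vector of markers to use (subset of
#'   `r toString(PE_MARKERS)`); `character(0)` gives the history-only risk.
#' @param risk_col Name of the output risk column.
#' @param chunk_size Number of women processed per block (memory control).
#' @return `cohort` with the risk column added (overwritten if present).
#' @export
compute_risks <- function(cohort, params, markers = PE_MARKERS,
                          risk_col = "risk", chunk_size = 2000) {
  validate_risk_params(params)
  cohort_valid <- validate_profiles(cohort)
  markers <- as.character(markers)
  if (!all(markers %in% PE_MARKERS)) {
    abort(
      paste0("Unknown marker(s): ", toString(setdiff(markers, PE_MARKERS))),
      class = "pescreen_config_error"
    )
  }
  n <- nrow(cohort)
  if (n == 0) {
    cohort[[risk_col]] <- numeric(0)
    return(cohort)
  }

  g <- g_grid(params)
  mu <- prior_mean(cohort_valid, params)
  sdg <- params$prior_sd
  m <- length(markers)

  # Beyond every knot (and the cutoff) the marker means are flat, so the
  # likelihood is constant in g there: the grid is only walked up to that
  # point and the remaining prior mass is added as a single Gaussian tail
  # term (trapezoid and exact tail agree far below quadrature tolerance).
  flat_from <- max(c(params$marker_knots[markers], params$preterm_cutoff))
  s_idx <- if (flat_from >= params$g_grid_max) {
    length(g)
  } else {
    which(g >= flat_from)[1]
  }
  ga <- g[seq_len(s_idx)]
  wt <- trapezoid_weights(ga)
  wb <- trapezoid_weights(ga, cutoff = params$preterm_cutoff)
  has_tail <- s_idx < length(g)

  if (m > 0) {
    cols <- mom_col(markers)
    missing_cols <- setdiff(cols, names(cohort))
    if (length(missing_cols) > 0) {
      abort(
        paste0("Cohort is missing MoM column(s): ", toString(missing_cols)),
        class = "pescreen_schema_error"
      )
    }
    X <- log10(as.matrix(cohort[, cols, drop = FALSE]))
    colnames(X) <- markers
    if (any(!is.finite(X))) {
      abort("MoM values must be positive and finite for all requested markers.",
            class = "pescreen_domain_error")
    }
    prec <- solve(marker_subcov(markers, params))
    Mg <- marker_mean_matrix(ga, markers, params)
    PMt <- prec %*% t(Mg)                  # m x |active grid|
    qg <- rowSums((Mg %*% prec) * Mg)
    # constant (reduced) log-likelihood in the flat region
    m0 <- params$marker_intercepts[markers]
    logc <- as.numeric(X %*% (prec %*% m0)) - 0.5 * sum(m0 * (prec %*% m0))
  } else {
    logc <- numeric(n)
  }

  risk <- numeric(n)
  starts <- seq(1, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1, n)
    # log posterior weight up to per-woman constants (cancel in the ratio)
    logw <- -0.5 * outer(mu[idx], ga, function(m_i, g_j) ((g_j - m_i) / sdg)^2)
    if (m > 0) {
      logw <- logw + X[idx, , drop = FALSE] %*% PMt -
        matrix(0.5 * qg, nrow = length(idx), ncol = length(ga), byrow = TRUE)
    }
    rowmax <- logw[cbind(seq_along(idx), max.col(logw, ties.method = "first"))]
    w <- exp(logw - rowmax)
    total <- as.numeric(w %*% wt)
    if (has_tail) {
      # prior mass on [g_s, g_max], on the same (sd * sqrt(2*pi)) scale as
      # the reduced prior term used in logw
      tail_mass <- (pnorm(params$g_grid_max, mu[idx], sdg) -
                    pnorm(ga[s_idx], mu[idx], sdg)) * sdg * sqrt(2 * pi)
      total <- total + exp(logc[idx] - rowmax) * tail_mass
    }
    if (any(!is.finite(total) | total <= 0)) {
      abort("Posterior normalizer below machine tolerance (grid too narrow or extreme MoMs).",
            class = "pescreen_numeric_error")
    }
    risk[idx] <- as.numeric(w %*% wb) / total
  }
  cohort[[risk_col]] <- pmin(pmax(risk, 0), 1)
  cohort
}

#' Display a probability as a "1:N" risk
#'
#' `N = round(1/p)` with round-half-away-from-zero and `N >= 1`. This is a
#' display convention only: risk classification must use the raw
#' probability, never the rounded display.
#'
#' @param p Probabilities in (0, 1].
#' @return Character vector like `"1:100"`.
#' @export
risk_to_one_in_n <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("`p` must lie in (0, 1].", class = "pescreen_domain_error")
  }
  sprintf("1:%d", pmax(1L, as.integer(floor(1 / p + 0.5))))
}

# Accepts 100, "1:100", "1 in 100" and returns N.
parse_threshold <- function(threshold) {
  if (is.numeric(threshold)) {
    n <- threshold
  } else {
    n <- suppressWarnings(as.numeric(gsub("^\\s*1\\s*(:|in)\\s*", "",
                                          as.character(threshold))))
  }
  if (is.na(n) || n < 1) {
    abort("Risk threshold must be numeric N or a string like '1:100'.",
          class = "pescreen_config_error")
  }
  n
}
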