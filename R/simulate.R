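#' Specification for a synthetic screened cohort
#'
#' Defines the population a [simulate_cohort()] call will draw: marginal
#' distributions of the maternal characteristics, the risk-model
#' parameters realized by the generator, population-level multiplicative
#' MoM miscentering, and the aspirin policy. The defaults emulate a South
#' Asian first-trimester screening population of 1863 women with preterm-PE
#' incidence near 1.34% and total-PE incidence near 3.17%, biochemical MoM
#' medians miscentered at 0.86 (PAPP-A) and 0.87 (PlGF), biophysical
#' medians at 0.99, and 17.4% aspirin uptake among screen-positive women
#' with a 60% preterm-PE risk reduction.
#'
#' @param n Number of women.
#' @param seed Integer seed (mandatory; the whole draw is reproducible).
#' @param age_mean,age_sd,age_range Age distribution (years), Gaussian
#'   truncated to `age_range`.
#' @param weight_mean,weight_sd,weight_range Weight (kg), truncated Gaussian.
#' @param height_mean,height_sd,height_range Height (cm), truncated Gaussian.
#' @param p_chronic_hypertension,p_diabetes,p_sle_aps,p_assisted,p_smoker
#'   Prevalences in `[0, 1]`.
#' @param parity_props Named proportions over
#'   `r toString(PARITY_LEVELS)` (summing to 1).
#' @param ga_screen_range Gestational age at screening (weeks), uniform.
#' @param mom_shift Named per-marker multiplicative miscentering factors
#'   applied population-wide to the generated MoMs.
#' @param aspirin_uptake Fraction of screen-positive women who take aspirin.
#' @param aspirin_effect Probability that aspirin prevents (or delays past
#'   the preterm cutoff) a would-be preterm-PE case.
#' @param aspirin_relabel What a prevented case becomes: `"term_pe"`
#'   (delivery redrawn between the cutoff and the no-PE boundary) or
#'   `"no_pe"`.
#' @param params Risk-model parameters the generator realizes
#'   ([default_risk_params()] if omitted).
#' @return An object of class `pe_cohort_spec`.
#' @export
cohort_spec <- function(n = 1863,
                        seed,
                        age_mean = 30.9, age_sd = 4.03, age_range = c(18, 45),
                        weight_mean = 63.1, weight_sd = 10.9, weight_range = c(35, 120),
                        height_mean = 159.5, height_sd = 5.5, height_range = c(140, 180),
                        p_chronic_hypertension = 30 / 1863,
                        p_diabetes = 53 / 1863,
                        p_sle_aps = 6 / 1863,
                        p_assisted = 97 / 1863,
                        p_smoker = 0,
                        parity_props = c(nulliparous = 1122 / 1863,
                                         parous_no_pe = 710 / 1863,
                                         parous_previous_pe = 31 / 1863),
                        ga_screen_range = c(11, 13 + 6 / 7),
                        mom_shift = c(map = 0.99, utapi = 0.99,
                                      pappa = 0.86, plgf = 0.87),
                        aspirin_uptake = 75 / 431,
                        aspirin_effect = 0.6,
                        aspirin_relabel = c("term_pe", "no_pe"),
                        params = default_risk_params()) {
  if (missing(seed)) {
    abort("`seed` is mandatory in a cohort spec.", class = "pescreen_config_error")
  }
  probs <- c(p_chronic_hypertension, p_diabetes, p_sle_aps, p_assisted, p_smoker,
             aspirin_uptake, aspirin_effect, parity_props)
  if (any(probs < 0 | probs > 1) || aspirin_effect >= 1) {
    abort("Prevalences/fractions must lie in [0, 1] and aspirin_effect in [0, 1).",
          class = "pescreen_config_error")
  }
  if (abs(sum(parity_props) - 1) > 1e-8 ||
      !identical(sort(names(parity_props)), sort(PARITY_LEVELS))) {
    abort("`parity_props` must be named over the parity classes and sum to 1.",
          class = "pescreen_config_error")
  }
  if (n < 0) abort("`n` must be non-negative.", class = "pescreen_config_error")
  shift <- unlist(mom_shift)
  if (!all(PE_MARKERS %in% names(shift)) || any(shift <= 0)) {
    abort("`mom_shift` must be positive and named over all four markers.",
          class = "pescreen_config_error")
  }
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed),
      age = c(age_mean, age_sd, age_range),
      weight = c(weight_mean, weight_sd, weight_range),
      height = c(height_mean, height_sd, height_range),
      p_chronic_hypertension = p_chronic_hypertension,
      p_diabetes = p_diabetes, p_sle_aps = p_sle_aps,
      p_assisted = p_assisted, p_smoker = p_smoker,
      parity_props = parity_props[PARITY_LEVELS],
      ga_screen_range = ga_screen_range,
      mom_shift = shift[PE_MARKERS],
      aspirin_uptake = aspirin_uptake,
      aspirin_effect = aspirin_effect,
      aspirin_relabel = match.arg(aspirin_relabel),
      params = validate_risk_params(params)
    ),
    class = "pe_cohort_spec"
  )
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' Simulate a screened cohort
#'
#' Draws, per woman: a maternal profile from the spec's marginal
#' distributions; the latent gestational age `g` at delivery-with-PE from
#' the history prior; the outcome (`preterm_pe` if `g` is below the
#' preterm cutoff, `term_pe` between cutoff and no-PE boundary, `no_pe`
#' beyond it); and log10 MoMs from the marker likelihood at `g` (no-PE
#' women draw from the zero-mean unaffected distribution). Population
#' miscentering (`mom_shift`) multiplies the generated MoMs; the unshifted
#' values are kept in `<marker>_mom_true` columns for ground-truth checks.
#' The draw is fully determined by `spec$seed`.
#'
#' Aspirin is not assigned here: prophylaxis targets screen-positive women,
#' so risks must be computed and classified first; see [apply_aspirin()].
#'
#' @param spec A [cohort_spec()].
#' @return A cohort tibble (one row per woman) with profile columns,
#'   `ga_screen`, `<marker>_mom` / `<marker>_mom_true`, `outcome`,
#'   `counterfactual_outcome`, `ga_delivery` (weeks) and `aspirin`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "pe_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  params <- spec$params

  profiles <- maternal_profile(
    age = rnorm_trunc(n, spec$age[1], spec$age[2], spec$age[3], spec$age[4]),
    weight = rnorm_trunc(n, spec$weight[1], spec$weight[2], spec$weight[3], spec$weight[4]),
    height = rnorm_trunc(n, spec$height[1], spec$height[2], spec$height[3], spec$height[4]),
    parity = sample(PARITY_LEVELS, n, replace = TRUE, prob = spec$parity_props),
    chronic_hypertension = runif(n) < spec$p_chronic_hypertension,
    diabetes = runif(n) < spec$p_diabetes,
    sle_aps = runif(n) < spec$p_sle_aps,
    conception = ifelse(runif(n) < spec$p_assisted, "assisted", "spontaneous"),
    smoker = runif(n) < spec$p_smoker
  )
  if (n == 0) {
    profiles <- maternal_profile()[0, ]
  }

  mu <- prior_mean(profiles, params)
  g <- rnorm(n, mu, params$prior_sd)
  outcome <- dplyr::case_when(
    g < params$preterm_cutoff ~ "preterm_pe",
    g < params$no_pe_boundary ~ "term_pe",
    TRUE ~ "no_pe"
  )
  ga_delivery <- ifelse(
    outcome == "no_pe",
    rnorm_trunc(n, 39.3, 1.5, 30, 43),
    pmax(g, params$g_grid_min)
  )

  # log10 MoMs: broken-stick mean at g for PE cases, zero mean for no-PE
  means <- marker_mean_matrix(g, PE_MARKERS, params)
  means[outcome == "no_pe", ] <- rep(params$marker_intercepts, each = sum(outcome == "no_pe"))
  noise <- matrix(rnorm(n * length(PE_MARKERS)), nrow = n,
                  ncol = length(PE_MARKERS)) %*%
    chol(params$marker_covariance)
  log10_moms <- means + noise
  mom_true <- 10^log10_moms
  mom_obs <- sweep(mom_true, 2, spec$mom_shift, `*`)

  cohort <- dplyr::bind_cols(
    tibble::tibble(id = seq_len(n)),
    profiles,
    tibble::tibble(ga_screen = runif(n, spec$ga_screen_range[1], spec$ga_screen_range[2]))
  )
  for (i in seq_along(PE_MARKERS)) {
    cohort[[mom_col(PE_MARKERS[i])]] <- mom_obs[, i]
    cohort[[paste0(mom_col(PE_MARKERS[i]), "_true")]] <- mom_true[, i]
  }
  cohort$outcome <- outcome
  cohort$counterfactual_outcome <- outcome
  cohort$ga_delivery <- ga_delivery
  cohort$aspirin <- FALSE
  cohort
}

#' Assign prophylactic aspirin and realize its effect
#'
#' Run after screening classification: assigns aspirin to a fraction of
#' high-risk women and, for each taker who would have developed preterm
#' PE, prevents (or delays past the preterm cutoff) the case with the
#' configured probability, independent of dose. The pre-treatment outcome
#' is preserved in `counterfactual_outcome`; the observed `outcome` and
#' `ga_delivery` are updated for prevented cases.
#'
#' @param cohort Cohort tibble with a logical `high_risk` column already set.
#' @param uptake Fraction of high-risk women who take aspirin, in `[0, 1]`.
#' @param effect Preterm-PE risk reduction probability, in `[0, 1)`.
#' @param relabel `"term_pe"` (delivery redrawn uniformly between cutoff and
#'   no-PE boundary) or `"no_pe"`.
#' @param params Risk-model parameters (for the cutoff and boundary).
#' @param seed Optional integer seed for this step.
#' @return The cohort with `aspirin`, `outcome`, `counterfactual_outcome`
#'   and `ga_delivery` updated.
#' @export
apply_aspirin <- function(cohort, uptake = 75 / 431, effect = 0.6,
                          relabel = c("term_pe", "no_pe"),
                          params = default_risk_params(), seed = NULL) {
  relabel <- match.arg(relabel)
  if (uptake < 0 || uptake > 1) {
    abort("`uptake` must lie in [0, 1].", class = "pescreen_config_error")
  }
  if (effect < 0 || effect >= 1) {
    abort("`effect` must lie in [0, 1).", class = "pescreen_config_error")
  }
  if (!"high_risk" %in% names(cohort)) {
    abort("Run classification first: `high_risk` column is required.",
          class = "pescreen_schema_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (!"counterfactual_outcome" %in% names(cohort)) {
    cohort$counterfactual_outcome <- cohort$outcome
  }
  hr <- which(cohort$high_risk)
  takers <- hr[runif(length(hr)) < uptake]
  cohort$aspirin <- FALSE
  cohort$aspirin[takers] <- TRUE

  would_be <- takers[cohort$outcome[takers] == "preterm_pe"]
  prevented <- would_be[runif(length(would_be)) < effect]
  if (length(prevented) > 0) {
    cohort$outcome[prevented] <- relabel
    cohort$ga_delivery[prevented] <- if (relabel == "term_pe") {
      runif(length(prevented), params$preterm_cutoff, params$no_pe_boundary)
    } else {
      rnorm_trunc(length(prevented), 39.3, 1.5, params$no_pe_boundary, 43)
    }
  }
  cohort
}
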