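#' Competing-risks model parameters
#'
#' Container for every coefficient of the competing-risks screening model:
#' the Gaussian prior on the gestational age at delivery with preeclampsia
#' (`g`, in weeks), the additive maternal-history effects on its mean, the
#' integration grid, the preterm cutoff, and the biomarker likelihood
#' (broken-stick means of the log10 MoMs as a function of `g`, and their
#' covariance in unaffected pregnancies).
#'
#' The marker mean model is `E[log10 MoM | g] = intercept + slope * max(0,
#' knot - g)`: at or beyond the knot a pregnancy is biochemically
#' indistinguishable from an unaffected one, so with the default zero
#' intercepts unaffected pregnancies center on 1 MoM.
#'
#' @param prior_baseline_mean Prior mean of `g` (weeks) for the reference
#'   profile (nulliparous, no medical history, at the reference age, weight
#'   and height).
#' @param prior_sd Prior SD of `g` (weeks), common to all profiles.
#' @param prior_effects Named list of additive shifts (weeks) applied to the
#'   prior mean. Binary terms: `chronic_hypertension`, `diabetes`, `sle_aps`,
#'   `conception_assisted`, `smoker`, `parous_no_pe`, `parous_previous_pe`.
#'   Continuous terms come in slope/reference pairs: `age_slope`/`age_ref`
#'   (weeks per year), `weight_slope`/`weight_ref` (weeks per kg),
#'   `height_slope`/`height_ref` (weeks per cm).
#' @param g_grid_min,g_grid_max,g_grid_step Integration grid over `g` (weeks).
#' @param preterm_cutoff Gestational cutoff defining preterm PE (weeks).
#' @param no_pe_boundary Boundary (weeks): `g` at or beyond it means PE never
#'   occurs before delivery (the competing no-PE outcome).
#' @param marker_knots,marker_slopes,marker_intercepts Named numeric vectors
#'   over the markers `r toString(PE_MARKERS)`.
#' @param marker_covariance Symmetric positive-definite covariance matrix of
#'   the log10 MoM vector, with dimnames equal to the marker names.
#' @param schema_version Config schema version string.
#'
#' @return An object of class `pe_risk_params` (a validated list).
#' @seealso [default_risk_params()], [read_risk_params()], [write_risk_params()]
#' @export
risk_model_parameters <- function(prior_baseline_mean,
                                  prior_sd,
                                  prior_effects,
                                  g_grid_min = 10,
                                  g_grid_max = 95,
                                  g_grid_step = 0.02,
                                  preterm_cutoff = 37,
                                  no_pe_boundary,
                                  marker_knots,
                                  marker_slopes,
                                  marker_intercepts = setNames(numeric(length(PE_MARKERS)), PE_MARKERS),
                                  marker_covariance,
                                  schema_version = "1.0") {
  params <- structure(
    list(
      schema_version = as.character(schema_version),
      prior_baseline_mean = as.numeric(prior_baseline_mean),
      prior_sd = as.numeric(prior_sd),
      prior_effects = prior_effects,
      g_grid_min = as.numeric(g_grid_min),
      g_grid_max = as.numeric(g_grid_max),
      g_grid_step = as.numeric(g_grid_step),
      preterm_cutoff = as.numeric(preterm_cutoff),
      no_pe_boundary = as.numeric(no_pe_boundary),
      marker_knots = unlist(marker_knots)[PE_MARKERS],
      marker_slopes = unlist(marker_slopes)[PE_MARKERS],
      marker_intercepts = unlist(marker_intercepts)[PE_MARKERS],
      marker_covariance = as.matrix(marker_covariance)[PE_MARKERS, PE_MARKERS]
    ),
    class = "pe_risk_params"
  )
  validate_risk_params(params)
}

PRIOR_EFFECT_KEYS <- c(
  "chronic_hypertension", "diabetes", "sle_aps", "conception_assisted",
  "smoker", "parous_no_pe", "parous_previous_pe",
  "age_slope", "age_ref", "weight_slope", "weight_ref",
  "height_slope", "height_ref"
)

validate_risk_params <- function(params) {
  stopifnot(inherits(params, "pe_risk_params"))
  if (!is.finite(params$prior_sd) || params$prior_sd <= 0) {
    abort("`prior_sd` must be a positive number.", class = "pescreen_config_error")
  }
  if (!(params$g_grid_min < params$preterm_cutoff &&
        params$preterm_cutoff < params$no_pe_boundary &&
        params$no_pe_boundary <= params$g_grid_max)) {
    abort(
      "Grid ordering violated: need g_grid_min < preterm_cutoff < no_pe_boundary <= g_grid_max.",
      class = "pescreen_config_error"
    )
  }
  if (params$g_grid_step <= 0) {
    abort("`g_grid_step` must be positive.", class = "pescreen_config_error")
  }
  bad <- setdiff(names(params$prior_effects), PRIOR_EFFECT_KEYS)
  if (length(bad) > 0) {
    abort(
      paste0("Unknown prior effect key(s): ", toString(bad)),
      class = "pescreen_config_error"
    )
  }
  for (v in c("marker_knots", "marker_slopes", "marker_intercepts")) {
    if (!identical(names(params[[v]]), PE_MARKERS) || anyNA(params[[v]])) {
      abort(
        paste0("`", v, "` must be a named numeric vector over: ", toString(PE_MARKERS)),
        class = "pescreen_config_error"
      )
    }
  }
  cov <- params$marker_covariance
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-10))) {
    abort("`marker_covariance` must be symmetric.", class = "pescreen_config_error")
  }
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("`marker_covariance` must be positive definite.", class = "pescreen_config_error")
  }
  params
}

#' Default (synthetic) competing-risks model parameters
#'
#' The published screening software's coefficients are proprietary and not
#' printed in the literature this package operationalizes, so the package
#' ships a synthetic, order-of-magnitude-plausible default parameter set.
#' It is calibrated so that, under the default cohort spec
#' ([cohort_spec()]), the population incidence of preterm PE is about 1.34%
#' and of total PE about 3.17%, history-alone screening discriminates with
#' an AUC near 0.76, and the detection-rate ladder across the standard
#' biomarker combinations spans roughly 40% to 80% at a 10% FPR. Marker
#' SDs follow typical unaffected log10 MoM spreads (MAP 0.031, UtAPI 0.13,
#' PAPP-A 0.26, PlGF 0.22). Use these defaults for simulation and testing,
#' not for clinical risk reporting.
#'
#' @return A `pe_risk_params` object.
#' @export
default_risk_params <- function() {
  sds <- c(map = 0.0307, utapi = 0.1325, pappa = 0.2550, plgf = 0.2153)
  corr <- diag(4)
  dimnames(corr) <- list(PE_MARKERS, PE_MARKERS)
  corr["map", "utapi"] <- corr["utapi", "map"] <- 0.10
  corr["pappa", "plgf"] <- corr["plgf", "pappa"] <- 0.20
  corr["map", "pappa"] <- corr["pappa", "map"] <- 0.03
  corr["map", "plgf"] <- corr["plgf", "map"] <- 0.03
  corr["utapi", "pappa"] <- corr["pappa", "utapi"] <- -0.05
  corr["utapi", "plgf"] <- corr["plgf", "utapi"] <- -0.05
  covmat <- diag(sds) %*% corr %*% diag(sds)
  dimnames(covmat) <- list(PE_MARKERS, PE_MARKERS)

  risk_model_parameters(
    prior_baseline_mean = 53.34,
    prior_sd = 7,
    prior_effects = list(
      chronic_hypertension = -9.5,
      diabetes = -3.5,
      sle_aps = -4.5,
      conception_assisted = -2.3,
      smoker = 1,
      parous_no_pe = 2.3,
      parous_previous_pe = -7,
      age_slope = -0.09, age_ref = 30,
      weight_slope = -0.06, weight_ref = 63,
      height_slope = 0.06, height_ref = 160
    ),
    no_pe_boundary = 39.79,
    marker_knots = c(map = 40, utapi = 40, pappa = 40, plgf = 40),
    marker_slopes = c(map = 0.0055, utapi = 0.030, pappa = -0.050, plgf = -0.058),
    marker_covariance = covmat
  )
}

#' @export
print.pe_risk_params <- function(x, ...) {
  cat("<pe_risk_params> schema", x$schema_version, "\n")
  cat(sprintf(
    "  prior: g ~ N(%.2f + history effects, %.2f^2) weeks\n",
    x$prior_baseline_mean, x$prior_sd
  ))
  cat(sprintf(
    "  grid: [%.0f, %.0f] step %.3g; preterm cutoff %.1f; no-PE boundary %.2f\n",
    x$g_grid_min, x$g_grid_max, x$g_grid_step, x$preterm_cutoff, x$no_pe_boundary
  ))
  cat("  marker slopes (per week below knot):\n")
  print(round(x$marker_slopes, 4))
  invisible(x)
}

#' Read or write model parameters as YAML
#'
#' Serializes a [risk_model_parameters()] object to a versioned YAML config
#' file (the `schema_version` field travels with it) and back.
#'
#' @param params A `pe_risk_params` object.
#' @param path File path.
#' @return `write_risk_params()` returns `path` invisibly;
#'   `read_risk_params()` returns a validated `pe_risk_params`.
#' @export
write_risk_params <- function(params, path) {
  stopifnot(inherits(params, "pe_risk_params"))
  out <- params
  out$marker_covariance <- lapply(
    seq_len(nrow(params$marker_covariance)),
    function(i) as.numeric(params$marker_covariance[i, ])
  )
  names(out$marker_covariance) <- PE_MARKERS
  out$marker_knots <- as.list(params$marker_knots)
  out$marker_slopes <- as.list(params$marker_slopes)
  out$marker_intercepts <- as.list(params$marker_intercepts)
  class(out) <- NULL
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_risk_params
#' @export
read_risk_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version)) {
    abort("Config file has no `schema_version` field.", class = "pescreen_config_error")
  }
  covmat <- do.call(rbind, lapply(raw$marker_covariance[PE_MARKERS], as.numeric))
  dimnames(covmat) <- list(PE_MARKERS, PE_MARKERS)
  risk_model_parameters(
    prior_baseline_mean = raw$prior_baseline_mean,
    prior_sd = raw$prior_sd,
    prior_effects = raw$prior_effects,
    g_grid_min = raw$g_grid_min,
    g_grid_max = raw$g_grid_max,
    g_grid_step = raw$g_grid_step,
    preterm_cutoff = raw$preterm_cutoff,
    no_pe_boundary = raw$no_pe_boundary,
    marker_knots = unlist(raw$marker_knots),
    marker_slopes = unlist(raw$marker_slopes),
    marker_intercepts = unlist(raw$marker_intercepts),
    marker_covariance = covmat,
    schema_version = raw$schema_version
  )
}

g_grid <- function(params) {
  seq(params$g_grid_min, params$g_grid_max, by = params$g_grid_step)
}
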