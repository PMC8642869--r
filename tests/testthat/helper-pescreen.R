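# Shared fixtures and independent oracles for the test suite.

PE_MARKERS <- pescreen:::PE_MARKERS

ref_profile <- function(...) maternal_profile(...)

# Random moderate profiles: prior mean stays well inside the integration
# grid (no chronic hypertension, at most one strong factor), so quadrature
# agrees with closed forms at tight tolerances.
random_profile <- function() {
  maternal_profile(
    age = runif(1, 20, 40),
    weight = runif(1, 45, 95),
    height = runif(1, 145, 175),
    parity = sample(c("nulliparous", "parous_no_pe", "parous_previous_pe"), 1),
    diabetes = runif(1) < 0.2,
    conception = sample(c("spontaneous", "assisted"), 1),
    smoker = FALSE
  )
}

# Profiles with at most mild risk factors: the prior mean stays > ~47
# weeks, so less than 1e-7 of prior mass falls below the grid and
# quadrature agrees with untruncated closed forms to < 1e-6.
random_mild_profile <- function() {
  maternal_profile(
    age = runif(1, 20, 40),
    weight = runif(1, 45, 95),
    height = runif(1, 145, 175),
    parity = sample(c("nulliparous", "parous_no_pe"), 1),
    conception = sample(c("spontaneous", "assisted"), 1)
  )
}

# Brute-force posterior oracle: plain trapezoid integration of
# prior x likelihood on a (by default 10x) finer grid, with the
# multivariate normal density written out directly. Independent of the
# package's integration path.
oracle_posterior_risk <- function(profile, log10_moms, params, refine = 10) {
  g <- seq(params$g_grid_min, params$g_grid_max,
           by = params$g_grid_step / refine)
  mu <- prior_distribution(profile, params)$mean
  logw <- dnorm(g, mu, params$prior_sd, log = TRUE)
  markers <- names(log10_moms)
  if (length(markers) > 0) {
    cov <- params$marker_covariance[markers, markers, drop = FALSE]
    prec <- solve(cov)
    logdet <- determinant(cov)$modulus
    for (j in seq_along(g)) {
      m <- params$marker_intercepts[markers] +
        params$marker_slopes[markers] * pmax(0, params$marker_knots[markers] - g[j])
      d <- log10_moms - m
      logw[j] <- logw[j] -
        0.5 * (length(markers) * log(2 * pi) + logdet + sum(d * (prec %*% d)))
    }
  }
  w <- exp(logw - max(logw))
  h <- g[2] - g[1]
  trapz <- function(y) h * (sum(y) - (y[1] + y[length(y)]) / 2)
  k <- max(which(g <= params$preterm_cutoff))
  trapz(w[1:k]) / trapz(w)
}

# Exhaustive threshold scan for DR at a fixed FPR (unweighted and
# weighted): try every observed score as "positive iff score >= c".
oracle_dr_scan <- function(scores, is_case, weights, target_fpr) {
  best <- c(dr = 0, fpr = 0)
  for (c0 in sort(unique(scores), decreasing = TRUE)) {
    pos <- scores >= c0
    fpr <- sum(weights[pos & !is_case]) / sum(weights[!is_case])
    tpr <- sum(weights[pos & is_case]) / sum(weights[is_case])
    if (fpr <= target_fpr) best <- c(dr = tpr, fpr = fpr)
  }
  best
}

make_params <- function(...) {
  p <- default_risk_params()
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  validate_risk_params(p)
}
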