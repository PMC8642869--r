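test_that("prior mean is the baseline plus the configured additive shifts", {
  p <- default_risk_params()
  ref <- maternal_profile(
    age = p$prior_effects$age_ref, weight = p$prior_effects$weight_ref,
    height = p$prior_effects$height_ref
  )
  pr <- prior_distribution(ref, p)
  expect_equal(pr$mean, p$prior_baseline_mean)
  expect_equal(pr$sd, p$prior_sd)

  htn <- dplyr::mutate(ref, chronic_hypertension = TRUE)
  expect_equal(prior_distribution(htn, p)$mean,
               p$prior_baseline_mean + p$prior_effects$chronic_hypertension)

  # previous-PE effect: paired difference equals the configured shift exactly,
  # over randomized profiles and randomized effect values
  set.seed(42)
  for (i in 1:20) {
    p2 <- p
    p2$prior_effects$parous_previous_pe <- runif(1, -10, -1)
    a <- random_profile()
    b <- dplyr::mutate(a, parity = "parous_previous_pe")
    a <- dplyr::mutate(a, parity = "nulliparous")
    expect_equal(
      prior_distribution(b, p2)$mean - prior_distribution(a, p2)$mean,
      p2$prior_effects$parous_previous_pe,
      tolerance = 1e-12
    )
  }
})

test_that("prior preterm risk is the Gaussian mass below the cutoff", {
  p <- default_risk_params()
  # mean at the cutoff: symmetric, probability one half
  at_cut <- make_params(prior_baseline_mean = p$preterm_cutoff)
  ref <- maternal_profile(age = 30, weight = 63, height = 160)
  expect_equal(prior_preterm_risk(ref, at_cut), 0.5)

  # vanishing sd with mean above the cutoff: risk collapses to zero
  tight <- make_params(prior_baseline_mean = 50, prior_sd = 1e-6)
  expect_equal(prior_preterm_risk(ref, tight), 0)

  # mean 45, sd 5, cutoff 37: standard normal CDF at -1.6
  p45 <- make_params(prior_baseline_mean = 45, prior_sd = 5)
  expect_equal(prior_preterm_risk(ref, p45), 0.0547993, tolerance = 1e-6)
})

test_that("marker log-likelihood matches the multivariate Gaussian density", {
  p <- default_risk_params()
  # at the conditional mean the log-density is the normalizing constant
  g <- 33
  mu <- pescreen:::marker_mean_matrix(g, PE_MARKERS, p)[1, ]
  ll <- marker_log_likelihood(mu, g, p)
  expect_equal(ll, -0.5 * (4 * log(2 * pi) +
                             as.numeric(determinant(p$marker_covariance)$modulus)))

  # beyond all knots with zero MoM deviations: zero-mean MVN at the origin
  ll0 <- marker_log_likelihood(setNames(rep(0, 4), PE_MARKERS), 45, p)
  expect_equal(ll0, ll)

  # single marker: univariate Gaussian formula
  x <- 0.12
  g2 <- c(30, 36, 44)
  m <- p$marker_slopes["plgf"] * pmax(0, p$marker_knots["plgf"] - g2)
  s <- sqrt(p$marker_covariance["plgf", "plgf"])
  expect_equal(marker_log_likelihood(c(plgf = x), g2, p),
               dnorm(x, m, s, log = TRUE), tolerance = 1e-12)

  expect_error(marker_log_likelihood(c(bogus = 0), 30, p),
               class = "pescreen_config_error")
})

test_that("posterior with no markers reproduces the prior risk", {
  p <- default_risk_params()
  set.seed(7)
  for (i in 1:10) {
    prof <- random_mild_profile()
    post <- posterior_preterm_risk(prof, numeric(0), p)
    expect_lt(abs(post$preterm_pe_probability - prior_preterm_risk(prof, p)), 1e-6)
    expect_lt(abs(post$preterm_pe_probability - post$prior_probability), 1e-6)
  }
})

test_that("posterior density integrates to one over the grid", {
  p <- default_risk_params()
  prof <- ref_profile()
  for (moms in list(numeric(0), c(plgf = -0.3), c(map = 0.05, utapi = 0.2))) {
    d <- posterior_density(prof, moms, p)
    h <- d$g[2] - d$g[1]
    integral <- h * (sum(d$density) - (d$density[1] + tail(d$density, 1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-8)
  }
})

test_that("posterior equals the conjugate closed form for one linear-mean marker", {
  # knot at the grid's upper end makes the marker mean linear in g over the
  # whole grid, so the Gaussian prior is conjugate and the posterior is
  # Gaussian; a steeper slope and tighter prior put the posterior astride
  # the cutoff where the comparison is informative
  p <- make_params(
    prior_baseline_mean = 38, prior_sd = 4,
    g_grid_min = 20, g_grid_max = 55, g_grid_step = 0.005,
    marker_knots = c(map = 55, utapi = 55, pappa = 55, plgf = 55),
    marker_slopes = c(map = 0.01, utapi = 0.05, pappa = -0.1, plgf = -0.2)
  )
  s <- unname(p$marker_slopes["plgf"])
  sm2 <- unname(p$marker_covariance["plgf", "plgf"])
  set.seed(11)
  for (i in 1:20) {
    prof <- random_mild_profile()
    mu0 <- prior_distribution(prof, p)$mean
    x <- runif(1, -4.2, -3.0)  # implied g between ~34 and 40 weeks
    prec_post <- 1 / p$prior_sd^2 + s^2 / sm2
    ghat <- unname(p$marker_knots["plgf"]) - x / s
    mu_post <- (mu0 / p$prior_sd^2 + ghat * s^2 / sm2) / prec_post
    closed <- pnorm((p$preterm_cutoff - mu_post) * sqrt(prec_post))
    expect_gt(closed, 1e-4)  # guard: the comparison is not vacuous
    got <- posterior_preterm_risk(prof, c(plgf = x), p)$preterm_pe_probability
    expect_lt(abs(got - closed), 1e-6)
  }
})

test_that("posterior matches brute-force fine-grid integration on random instances", {
  set.seed(123)
  n_inst <- 100
  worst <- 0
  for (i in seq_len(n_inst)) {
    p <- make_params(
      prior_baseline_mean = runif(1, 50, 56),
      prior_sd = runif(1, 5, 9),
      marker_slopes = default_risk_params()$marker_slopes * runif(1, 0.5, 1.5),
      marker_knots = setNames(rep(runif(1, 38, 42), 4), PE_MARKERS)
    )
    prof <- random_profile()
    mks <- sample(PE_MARKERS, sample(1:4, 1))
    sds <- sqrt(diag(p$marker_covariance))[mks]
    moms <- setNames(rnorm(length(mks), 0, 1.5 * sds), mks)
    got <- posterior_preterm_risk(prof, moms, p)$preterm_pe_probability
    want <- oracle_posterior_risk(prof, moms, p, refine = 10)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-5)
})

test_that("risk is monotone in the marker deviations under the default signs", {
  p <- default_risk_params()
  prof <- ref_profile()
  plgf_grid <- seq(-0.8, 0.8, length.out = 15)
  r_plgf <- vapply(plgf_grid, function(x) {
    posterior_preterm_risk(prof, c(plgf = x), p)$preterm_pe_probability
  }, numeric(1))
  expect_true(all(diff(r_plgf) <= 1e-12))  # lower PlGF, higher risk

  map_grid <- seq(-0.12, 0.12, length.out = 15)
  r_map <- vapply(map_grid, function(x) {
    posterior_preterm_risk(prof, c(map = x), p)$preterm_pe_probability
  }, numeric(1))
  expect_true(all(diff(r_map) >= -1e-12))  # higher MAP, higher risk
})

test_that("one-in-N display rounds half away from zero and rejects bad input", {
  expect_identical(risk_to_one_in_n(0.01), "1:100")
  expect_identical(risk_to_one_in_n(1), "1:1")
  expect_identical(risk_to_one_in_n(0.0213), "1:47")
  expect_identical(risk_to_one_in_n(c(0.4, 2 / 3)), c("1:3", "1:2"))
  expect_error(risk_to_one_in_n(0), class = "pescreen_domain_error")
  expect_error(risk_to_one_in_n(-0.1), class = "pescreen_domain_error")
})
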