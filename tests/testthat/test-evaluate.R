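test_that("risk classification uses an inclusive 1-in-N boundary", {
  expect_true(classify_risk(0.0100, "1:100"))
  expect_false(classify_risk(0.0099, "1:100"))
  expect_true(classify_risk(1.0, "1:2"))
  expect_true(classify_risk(1.0, 1000))
  expect_equal(classify_risk(c(0.02, 0.001), "1 in 100"), c(TRUE, FALSE))
  expect_error(classify_risk(1.2), class = "pescreen_domain_error")
  expect_error(classify_risk(0.5, "nonsense"), class = "pescreen_config_error")
})

test_that("aspirin adjustment reproduces both count conventions", {
  adj <- aspirin_adjust(25, 19, 6, effect = 0.6, convention = "additive_paper")
  expect_equal(adj$multiplier, 2.5)
  expect_equal(adj$prevented_cases, 15)
  expect_equal(adj$adjusted_total_cases, 40)
  expect_equal(adj$adjusted_high_risk_cases, 34)

  lit <- aspirin_adjust(25, 19, 6, effect = 0.6, convention = "counterfactual")
  expect_equal(lit$prevented_cases, 9)
  expect_equal(lit$adjusted_total_cases, 34)
  expect_equal(lit$adjusted_high_risk_cases, 28)

  # zero effect: identity under either convention
  for (conv in c("additive_paper", "counterfactual")) {
    z <- aspirin_adjust(25, 19, 6, effect = 0, convention = conv)
    expect_equal(z$prevented_cases, 0)
    expect_equal(z$adjusted_total_cases, 25)
    expect_equal(z$adjusted_high_risk_cases, 19)
  }

  expect_error(aspirin_adjust(5, 9, 2), class = "pescreen_domain_error")
  expect_error(aspirin_adjust(25, 19, 6, effect = 1),
               class = "pescreen_config_error")
})

test_that("weighted ROC matches hand enumeration on a toy set", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  is_case <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  w <- c(2.5, 1, 1, 1, 1, 1)
  roc <- weighted_roc(scores, is_case, w)
  # case mass 3.5, control mass 4; thresholds descend through the scores
  expect_equal(roc$threshold, c(Inf, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  expect_equal(roc$tpr, c(0, 2.5 / 3.5, 2.5 / 3.5, 2.5 / 3.5, 1, 1, 1))
  expect_equal(roc$fpr, c(0, 0, 1 / 4, 2 / 4, 2 / 4, 3 / 4, 1))

  # ties move together
  roc_tie <- weighted_roc(c(1, 1, 0), c(TRUE, FALSE, FALSE), 1)
  expect_equal(roc_tie$fpr, c(0, 0.5, 1))
  expect_equal(roc_tie$tpr, c(0, 1, 1))

  # perfectly separated scores pass through (0, 1)
  roc_perf <- weighted_roc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE), 1)
  expect_true(any(roc_perf$fpr == 0 & roc_perf$tpr == 1))

  expect_error(weighted_roc(1:3, c(TRUE, TRUE, TRUE)),
               class = "pescreen_domain_error")
  expect_error(weighted_roc(1:2, c(TRUE, FALSE), c(-1, 1)),
               class = "pescreen_domain_error")
})

test_that("unit-weight ROC and AUC agree with pROC and the U statistic", {
  skip_if_not_installed("pROC")
  set.seed(8)
  n <- 400
  is_case <- runif(n) < 0.3
  scores <- rnorm(n, mean = ifelse(is_case, 1, 0))
  roc <- weighted_roc(scores, is_case, 1)
  auc <- roc_auc(roc)

  ref <- pROC::auc(pROC::roc(response = is_case, predictor = scores,
                             quiet = TRUE, direction = "<"))
  expect_equal(auc, as.numeric(ref), tolerance = 1e-12)

  # Mann-Whitney U / (n1*n0), ties counted half
  u <- sum(vapply(scores[is_case], function(s) {
    sum(s > scores[!is_case]) + 0.5 * sum(s == scores[!is_case])
  }, numeric(1)))
  expect_equal(auc, u / (sum(is_case) * sum(!is_case)), tolerance = 1e-12)

  # rank invariance under monotone transforms
  roc2 <- weighted_roc(qlogis(plogis(scores)), is_case, 1)
  expect_equal(roc_auc(roc2), auc, tolerance = 1e-12)
})

test_that("DR at fixed FPR uses the conservative empirical convention", {
  # toy 20-point set against an exhaustive threshold scan
  set.seed(21)
  scores <- round(runif(20), 2)
  is_case <- runif(20) < 0.4
  w <- ifelse(is_case, sample(c(1, 2.5), 20, TRUE), 1)
  roc <- weighted_roc(scores, is_case, w)
  for (target in c(0.05, 0.10, 0.25, 0.5)) {
    got <- dr_at_fpr(roc, target)
    want <- oracle_dr_scan(scores, is_case, w, target)
    expect_equal(got$dr, unname(want["dr"]), tolerance = 1e-12)
    expect_lte(got$fpr, target)
  }

  # perfect classifier: DR 1 at any FPR
  roc_perf <- weighted_roc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE), 1)
  expect_equal(dr_at_fpr(roc_perf, 0.01)$dr, 1)

  # uninformative scores: DR at the target FPR is close to the FPR itself
  set.seed(4)
  n <- 6000
  lab <- runif(n) < 0.25
  sc <- runif(n)
  dr0 <- dr_at_fpr(weighted_roc(sc, lab, 1), 0.10)
  expect_lt(abs(dr0$dr - 0.10), 0.04)
})

test_that("ROC curves are monotone step functions from (0,0) to (1,1)", {
  set.seed(14)
  for (i in 1:5) {
    n <- 200
    lab <- runif(n) < 0.3
    sc <- round(rnorm(n, ifelse(lab, 0.5, 0)), 1)  # heavy ties
    w <- runif(n, 0.5, 3)
    roc <- weighted_roc(sc, lab, w)
    expect_true(all(diff(roc$fpr) >= -1e-12))
    expect_true(all(diff(roc$tpr) >= -1e-12))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(tail(roc$fpr, 1), tail(roc$tpr, 1)), c(1, 1))
  }
})

test_that("bootstrap AUC interval is seeded, ordered and covers the estimate", {
  set.seed(2)
  n <- 300
  lab <- runif(n) < 0.3
  sc <- rnorm(n, ifelse(lab, 1, 0))
  a1 <- auc_ci(sc, lab, n_boot = 200, seed = 5)
  a2 <- auc_ci(sc, lab, n_boot = 200, seed = 5)
  expect_identical(a1, a2)
  expect_lt(a1$auc_lo, a1$auc)
  expect_gt(a1$auc_hi, a1$auc)
  # chance-level scores give an AUC near one half
  sc0 <- rnorm(n)
  expect_lt(abs(roc_auc(weighted_roc(sc0, lab, 1)) - 0.5), 0.1)
})

test_that("performance summary ties the weighting to the adjusted counts", {
  set.seed(33)
  n <- 3000
  coh <- tibble::tibble(
    outcome = sample(c("no_pe", "term_pe", "preterm_pe"), n, TRUE,
                     prob = c(0.95, 0.03, 0.02)),
    risk = runif(n)^3,
    aspirin = FALSE
  )
  # make risk informative and set aspirin among some high-risk cases
  coh$risk[coh$outcome == "preterm_pe"] <-
    pmin(1, coh$risk[coh$outcome == "preterm_pe"] + 0.4)
  coh$aspirin[which(coh$outcome == "preterm_pe")[1:5]] <- TRUE

  perf <- screening_performance(coh, "risk", threshold = "1:100")
  expect_s3_class(perf, "pe_performance")
  expect_equal(perf$multiplier, 2.5)
  expect_equal(perf$observed_cases_on_aspirin, 5)
  expect_equal(perf$prevented_cases, 12.5)
  expect_equal(perf$adjusted_total_cases, perf$observed_total_cases + 12.5)

  # effect 0 leaves all performance metrics at their unweighted values
  p0 <- screening_performance(coh, "risk", aspirin_effect = 0)
  roc_un <- weighted_roc(coh$risk, coh$outcome == "preterm_pe", 1)
  expect_equal(p0$auc, roc_auc(roc_un), tolerance = 1e-12)
  expect_equal(p0$dr_at_fpr, dr_at_fpr(roc_un, 0.10)$dr, tolerance = 1e-12)
  expect_equal(p0$adjusted_total_cases, p0$observed_total_cases)

  g <- glance(perf)
  expect_true(all(c("spr", "auc", "dr_at_fpr") %in% names(g)))
})

test_that("cohort summary reports incidences, group stats and Bonferroni markers", {
  set.seed(44)
  n <- 1863
  outcome <- rep("no_pe", n)
  outcome[1:25] <- "preterm_pe"
  outcome[26:59] <- "term_pe"
  coh <- tibble::tibble(
    age = rnorm(n, 30, 4), weight = rnorm(n, 63, 10), height = rnorm(n, 160, 5),
    chronic_hypertension = runif(n) < 0.02, diabetes = runif(n) < 0.03,
    sle_aps = FALSE, smoker = FALSE,
    conception = sample(c("spontaneous", "assisted"), n, TRUE, c(0.95, 0.05)),
    parity = sample(c("nulliparous", "parous_no_pe", "parous_previous_pe"),
                    n, TRUE, c(0.6, 0.38, 0.02)),
    outcome = outcome
  )
  coh$bmi <- coh$weight / (coh$height / 100)^2
  for (mk in PE_MARKERS) coh[[paste0(mk, "_mom")]] <- exp(rnorm(n, 0, 0.3))

  inc <- pe_incidence(coh)
  expect_equal(round(100 * inc$pe_incidence, 2), 3.17)
  expect_equal(round(100 * inc$preterm_pe_incidence, 2), 1.34)

  tab <- cohort_summary(coh)
  expect_true(all(c("characteristic", "stat_no_pe", "stat_pe",
                    "p_value", "p_adjusted", "test") %in% names(tab)))
  mk_rows <- tab[grepl("MoM", tab$characteristic), ]
  expect_equal(nrow(mk_rows), 4)
  expect_equal(mk_rows$p_adjusted, pmin(1, mk_rows$p_value * 4), tolerance = 1e-12)

  # identical groups: continuous p-values are 1 for exactly equal data
  same <- coh
  same$age <- 30
  tab_same <- cohort_summary(same)
  expect_equal(tab_same$p_value[tab_same$characteristic == "Age (years)"], 1)
})

test_that("chi-square path in the summary matches the textbook formula", {
  # 2x2 with all expected counts >= 5
  outcome <- rep(c("no_pe", "preterm_pe"), c(150, 50))
  diabetes <- c(rep(c(TRUE, FALSE), c(30, 120)), rep(c(TRUE, FALSE), c(20, 30)))
  coh <- tibble::tibble(outcome = outcome, diabetes = diabetes)
  tab <- cohort_summary(coh, markers = character(0))
  p_pkg <- tab$p_value[tab$characteristic == "Diabetes mellitus"]
  O <- table(diabetes, outcome != "no_pe")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  x2 <- sum((O - E)^2 / E)
  expect_equal(p_pkg, stats::pchisq(x2, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("AUC sample-size helper behaves like the Hanley-McNeil variance", {
  res <- sample_size_for_auc(0.9, se_target = 0.05)
  expect_true(res$required_cases > 0 && is.finite(res$required_cases))
  expect_identical(res$variance_model, "hanley_mcneil")

  # tighter precision demands more cases, diverging as se_target tends to 0
  sizes <- vapply(c(0.05, 0.02, 0.01, 0.005),
                  function(s) sample_size_for_auc(0.9, se_target = s)$required_cases,
                  numeric(1))
  expect_true(all(diff(sizes) > 0))
  expect_error(sample_size_for_auc(0.9, se_target = 0), class = "pescreen_domain_error")

  # doubling the allowed variance roughly halves the cases (large-n regime)
  n1 <- sample_size_for_auc(0.9, se_target = 0.01)$required_cases
  n2 <- sample_size_for_auc(0.9, se_target = 0.01 * sqrt(2))$required_cases
  expect_lt(abs(n1 / n2 - 2), 0.3)

  # test mode reports its assumptions alongside the count
  tm <- sample_size_for_auc(0.9, alpha = 0.05, power = 0.8, null_auc = 0.5,
                            mode = "test_vs_null")
  expect_true(tm$required_cases >= 2)
  expect_equal(tm$null_auc, 0.5)
  expect_error(sample_size_for_auc(0.45), class = "pescreen_domain_error")
})
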