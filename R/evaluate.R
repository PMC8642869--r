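#' Classify a risk against a "1 in N" threshold
#'
#' High risk iff `risk >= 1/N` (inclusive boundary), using the raw
#' probability — never the rounded "1:N" display.
#'
#' @param risk Numeric vector of probabilities.
#' @param threshold `"1:100"`, `"1 in 100"` or the number `N`.
#' @return Logical vector: `TRUE` for high risk.
#' @export
classify_risk <- function(risk, threshold = "1:100") {
  if (any(!is.finite(risk) | risk < 0 | risk > 1)) {
    abort("`risk` must contain probabilities in [0, 1].",
          class = "pescreen_domain_error")
  }
  risk >= 1 / parse_threshold(threshold)
}

#' Counterfactual aspirin adjustment of preterm-PE case counts
#'
#' Estimates how many preterm-PE cases there would have been had no
#' high-risk woman taken aspirin, from the observed counts and the assumed
#' risk-reduction `effect`. The multiplier is `1/(1 - effect)` (2.5 for
#' the conventional 0.6 effect). Two conventions are supported:
#'
#' * `additive_paper`: `prevented = multiplier * observed_on_aspirin`,
#'   added on top of the observed cases (so each observed treated case
#'   stands for `1 + multiplier` counterfactual cases). This reproduces
#'   the arithmetic used in the source analyses (e.g. 25 observed + 15
#'   prevented = 40 adjusted, with 6 treated observed cases).
#' * `counterfactual`: `prevented = (multiplier - 1) * observed_on_aspirin`,
#'   the literal reading under which `multiplier * observed` is the total
#'   number of treated women who would have developed preterm PE.
#'
#' @param observed_total Observed preterm-PE cases, all women.
#' @param observed_high_risk Observed preterm-PE cases classified high risk.
#' @param observed_on_aspirin Observed preterm-PE cases among aspirin takers.
#' @param effect Aspirin risk reduction, in `[0, 1)`.
#' @param convention `"additive_paper"` (default) or `"counterfactual"`.
#' @return A one-row tibble with the observed counts, `multiplier`,
#'   `prevented_cases` (real-valued), `adjusted_total_cases` and
#'   `adjusted_high_risk_cases`.
#' @export
aspirin_adjust <- function(observed_total, observed_high_risk,
                           observed_on_aspirin, effect = 0.6,
                           convention = c("additive_paper", "counterfactual")) {
  convention <- match.arg(convention)
  if (!(observed_on_aspirin <= observed_high_risk &&
        observed_high_risk <= observed_total)) {
    abort("Need observed_on_aspirin <= observed_high_risk <= observed_total.",
          class = "pescreen_domain_error")
  }
  if (effect < 0 || effect >= 1) {
    abort("`effect` must lie in [0, 1).", class = "pescreen_config_error")
  }
  multiplier <- 1 / (1 - effect)
  # with zero effect nothing can have been prevented, under either reading
  prevented <- if (effect == 0) 0 else switch(convention,
    additive_paper = multiplier * observed_on_aspirin,
    counterfactual = (multiplier - 1) * observed_on_aspirin
  )
  tibble::tibble(
    convention = convention,
    observed_total_cases = observed_total,
    observed_high_risk_cases = observed_high_risk,
    observed_cases_on_aspirin = observed_on_aspirin,
    multiplier = multiplier,
    prevented_cases = prevented,
    adjusted_total_cases = observed_total + prevented,
    adjusted_high_risk_cases = observed_high_risk + prevented
  )
}

#' Weighted empirical ROC curve
#'
#' Builds the empirical ROC of `scores` against case status, with optional
#' non-negative per-observation weights. Ties are grouped: all
#' observations sharing a score enter or leave the positive set together.
#' Weights carry the aspirin counterfactual into the evaluation: each
#' observed treated preterm-PE case receives the extra mass implied by the
#' adjustment convention (prevented cases inherit the score distribution
#' of the observed treated cases), so no pseudo-records with invented
#' scores are needed.
#'
#' @param scores Numeric risk scores (higher = more suspicious).
#' @param is_case Logical: `TRUE` for preterm-PE cases.
#' @param weights Non-negative weights, recycled if length 1 (default 1).
#' @return A tibble of class `pe_roc` with columns `threshold`
#'   (classify positive iff `score >= threshold`), `fpr` and `tpr`,
#'   starting at (0, 0) for `threshold = Inf` and ending at (1, 1).
#' @export
weighted_roc <- function(scores, is_case, weights = 1) {
  n <- length(scores)
  weights <- rep_len(weights, n)
  if (any(!is.finite(scores)) || any(is.na(is_case))) {
    abort("Scores and case labels must be complete.", class = "pescreen_domain_error")
  }
  if (any(weights < 0)) {
    abort("Weights must be non-negative.", class = "pescreen_domain_error")
  }
  w_case <- sum(weights[is_case])
  w_ctrl <- sum(weights[!is_case])
  if (w_case <= 0 || w_ctrl <= 0) {
    abort("Need positive case and control mass to build a ROC curve.",
          class = "pescreen_domain_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  grp <- !duplicated(s)
  thresholds <- s[grp]
  case_w <- rowsum(weights[ord] * is_case[ord], group = cumsum(grp), reorder = FALSE)
  ctrl_w <- rowsum(weights[ord] * !is_case[ord], group = cumsum(grp), reorder = FALSE)
  out <- tibble::tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, cumsum(ctrl_w) / w_ctrl),
    tpr = c(0, cumsum(case_w) / w_case)
  )
  structure(out, class = c("pe_roc", class(tibble::tibble())))
}

#' Detection rate at a fixed false-positive rate
#'
#' Empirical (non-interpolated) reading of the ROC: the detection rate at
#' the most permissive cutoff whose FPR does not exceed the target.
#'
#' @param roc A [weighted_roc()] curve.
#' @param target_fpr Target FPR (default 0.10).
#' @return A one-row tibble: `dr`, `fpr` (attained), `cutoff` (score) and
#'   `cutoff_one_in_n` (the cutoff displayed as "1:N" when it is a
#'   probability).
#' @export
dr_at_fpr <- function(roc, target_fpr = 0.10) {
  stopifnot(inherits(roc, "pe_roc"))
  ok <- which(roc$fpr <= target_fpr)
  i <- ok[length(ok)]  # most permissive cutoff still within the FPR budget
  cutoff <- roc$threshold[i]
  tibble::tibble(
    dr = roc$tpr[i],
    fpr = roc$fpr[i],
    cutoff = cutoff,
    cutoff_one_in_n = if (is.finite(cutoff) && cutoff > 0 && cutoff <= 1) {
      risk_to_one_in_n(cutoff)
    } else {
      NA_character_
    }
  )
}

#' Area under a weighted empirical ROC curve
#'
#' Trapezoidal area under the curve. With all weights 1 this equals the
#' Mann-Whitney U statistic divided by `n_case * n_control` (ties counted
#' half).
#'
#' @param roc A [weighted_roc()] curve.
#' @return The AUC as a single number.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "pe_roc"))
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' AUC with a stratified bootstrap confidence interval
#'
#' Point estimate from [roc_auc()]; the CI resamples women with
#' replacement within the case and control strata (each woman keeps her
#' weight), recomputes the weighted AUC per replicate, and takes
#' percentile bounds.
#'
#' @inheritParams weighted_roc
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the resampling.
#' @return A one-row tibble: `auc`, `auc_lo`, `auc_hi`, `n_boot`.
#' @export
auc_ci <- function(scores, is_case, weights = 1, n_boot = 2000,
                   conf = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weights <- rep_len(weights, length(scores))
  est <- roc_auc(weighted_roc(scores, is_case, weights))
  cases <- which(is_case)
  ctrls <- which(!is_case)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(cases, replace = TRUE), sample(ctrls, replace = TRUE))
    roc_auc(weighted_roc(scores[idx], is_case[idx], weights[idx]))
  }, numeric(1))
  qs <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  tibble::tibble(auc = est, auc_lo = qs[1], auc_hi = qs[2], n_boot = n_boot)
}

#' Screening performance for one risk column
#'
#' Computes, for an evaluated cohort: the screen-positive rate at the risk
#' threshold, the aspirin-adjusted case counts, and the weighted ROC
#' metrics (AUC, DR at the target FPR, and the risk cutoff attaining it).
#' Cases are observed preterm-PE pregnancies; controls are all others.
#' Observed preterm-PE cases in aspirin takers carry the extra weight
#' implied by the adjustment convention so that prevented cases (who have
#' no observed risk) inherit the treated cases' score distribution.
#'
#' @param cohort Cohort tibble with `outcome`, `aspirin` and the risk column.
#' @param risk_col Name of the risk column to evaluate.
#' @param label Combination label carried into the output.
#' @param threshold Risk threshold, e.g. `"1:100"`.
#' @param target_fpr Target FPR for the DR (default 0.10).
#' @param aspirin_effect Assumed aspirin risk reduction (default 0.6).
#' @param convention Adjustment convention, see [aspirin_adjust()].
#' @param ci Compute a bootstrap CI for the AUC? (slower).
#' @param n_boot,seed Passed to [auc_ci()] when `ci = TRUE`.
#' @return A one-row tibble of class `pe_performance`: `combination`,
#'   `n`, `spr`, `dr_unadjusted`, `auc`, `auc_lo`, `auc_hi`, `dr_at_fpr`,
#'   `cutoff_one_in_n`, plus the [aspirin_adjust()] count columns.
#' @export
screening_performance <- function(cohort, risk_col = "risk",
                                  label = risk_col,
                                  threshold = "1:100", target_fpr = 0.10,
                                  aspirin_effect = 0.6,
                                  convention = c("additive_paper", "counterfactual"),
                                  ci = FALSE, n_boot = 2000, seed = NULL) {
  convention <- match.arg(convention)
  stopifnot(all(c("outcome", "aspirin", risk_col) %in% names(cohort)))
  risk <- cohort[[risk_col]]
  is_case <- cohort$outcome == "preterm_pe"
  high <- classify_risk(risk, threshold)

  counts <- aspirin_adjust(
    observed_total = sum(is_case),
    observed_high_risk = sum(is_case & high),
    observed_on_aspirin = sum(is_case & cohort$aspirin),
    effect = aspirin_effect, convention = convention
  )

  # per-woman ROC weights implied by the adjustment convention
  weights <- rep(1, nrow(cohort))
  treated_cases <- is_case & cohort$aspirin
  if (any(treated_cases)) {
    extra <- counts$prevented_cases / sum(treated_cases)
    weights[treated_cases] <- 1 + extra
  }

  roc <- weighted_roc(risk, is_case, weights)
  dr <- dr_at_fpr(roc, target_fpr)
  auc_row <- if (ci) {
    auc_ci(risk, is_case, weights, n_boot = n_boot, seed = seed)
  } else {
    tibble::tibble(auc = roc_auc(roc), auc_lo = NA_real_, auc_hi = NA_real_)
  }

  out <- dplyr::bind_cols(
    tibble::tibble(
      combination = label,
      n = nrow(cohort),
      spr = mean(high),
      dr_unadjusted = sum(is_case & high) / sum(is_case)
    ),
    auc_row[, c("auc", "auc_lo", "auc_hi")],
    tibble::tibble(
      dr_at_fpr = dr$dr,
      target_fpr = target_fpr,
      cutoff_one_in_n = dr$cutoff_one_in_n
    ),
    counts
  )
  structure(out, class = c("pe_performance", class(tibble::tibble())))
}

#' @export
glance.pe_performance <- function(x, ...) {
  tibble::as_tibble(x)[, c("combination", "n", "spr", "auc",
                           "dr_at_fpr", "cutoff_one_in_n",
                           "adjusted_total_cases", "adjusted_high_risk_cases")]
}

#' Required preterm-PE cases for an AUC study
#'
#' Sample-size helper based on the Hanley-McNeil variance approximation
#' for an empirical AUC,
#' `V = (A(1-A) + (nc-1)(Q1-A^2) + (nn-1)(Q2-A^2)) / (nc*nn)` with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)` and `nn = ratio * nc` controls.
#' Two modes:
#'
#' * `"precision"`: the smallest case count whose AUC standard error does
#'   not exceed `se_target`.
#' * `"test_vs_null"`: the smallest case count giving the stated power, at
#'   one-sided level `alpha`, to distinguish `auc0` from `null_auc`.
#'
#' Published screening sample-size statements rarely pin down which
#' formula (or control:case ratio) was used, so the returned tibble
#' records every assumption alongside the count.
#'
#' @param auc0 Expected AUC, in (0.5, 1).
#' @param se_target Target standard error of the AUC (precision mode).
#' @param alpha Type-I error (test mode, one-sided).
#' @param power Desired power (test mode).
#' @param null_auc Null AUC (test mode, default 0.5).
#' @param control_case_ratio Controls per case (default 72, roughly a 1.34%
#'   case prevalence).
#' @param mode `"precision"` (default) or `"test_vs_null"`.
#' @return A one-row tibble: `required_cases`, `required_total`, and the
#'   assumptions used.
#' @export
sample_size_for_auc <- function(auc0, se_target = 0.05, alpha = 0.05,
                                power = 0.80, null_auc = 0.5,
                                control_case_ratio = 72,
                                mode = c("precision", "test_vs_null")) {
  mode <- match.arg(mode)
  if (auc0 <= 0.5 || auc0 >= 1) {
    abort("`auc0` must lie in (0.5, 1).", class = "pescreen_domain_error")
  }
  if (mode == "precision" && se_target <= 0) {
    abort("`se_target` must be positive (cases diverge as it tends to 0).",
          class = "pescreen_domain_error")
  }
  hm_var <- function(a, nc) {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    nn <- control_case_ratio * nc
    (a * (1 - a) + (nc - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) / (nc * nn)
  }
  feasible <- function(nc) {
    if (mode == "precision") {
      sqrt(hm_var(auc0, nc)) <= se_target
    } else {
      qnorm(1 - alpha) * sqrt(hm_var(null_auc, nc)) +
        qnorm(power) * sqrt(hm_var(auc0, nc)) <= auc0 - null_auc
    }
  }
  nc <- 2
  while (!feasible(nc) && nc < 1e7) nc <- nc + 1
  if (!feasible(nc)) {
    abort("Infeasible inputs: no attainable case count below 1e7.",
          class = "pescreen_domain_error")
  }
  tibble::tibble(
    required_cases = nc,
    required_total = nc * (1 + control_case_ratio),
    mode = mode, auc0 = auc0,
    se_target = if (mode == "precision") se_target else NA_real_,
    alpha = if (mode == "test_vs_null") alpha else NA_real_,
    power = if (mode == "test_vs_null") power else NA_real_,
    null_auc = if (mode == "test_vs_null") null_auc else NA_real_,
    control_case_ratio = control_case_ratio,
    variance_model = "hanley_mcneil"
  )
}
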