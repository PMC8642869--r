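#' Cohort characteristics table by PE status
#'
#' Builds a Table-1-style summary: continuous characteristics as mean +/-
#' SD with a two-sample t-test (no PE vs any PE), categorical ones as
#' n (%) with a chi-square test (Fisher's exact when any expected cell is
#' below 5), and the log10 MoM distributions compared across the three
#' outcome groups (no PE, term PE, preterm PE) by one-way ANOVA with
#' Bonferroni correction applied within the marker family.
#'
#' @param cohort Cohort tibble with profile columns, `<marker>_mom`
#'   columns and `outcome`.
#' @param markers Markers whose log10 MoM distributions are compared.
#' @return A tibble: `characteristic`, `stat_no_pe`, `stat_pe`, `p_value`,
#'   `p_adjusted` (markers only), `test`. Empty strata yield `NA`, not
#'   errors.
#' @export
cohort_summary <- function(cohort, markers = PE_MARKERS) {
  stopifnot("outcome" %in% names(cohort))
  pe <- cohort$outcome != "no_pe"

  fmt_mean_sd <- function(x) {
    if (length(x) == 0) return(NA_character_)
    sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  }
  fmt_n_pct <- function(x) {
    if (length(x) == 0) return(NA_character_)
    sprintf("%d (%.1f%%)", sum(x), 100 * mean(x))
  }
  t_p <- function(x) {
    a <- x[!pe]; b <- x[pe]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (stats::sd(x) == 0) return(1)  # identical data: no evidence of a difference
    tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
  }
  cat_p <- function(x) {
    if (length(unique(pe)) < 2 || length(unique(x)) < 2) return(NA_real_)
    tab <- table(x, pe)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      fisher.test(tab)$p.value
    } else {
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
  }

  rows <- list()
  add <- function(characteristic, stat_no_pe, stat_pe, p, test) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      characteristic = characteristic, stat_no_pe = stat_no_pe,
      stat_pe = stat_pe, p_value = p, test = test
    )
  }

  cont <- c(age = "Age (years)", weight = "Weight (kg)", height = "Height (cm)",
            bmi = "Body mass index (kg/m²)",
            ga_delivery = "Gestational age at delivery (weeks)")
  for (v in names(cont)) {
    if (!v %in% names(cohort)) next
    x <- cohort[[v]]
    add(cont[[v]], fmt_mean_sd(x[!pe]), fmt_mean_sd(x[pe]), t_p(x), "t-test")
  }

  bin <- c(chronic_hypertension = "Chronic hypertension", diabetes = "Diabetes mellitus",
           sle_aps = "SLE/APS", smoker = "Smoker")
  for (v in names(bin)) {
    if (!v %in% names(cohort)) next
    x <- as.logical(cohort[[v]])
    add(bin[[v]], fmt_n_pct(x[!pe]), fmt_n_pct(x[pe]), cat_p(x),
        "chi-square/Fisher")
  }
  if ("conception" %in% names(cohort)) {
    x <- cohort$conception == "assisted"
    add("Assisted conception", fmt_n_pct(x[!pe]), fmt_n_pct(x[pe]), cat_p(x),
        "chi-square/Fisher")
  }
  if ("parity" %in% names(cohort)) {
    p <- cat_p(cohort$parity)
    for (lev in PARITY_LEVELS) {
      x <- cohort$parity == lev
      add(paste0("Parity: ", gsub("_", " ", lev)),
          fmt_n_pct(x[!pe]), fmt_n_pct(x[pe]), p, "chi-square/Fisher")
    }
  }

  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- NA_real_

  # marker log10 MoMs: ANOVA across the three outcome groups, Bonferroni
  # within the marker family only
  marker_rows <- list()
  for (mk in markers) {
    col <- mom_col(mk)
    if (!col %in% names(cohort)) next
    lm10 <- log10(cohort[[col]])
    grp <- factor(cohort$outcome, levels = c("no_pe", "term_pe", "preterm_pe"))
    p <- if (nlevels(droplevels(grp)) < 2 || stats::sd(lm10) == 0) {
      if (stats::sd(lm10) == 0) 1 else NA_real_
    } else {
      summary(aov(lm10 ~ grp))[[1]][["Pr(>F)"]][1]
    }
    marker_rows[[mk]] <- tibble::tibble(
      characteristic = paste0("log10 ", toupper(mk), " MoM"),
      stat_no_pe = fmt_mean_sd(lm10[!pe]),
      stat_pe = fmt_mean_sd(lm10[pe]),
      p_value = p, test = "ANOVA (3 groups)"
    )
  }
  if (length(marker_rows) > 0) {
    mtab <- dplyr::bind_rows(marker_rows)
    mtab$p_adjusted <- p.adjust(mtab$p_value, method = "bonferroni")
    out <- dplyr::bind_rows(out, mtab)
  }
  out
}

#' Incidence of PE outcomes in a cohort
#'
#' @param cohort Cohort tibble with `outcome`.
#' @return A one-row tibble: `n`, `n_pe`, `n_preterm_pe`, `pe_incidence`,
#'   `preterm_pe_incidence` (fractions).
#' @export
pe_incidence <- function(cohort) {
  tibble::tibble(
    n = nrow(cohort),
    n_pe = sum(cohort$outcome != "no_pe"),
    n_preterm_pe = sum(cohort$outcome == "preterm_pe"),
    pe_incidence = sum(cohort$outcome != "no_pe") / nrow(cohort),
    preterm_pe_incidence = sum(cohort$outcome == "preterm_pe") / nrow(cohort)
  )
}
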