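#' Screening evaluation configuration
#'
#' @param threshold Risk threshold for classification, e.g. `"1:100"`.
#' @param target_fpr Target FPR for detection rates (default 0.10).
#' @param aspirin_effect Assumed aspirin risk reduction (default 0.6).
#' @param convention Aspirin count convention, see [aspirin_adjust()].
#' @param alpha Significance level for MoM QC.
#' @param band Clinical-irrelevance band for re-centering, see [recenter()].
#' @param ci Bootstrap AUC confidence intervals in performance summaries?
#' @param n_boot Bootstrap replicates.
#' @param seed Seed governing all randomness downstream of the config
#'   (bootstrap resampling).
#' @return A list of class `pe_screening_config`.
#' @export
screening_config <- function(threshold = "1:100", target_fpr = 0.10,
                             aspirin_effect = 0.6,
                             convention = c("additive_paper", "counterfactual"),
                             alpha = 0.05, band = c(0.98, 1.02),
                             ci = FALSE, n_boot = 2000, seed = 1L) {
  if (target_fpr <= 0 || target_fpr >= 1) {
    abort("`target_fpr` must lie in (0, 1).", class = "pescreen_config_error")
  }
  if (aspirin_effect < 0 || aspirin_effect >= 1) {
    abort("`aspirin_effect` must lie in [0, 1).", class = "pescreen_config_error")
  }
  structure(
    list(
      threshold = threshold, target_fpr = target_fpr,
      aspirin_effect = aspirin_effect, convention = match.arg(convention),
      alpha = alpha, band = band, ci = ci, n_boot = n_boot,
      seed = as.integer(seed)
    ),
    class = "pe_screening_config"
  )
}

#' Standard biomarker combinations
#'
#' The conventional ladder of screening tests: maternal history alone,
#' history plus each single biomarker, the biophysical triple plus PlGF,
#' and all four markers.
#'
#' @return Named list of marker vectors, in evaluation order.
#' @export
standard_combinations <- function() {
  list(
    "history" = character(0),
    "history+MAP" = "map",
    "history+UtAPI" = "utapi",
    "history+PlGF" = "plgf",
    "history+MAP+UtAPI+PlGF" = c("map", "utapi", "plgf"),
    "history+MAP+UtAPI+PlGF+PAPPA" = c("map", "utapi", "plgf", "pappa")
  )
}

#' Run the full screening analysis pipeline
#'
#' End-to-end, in the analysis order: MoM QC and re-centering on
#' unaffected pregnancies; posterior risk computation for every standard
#' biomarker combination on the re-centered MoMs; classification at the
#' risk threshold; aspirin-adjusted performance summary (SPR, weighted
#' ROC, DR at the target FPR, AUC) per combination. The screen-positive
#' rate at the threshold is also reported for the pre-QC all-marker risk,
#' so the effect of re-centering on the SPR is visible.
#'
#' @param cohort A cohort tibble ([simulate_cohort()] or [read_cohort()])
#'   with outcomes and an `aspirin` column.
#' @param params [risk_model_parameters()].
#' @param config [screening_config()].
#' @param combinations Named list of marker vectors (default
#'   [standard_combinations()]).
#' @return An object of class `pe_report`: list with `qc` (the [mom_qc()]
#'   result), `risks` (cohort plus one risk column per combination),
#'   `performance` (one row per combination), `spr_pre_qc`, `spr_post_qc`,
#'   and `manifest` (config/parameter hashes, seed, versions).
#' @export
run_pipeline <- function(cohort, params = default_risk_params(),
                         config = screening_config(),
                         combinations = standard_combinations()) {
  stopifnot(inherits(config, "pe_screening_config"))
  validate_risk_params(params)
  if (!"aspirin" %in% names(cohort)) cohort$aspirin <- FALSE

  all_markers <- unique(unlist(combinations))
  pre <- compute_risks(cohort, params, markers = all_markers, risk_col = ".risk_pre")
  spr_pre <- mean(classify_risk(pre$.risk_pre, config$threshold))

  qc <- mom_qc(cohort, markers = all_markers, alpha = config$alpha,
               band = config$band)
  risks <- qc$cohort

  perf <- list()
  for (label in names(combinations)) {
    col <- paste0("risk_", gsub("[^a-zA-Z0-9]+", "_", tolower(label)))
    risks <- compute_risks(risks, params, markers = combinations[[label]],
                           risk_col = col)
    perf[[label]] <- screening_performance(
      risks, risk_col = col, label = label,
      threshold = config$threshold, target_fpr = config$target_fpr,
      aspirin_effect = config$aspirin_effect, convention = config$convention,
      ci = config$ci, n_boot = config$n_boot, seed = config$seed
    )
  }
  performance <- dplyr::bind_rows(perf)

  last_col <- paste0("risk_", gsub("[^a-zA-Z0-9]+", "_",
                                   tolower(tail(names(combinations), 1))))
  spr_post <- mean(classify_risk(risks[[last_col]], config$threshold))

  manifest <- list(
    package_version = as.character(utils::packageVersion("pescreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n = nrow(cohort),
    seed = config$seed,
    params_hash = rlang::hash(unclass(params)),
    config_hash = rlang::hash(unclass(config)),
    combinations = lapply(combinations, as.character)
  )

  structure(
    list(qc = qc, risks = risks, performance = performance,
         spr_pre_qc = spr_pre, spr_post_qc = spr_post, manifest = manifest),
    class = "pe_report"
  )
}

#' @export
print.pe_report <- function(x, ...) {
  cat("<pe_report>", x$manifest$n, "women;",
      sprintf("SPR pre/post QC: %.1f%% / %.1f%%\n",
              100 * x$spr_pre_qc, 100 * x$spr_post_qc))
  cat("Re-centering factors:\n")
  print(as.data.frame(x$qc$report[, c("marker", "median_mom",
                                      "recentering_factor", "applied")]))
  cat("\nPerformance by combination:\n")
  print(as.data.frame(dplyr::mutate(
    x$performance[, c("combination", "spr", "auc", "dr_at_fpr", "cutoff_one_in_n")],
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3))
  )))
  invisible(x)
}

#' @export
tidy.pe_report <- function(x, ...) tibble::as_tibble(x$performance)

#' @export
glance.pe_report <- function(x, ...) {
  tibble::tibble(
    n = x$manifest$n,
    spr_pre_qc = x$spr_pre_qc,
    spr_post_qc = x$spr_post_qc,
    auc_history = x$performance$auc[1],
    auc_full = tail(x$performance$auc, 1),
    dr_full = tail(x$performance$dr_at_fpr, 1)
  )
}

#' Export a pipeline report
#'
#' Writes the performance summary and the re-centering report as JSON, a
#' markdown table of the combination ladder (combination, risk cutoff, DR
#' at the target FPR), and the run manifest. Outputs are deterministic
#' given identical inputs and manifest seed: re-running writes
#' byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "pe_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    performance = file.path(dir, "performance.json"),
    recentering = file.path(dir, "recentering.json"),
    table = file.path(dir, "performance.md"),
    manifest = file.path(dir, "manifest.json")
  )
  payload <- function(x) {
    list(manifest_hash = rlang::hash(report$manifest), data = x)
  }
  jsonlite::write_json(payload(report$performance), paths["performance"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(payload(report$qc$report), paths["recentering"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  tab <- report$performance
  lines <- c(
    "| Screening test | Risk cutoff | DR @ FPR | AUC |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.1f%% | %.3f |",
            tab$combination, tab$cutoff_one_in_n, 100 * tab$dr_at_fpr, tab$auc)
  )
  writeLines(lines, paths["table"])
  invisible(paths)
}
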