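# End-to-end orchestration: score -> calibrate -> cross-tabulate ->
# mixed-model comparison -> Cox/ROC/DeLong -> diagnostic tables.

# stable polynomial hash of the run options, for run provenance
options_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full score-comparison analysis on a cohort
#'
#' Executes the complete pipeline on a validated cohort bundle:
#' \enumerate{
#'   \item Erlangen Score (with and without the amyloid-ratio adjustment)
#'     and ATN(R) constellations for every subject;
#'   \item Youden-index calibration of the pTau/Abeta1-42 ratio cut-off on
#'     the neurochemically definite AD profiles (all four markers
#'     pathological) versus the biomarker-negative profiles, then binary
#'     ratio classification;
#'   \item constellation-by-classifier cross-tabulations;
#'   \item mixed-model comparison of MMSE z-score trajectories across the
#'     candidate groupings (binary score, ordinal score, ratio classifier,
#'     ratio-free score), when visits are available;
#'   \item Cox-based 10-year conversion probabilities, AUCs and paired
#'     DeLong comparisons against the ratio classifier, plus diagnostic
#'     2x2 tables, when outcomes are available.
#' }
#' A stage that is degenerate on the supplied cohort (e.g. a single risk
#' group, or no events) is flagged in `$stage_errors` while the remaining
#' stages complete.
#'
#' @param bundle A [read_cohort_tables()] bundle, or a
#'   [generate_cohort()] result.
#' @param panel An [assay_panel()]; defaults to the bundle's
#'   highest-priority panel when available, else [default_panel()].
#' @param horizon Cox prediction horizon in years.
#' @return An object of class `ers_analysis_report`.
#' @export
run_full_comparison <- function(bundle, panel = NULL, horizon = 10) {
  if (inherits(bundle, "synthetic_cohort")) {
    bundle <- list(profiles = bundle$profiles, visits = bundle$visits,
                   outcomes = bundle$outcomes, panels = NULL,
                   panel_priority = NULL)
  }
  if (is.null(panel)) {
    panel <- if (!is.null(bundle$panels)) {
      bundle$panels[[bundle$panel_priority[1]]]
    } else {
      default_panel()
    }
  }
  profiles <- bundle$profiles
  stage_errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stage_errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # -- scoring ---------------------------------------------------------
  cons <- constellation_of(profiles, panel)
  ers <- ers_score(profiles, panel)
  ers_nr <- ers_score(profiles, panel, use_ratio = FALSE)

  # -- ratio calibration ----------------------------------------------
  ratio <- ptau_ab42_ratio(profiles$ptau, profiles$ab42)
  is_case <- cons$R & cons$A & cons$T_ & cons$N
  is_control <- !cons$R & !cons$A & !cons$T_ & !cons$N
  is_case[is.na(is_case)] <- FALSE
  is_control[is.na(is_control)] <- FALSE
  calibration <- run_stage("calibration",
                           calibrate_youden(ratio[is_case], ratio[is_control]))
  ratio_class <- if (!is.null(calibration)) {
    classify_ratio(ratio, calibration)$risk_class
  } else {
    factor(rep(NA_character_, nrow(profiles)), levels = c("low", "high"))
  }

  crosstabs <- list(
    ers = constellation_crosstab(cons$constellation,
                                 factor(ers$total, levels = 0:4)),
    ers_risk = constellation_crosstab(cons$constellation, ers$risk_class),
    ratio = constellation_crosstab(cons$constellation, ratio_class)
  )

  # -- trajectory models ----------------------------------------------
  model_table <- NULL
  lmm_fits <- NULL
  if (!is.null(bundle$visits)) {
    groupings <- list(
      ers_binary = factor(ifelse(ers$total > 1L, "pathologic", "normal"),
                          levels = c("normal", "pathologic")),
      ers_ordinal = factor(ers$total),
      ratio = ratio_class,
      ers_no_ratio = factor(ifelse(ers_nr$total > 1L, "pathologic", "normal"),
                            levels = c("normal", "pathologic"))
    )
    lmm_fits <- list()
    for (nm in names(groupings)) {
      g <- stats::setNames(as.character(groupings[[nm]]), profiles$subject_id)
      g <- g[!is.na(g)]
      fit <- run_stage(paste0("lmm_", nm), {
        if (length(unique(g)) < 2L) stop("grouping '", nm, "' has a single level")
        fit_zmmse_lmm(bundle$visits[bundle$visits$subject_id %in% names(g), ], g)
      })
      if (!is.null(fit)) lmm_fits[[nm]] <- fit
    }
    if (length(lmm_fits) >= 1L) {
      model_table <- run_stage("model_table", compare_lmm(lmm_fits))
    }
  }

  # -- dementia risk ---------------------------------------------------
  risk <- NULL
  diagnostics <- NULL
  if (!is.null(bundle$outcomes)) {
    scores <- list(
      ratio = stats::setNames(ratio, profiles$subject_id),
      ers = stats::setNames(ers$total, profiles$subject_id),
      ers_no_ratio = stats::setNames(ers_nr$total, profiles$subject_id)
    )
    risk <- run_stage("risk",
                      compare_risk_scores(scores, bundle$outcomes, horizon))
    diagnostics <- run_stage("diagnostics", {
      omap <- match(bundle$outcomes$subject_id, profiles$subject_id)
      ev <- as.integer(bundle$outcomes$event)
      out <- list(
        ers = diagnostic_table(ers$total[omap] > 1L, ev)
      )
      if (!anyNA(ratio_class)) {
        out$ratio <- diagnostic_table(ratio_class[omap] == "high", ev)
      }
      out
    })
  }

  structure(
    list(
      scores = data.frame(
        subject_id = profiles$subject_id,
        constellation = cons$constellation,
        ers_total = ers$total,
        ers_risk = ers$risk_class,
        ers_no_ratio_total = ers_nr$total,
        ers_no_ratio_risk = ers_nr$risk_class,
        ptau_ab42_ratio = ratio,
        ratio_risk = ratio_class
      ),
      calibration = calibration,
      crosstabs = crosstabs,
      model_table = model_table,
      lmm_fits = lmm_fits,
      risk = risk,
      diagnostics = diagnostics,
      stage_errors = stage_errors,
      provenance = list(
        n_subjects = nrow(profiles),
        panel_id = panel$panel_id,
        horizon = horizon,
        config_hash = options_hash(list(panel = unclass(panel),
                                        horizon = horizon)),
        package_version = as.character(utils::packageVersion("ersrisk"))
      )
    ),
    class = "ers_analysis_report"
  )
}

#' @export
print.ers_analysis_report <- function(x, ...) {
  cat("Erlangen Score vs pTau/Abeta1-42 ratio: analysis report\n")
  cat(sprintf("  cohort: %d subjects (panel %s, config %s)\n",
              x$provenance$n_subjects, x$provenance$panel_id,
              x$provenance$config_hash))
  tab <- table(x$scores$ers_risk)
  cat("  ERS risk classes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibrated pTau/Abeta1-42 cut-off: %.4g (J = %.3f)\n",
                x$calibration$cutoff, x$calibration$youden_j))
  }
  if (!is.null(x$model_table)) {
    cat("\nTrajectory model comparison:\n")
    print(x$model_table)
  }
  if (!is.null(x$risk)) {
    cat("\n")
    print(x$risk)
  }
  if (length(x$stage_errors)) {
    cat("\nFlagged stages:\n")
    for (nm in names(x$stage_errors)) {
      cat("  ", nm, ": ", x$stage_errors[[nm]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `scores.csv` (per-subject scores and classifications),
#' `crosstab_ers.csv` / `crosstab_ratio.csv`, `model_table.csv` (when
#' fitted) and `report.json` (calibration, AUCs, DeLong comparisons,
#' diagnostic tables and provenance).
#'
#' @param report An `ers_analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ers_analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$crosstabs$ers),
                   file.path(dir, "crosstab_ers.csv"))
  utils::write.csv(as.data.frame(report$crosstabs$ratio),
                   file.path(dir, "crosstab_ratio.csv"))
  if (!is.null(report$model_table)) {
    utils::write.csv(as.data.frame(report$model_table),
                     file.path(dir, "model_table.csv"), row.names = FALSE)
  }
  js <- list(
    calibration = if (!is.null(report$calibration)) unclass(report$calibration),
    auc = if (!is.null(report$risk)) report$risk$auc,
    delong = if (!is.null(report$risk)) {
      lapply(report$risk$delong, function(d) unclass(d))
    },
    diagnostics = lapply(report$diagnostics, unclass),
    stage_errors = report$stage_errors,
    provenance = report$provenance
  )
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
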