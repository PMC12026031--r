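#' pTau181/Abeta1-42 ratio
#'
#' @param ptau,ab42 Concentrations in pg/mL, positive, no missing values.
#' @return Numeric vector `ptau / ab42`.
#' @export
ptau_ab42_ratio <- function(ptau, ab42) {
  if (anyNA(ptau)) stop_field("ptau", "missing value; ratio undefined")
  if (anyNA(ab42)) stop_field("ab42", "missing value; ratio undefined")
  check_positive(ptau, "ptau")
  check_positive(ab42, "ab42")
  ptau / ab42
}

#' Calibrate a ratio cut-off by maximizing Youden's J
#'
#' Chooses the decision threshold for a marker that is higher in cases than
#' controls by maximizing the empirical Youden index
#' J = sensitivity + specificity - 1, where sensitivity is the fraction of
#' cases strictly above the threshold and specificity the fraction of
#' controls at or below it. Candidate thresholds are the midpoints between
#' consecutive distinct pooled values plus sentinels below and above all
#' observations, so the chosen cut-off never coincides with an observed
#' value. Ties in J are broken toward the candidate with the higher
#' specificity, then toward the smaller cut-off, which makes calibration
#' deterministic.
#'
#' In the intended use the cases are neurochemically definite AD profiles
#' (all four markers clearly pathological) and the controls biomarker-
#' negative profiles, and the marker is the pTau181/Abeta1-42 ratio;
#' nothing restricts the function to that marker.
#'
#' @param case_values,control_values Numeric marker values for cases and
#'   controls; both must be non-empty.
#' @return An object of class `youden_calibration`: list with `cutoff`,
#'   `youden_j`, `sensitivity`, `specificity`, `n_cases`, `n_controls`,
#'   `degenerate` (TRUE when the two samples are indistinguishable and
#'   J = 0).
#' @export
calibrate_youden <- function(case_values, control_values) {
  if (length(case_values) < 1L) stop_field("case_values", "needs >= 1 case")
  if (length(control_values) < 1L) stop_field("control_values", "needs >= 1 control")
  if (!all(is.finite(case_values))) stop_field("case_values", "must be finite")
  if (!all(is.finite(control_values))) stop_field("control_values", "must be finite")

  pooled <- sort(unique(c(case_values, control_values)))
  cand <- if (length(pooled) == 1L) {
    c(pooled - 1, pooled + 1)
  } else {
    c(pooled[1] - 1,
      (pooled[-1] + pooled[-length(pooled)]) / 2,
      pooled[length(pooled)] + 1)
  }
  sens <- vapply(cand, function(c_) mean(case_values > c_), numeric(1))
  spec <- vapply(cand, function(c_) mean(control_values <= c_), numeric(1))
  j <- sens + spec - 1

  # tie-break: max J, then max specificity, then smallest cut-off
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  best <- best[which.min(cand[best])]

  degenerate <- max(j) <= 0
  if (degenerate) {
    warning("degenerate separation: cases and controls are indistinguishable (J = 0)",
            call. = FALSE)
  }
  structure(
    list(
      cutoff = cand[best],
      youden_j = j[best],
      sensitivity = sens[best],
      specificity = spec[best],
      n_cases = length(case_values),
      n_controls = length(control_values),
      degenerate = degenerate
    ),
    class = "youden_calibration"
  )
}

#' @export
print.youden_calibration <- function(x, ...) {
  cat("Youden-index calibration\n")
  cat(sprintf("  cut-off      %.6g (high risk strictly above)\n", x$cutoff))
  cat(sprintf("  J            %.3f (sens %.3f, spec %.3f)\n",
              x$youden_j, x$sensitivity, x$specificity))
  cat(sprintf("  calibrated on %d cases / %d controls\n", x$n_cases, x$n_controls))
  if (isTRUE(x$degenerate)) cat("  WARNING: degenerate separation\n")
  invisible(x)
}

#' @export
coef.youden_calibration <- function(object, ...) {
  c(cutoff = object$cutoff, youden_j = object$youden_j,
    sensitivity = object$sensitivity, specificity = object$specificity)
}

#' Classify ratios against a calibrated cut-off
#'
#' High risk iff the ratio lies strictly above the calibrated cut-off;
#' a value exactly at the cut-off is low risk.
#'
#' @param ratio Numeric pTau/Abeta1-42 ratios.
#' @param calibration A [calibrate_youden()] result, or a bare numeric
#'   cut-off.
#' @return A data.frame with columns `ratio`, `cutoff`, `risk_class`
#'   (factor low/high).
#' @export
classify_ratio <- function(ratio, calibration) {
  cutoff <- if (inherits(calibration, "youden_calibration")) {
    calibration$cutoff
  } else if (is.numeric(calibration) && length(calibration) == 1L) {
    calibration
  } else {
    stop_field("calibration", "must be a youden_calibration or a numeric cut-off")
  }
  check_positive(ratio, "ratio")
  data.frame(
    ratio = ratio,
    cutoff = cutoff,
    risk_class = factor(ifelse(ratio > cutoff, "high", "low"),
                        levels = c("low", "high"))
  )
}
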