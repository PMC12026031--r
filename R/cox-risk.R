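#' Cox proportional-hazards model for conversion to dementia
#'
#' Fits a Cox model of time to dementia on a single per-subject risk score
#' (Breslow tie handling) and stores the Breslow baseline cumulative
#' hazard, so that time-dependent conversion probabilities can be
#' predicted at a fixed horizon. The fit is delegated to
#' [survival::coxph()]; monotone separation (all events beyond the range
#' of the covariate) is detected and flagged rather than silently
#' returning a diverging coefficient.
#'
#' @param outcomes Data.frame with `subject_id`, `event` (0/1 or logical),
#'   `time` (years, > 0).
#' @param score Per-subject risk score: vector named by subject id, or a
#'   data.frame with `subject_id` and a score column.
#' @param horizon Prediction horizon in years (default 10).
#' @return An object of class `ers_cox`: `beta`, `se`, `baseline_cumhaz`
#'   (data.frame `time`, `hazard`), `horizon`, `n`, `n_events`,
#'   `separation` flag and the underlying `coxph` fit.
#' @export
fit_conversion_cox <- function(outcomes, score, horizon = 10) {
  need <- c("subject_id", "event", "time")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) {
    stop_field("outcomes", paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  if (any(outcomes$time <= 0)) stop_field("time", "must be > 0")
  ev <- as.integer(outcomes$event)
  if (!all(ev %in% c(0L, 1L))) stop_field("event", "must be binary 0/1")
  if (sum(ev) < 1L) stop_field("event", "needs >= 1 event")
  x <- score_vector(score, outcomes$subject_id)
  if (stats::sd(x) == 0) stop_field("score", "covariate is constant")

  fit <- survival::coxph(survival::Surv(outcomes$time, ev) ~ x,
                         ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))[1]
  separation <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 100
  if (separation) {
    warning("monotone separation: the partial likelihood has no finite maximizer",
            call. = FALSE)
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(
    list(beta = beta, se = se,
         baseline_cumhaz = data.frame(time = bh$time, hazard = bh$hazard),
         horizon = horizon, n = length(ev), n_events = sum(ev),
         separation = separation, coxph = fit),
    class = "ers_cox"
  )
}

score_vector <- function(score, subject_id) {
  if (is.data.frame(score)) {
    val_col <- setdiff(names(score), "subject_id")[1]
    score <- stats::setNames(score[[val_col]], as.character(score$subject_id))
  }
  if (!is.null(names(score))) {
    absent <- setdiff(as.character(subject_id), names(score))
    if (length(absent)) {
      stop_field("score", paste("no score for subject(s):",
                                paste(utils::head(absent, 3), collapse = ", ")))
    }
    score <- score[as.character(subject_id)]
  } else if (length(score) != length(subject_id)) {
    stop_field("score", "length must match the outcome records")
  }
  as.numeric(score)
}

#' @export
print.ers_cox <- function(x, ...) {
  cat("Cox proportional-hazards model for conversion to dementia\n")
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  log hazard ratio per score unit: %.4f (SE %.4f, HR %.3f)\n",
              x$beta, x$se, exp(x$beta)))
  cat(sprintf("  horizon: %g years (baseline cumulative hazard %.4f)\n",
              x$horizon, baseline_cumhaz_at(x, x$horizon)))
  if (x$separation) cat("  WARNING: monotone separation, estimate unreliable\n")
  invisible(x)
}

#' @export
coef.ers_cox <- function(object, ...) c(beta = object$beta)

baseline_cumhaz_at <- function(fit, horizon) {
  bh <- fit$baseline_cumhaz
  if (horizon > max(bh$time)) {
    warning(sprintf(
      "horizon %g exceeds the last observed time %g; using the last cumulative-hazard step",
      horizon, max(bh$time)), call. = FALSE)
  }
  idx <- findInterval(horizon, bh$time)
  if (idx == 0L) 0 else bh$hazard[idx]
}

#' Predicted probability of conversion by the horizon
#'
#' `1 - S(h | x) = 1 - exp(-Lambda0(h) * exp(beta * x))` with the Breslow
#' baseline cumulative hazard `Lambda0`. Because the map from score to
#' probability is strictly increasing whenever `beta > 0`, ranking
#' subjects by predicted probability is identical to ranking them by the
#' raw score: the Cox step calibrates the probabilities but cannot change
#' empirical discrimination measures such as the AUC.
#'
#' @param fit An `ers_cox` fit.
#' @param score Numeric score value(s).
#' @param horizon Years; defaults to the fit's horizon.
#' @return Probabilities in `[0, 1]`.
#' @export
predict_event_probability <- function(fit, score, horizon = fit$horizon) {
  stopifnot(inherits(fit, "ers_cox"))
  1 - exp(-baseline_cumhaz_at(fit, horizon) * exp(fit$beta * as.numeric(score)))
}

#' Empirical ROC area under the curve
#'
#' Mann-Whitney estimate with half-credit for ties: the probability that a
#' randomly chosen event subject scores above a randomly chosen non-event
#' subject, counting ties as 1/2.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary event indicators (0/1 or logical), both classes
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(as.integer(labels))
  if (anyNA(scores) || anyNA(labels)) stop_field("scores", "missing values")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop_field("labels", "both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values ("structural components"): for each event subject the
# fraction of non-event subjects it outranks (ties 1/2), and vice versa
delong_components <- function(scores, labels) {
  xp <- scores[labels]
  xn <- scores[!labels]
  psi <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Non-parametric comparison of the AUCs of two risk scores measured on
#' the same subjects with the same event labels. Variances and the
#' covariance of the two empirical AUCs are estimated from the placement
#' values (structural components) of the event and non-event subjects;
#' the difference is referred to a standard normal.
#'
#' @param scores_a,scores_b Numeric scores for the identical subjects.
#' @param labels Binary event indicators.
#' @return An object of class `risk_comparison`: `auc_a`, `auc_b`,
#'   `var_a`, `var_b`, `cov_ab`, `z`, `p` (two-sided), `degenerate` flag
#'   (difference has zero estimated variance, e.g. identical scores).
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- as.logical(as.integer(labels))
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop_field("scores", "both score vectors and labels must have equal length")
  }
  if (sum(labels) == 0L || sum(!labels) == 0L) {
    stop_field("labels", "both classes must be present")
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  if (m == 1L) s10[] <- 0
  if (n == 1L) s01[] <- 0
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps
  z <- if (degenerate) NA_real_ else (ca$auc - cb$auc) / sqrt(var_diff)
  structure(
    list(auc_a = ca$auc, auc_b = cb$auc,
         var_a = S[1, 1], var_b = S[2, 2], cov_ab = S[1, 2],
         z = z, p = if (degenerate) NA_real_ else 2 * stats::pnorm(-abs(z)),
         degenerate = degenerate, n_events = m, n_nonevents = n),
    class = "risk_comparison"
  )
}

#' @export
print.risk_comparison <- function(x, ...) {
  cat("Paired DeLong AUC comparison\n")
  cat(sprintf("  AUC A %.4f vs AUC B %.4f (difference %+.4f)\n",
              x$auc_a, x$auc_b, x$auc_a - x$auc_b))
  if (x$degenerate) {
    cat("  degenerate comparison: zero variance of the AUC difference\n")
  } else {
    cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z, x$p))
  }
  invisible(x)
}

#' Diagnostic 2x2 summary of a binary risk call against conversion
#'
#' Cross-classifies the dichotomized risk score against the observed
#' conversion flag and reports sensitivity, specificity, positive and
#' negative likelihood ratios, and the diagnostic odds s ratio with its
#' Wald 95% confidence interval
#' `exp(log OR +/- 1.96 sqrt(1/tp + 1/fp + 1/fn + 1/tn))`.
#' When any cell is zero the Haldane-Anscombe 0.5 continuity correction
#' is applied to the OR and CI and the result is flagged `corrected`.
#'
#' @param predicted_high Logical (or 0/1) high-risk calls.
#' @param event Logical (or 0/1) conversion flags.
#' @return An object of class `diagnostic_table`.
#' @export
diagnostic_table <- function(predicted_high, event) {
  ph <- as.logical(as.integer(predicted_high))
  ev <- as.logical(as.integer(event))
  if (length(ph) != length(ev)) stop_field("predicted_high", "length mismatch")
  tp <- sum(ph & ev); fp <- sum(ph & !ev)
  fn <- sum(!ph & ev); tn <- sum(!ph & !ev)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  corrected <- any(c(tp, fp, fn, tn) == 0L)
  cc <- if (corrected) 0.5 else 0
  or <- ((tp + cc) * (tn + cc)) / ((fp + cc) * (fn + cc))
  se_log <- sqrt(1 / (tp + cc) + 1 / (fp + cc) + 1 / (fn + cc) + 1 / (tn + cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = sens, specificity = spec,
         lr_pos = sens / (1 - spec), lr_neg = (1 - sens) / spec,
         odds_ratio = or, or_ci = ci, corrected = corrected),
    class = "diagnostic_table"
  )
}

#' @export
print.diagnostic_table <- function(x, ...) {
  cat("Diagnostic 2x2 summary\n")
  cat(sprintf("  tp %d  fp %d  fn %d  tn %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  LR+ %.3f  LR- %.3f\n", x$lr_pos, x$lr_neg))
  cat(sprintf("  diagnostic OR %.4g, 95%% CI (%.4g, %.4g)%s\n",
              x$odds_ratio, x$or_ci[1], x$or_ci[2],
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Compare several risk scores as predictors of conversion to dementia
#'
#' For each supplied score this fits the conversion Cox model, predicts
#' the conversion probability at the horizon and computes the empirical
#' AUC of those probabilities against observed conversion; every
#' non-reference score is then compared against the first (reference)
#' score by the paired DeLong test.
#'
#' @param scores Named list (or data.frame) of per-subject numeric scores,
#'   aligned with `outcomes$subject_id` or named by subject id.
#' @param outcomes Outcome records as in [fit_conversion_cox()].
#' @param horizon Prediction horizon in years.
#' @return An object of class `risk_score_comparison`: `auc` table,
#'   `delong` list of pairwise comparisons against the reference, and the
#'   per-score `ers_cox` fits.
#' @export
compare_risk_scores <- function(scores, outcomes, horizon = 10) {
  if (is.data.frame(scores)) {
    scores <- as.list(scores[setdiff(names(scores), "subject_id")])
  }
  stopifnot(is.list(scores), length(scores) >= 1L, !is.null(names(scores)))
  ev <- as.integer(outcomes$event)
  fits <- lapply(scores, function(s) fit_conversion_cox(outcomes, s, horizon))
  probs <- lapply(names(scores), function(nm) {
    predict_event_probability(fits[[nm]], score_vector(scores[[nm]], outcomes$subject_id))
  })
  names(probs) <- names(scores)
  auc <- vapply(probs, roc_auc, numeric(1), labels = ev)
  ref <- names(scores)[1]
  delong <- if (length(scores) > 1L) {
    lapply(names(scores)[-1], function(nm) {
      delong_compare(probs[[ref]], probs[[nm]], ev)
    })
  } else {
    list()
  }
  names(delong) <- if (length(scores) > 1L) {
    paste(ref, "vs", names(scores)[-1])
  } else {
    character(0)
  }
  structure(
    list(auc = data.frame(score = names(scores), auc = unname(auc),
                          beta = vapply(fits, `[[`, numeric(1), "beta"),
                          row.names = NULL),
         delong = delong, fits = fits, probabilities = probs,
         horizon = horizon, reference = ref),
    class = "risk_score_comparison"
  )
}

#' @export
print.risk_score_comparison <- function(x, ...) {
  cat(sprintf("Risk-score comparison (Cox probabilities at %g years)\n", x$horizon))
  tab <- x$auc
  tab$auc <- round(tab$auc, 4)
  tab$beta <- round(tab$beta, 4)
  print.data.frame(tab, row.names = FALSE)
  for (nm in names(x$delong)) {
    d <- x$delong[[nm]]
    cat(sprintf("  %s: AUC %.4f vs %.4f, %s\n", nm, d$auc_a, d$auc_b,
                if (d$degenerate) "degenerate" else sprintf("p = %.4g", d$p)))
  }
  invisible(x)
}
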