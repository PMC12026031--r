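#' Reference constellation counts of the 259-subject cross-tabulation
#'
#' Column totals of the published constellation cross-tabulation, in the
#' order of [observed_constellations()]: 87 biomarker-negative subjects,
#' the Alzheimer's-continuum constellations (including 58 with isolated
#' amyloid-ratio positivity plus tau pathology and 30 with the full
#' concordant AD profile), and 63 SNAP subjects. They sum to 259.
#'
#' @return Named integer vector of length 13.
#' @export
table1_counts <- function() {
  stats::setNames(
    c(87L, 1L, 5L, 5L, 3L, 2L, 2L, 3L, 58L, 30L, 9L, 18L, 36L),
    observed_constellations()
  )
}

#' Configuration of the synthetic memory-clinic cohort
#'
#' The defaults reproduce the statistical structure the analysis assumes:
#' 259 subjects with constellation frequencies equal to the reference
#' cross-tabulation totals, MMSE z-score trajectories following the
#' random-intercept-and-slope AR(1) model at the published binary-score
#' fixed effects, annual visits truncated at a follow-up drawn from a
#' distribution with median 3.25 years and IQR 4.9, and exponential
#' conversion hazards calibrated so that about 31% of subjects convert
#' to dementia (81/259 in the reference cohort).
#'
#' @param n_subjects Cohort size.
#' @param constellation_weights Probabilities over the 13 observed
#'   constellations (normalized internally).
#' @param borderline_probability Per-marker probability that a generated
#'   value lands in the borderline band instead of the clear zone.
#' @param lmm_truth List: `beta` (intercept, time slope, group effect,
#'   group-by-time effect, z-units and z-units/year), `var_u0`, `var_u1`,
#'   `cov_u01`, `rho`, `var_e`.
#' @param hazard_truth List: `baseline_rate` (events/year in the low-risk
#'   group) and `log_hr` (log hazard ratio of the high-risk group).
#' @param panel An [assay_panel()] for value placement.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 259,
                          constellation_weights = table1_counts(),
                          borderline_probability = 0,
                          lmm_truth = list(beta = c(-1.30, -0.07, -0.40, -0.40),
                                           var_u0 = 1.0, var_u1 = 0.02,
                                           cov_u01 = 0, rho = 0.3,
                                           var_e = 0.25),
                          hazard_truth = list(baseline_rate = 0.0554,
                                              log_hr = log(3)),
                          panel = default_panel()) {
  stopifnot(n_subjects >= 1,
            length(constellation_weights) == 13L,
            all(constellation_weights >= 0), sum(constellation_weights) > 0,
            borderline_probability >= 0, borderline_probability <= 1)
  if (is.null(names(constellation_weights))) {
    names(constellation_weights) <- observed_constellations()
  }
  check_varcomp(lmm_truth)
  structure(
    list(n_subjects = as.integer(n_subjects),
         constellation_weights = constellation_weights / sum(constellation_weights),
         borderline_probability = borderline_probability,
         lmm_truth = lmm_truth,
         hazard_truth = hazard_truth,
         panel = panel),
    class = "cohort_config"
  )
}

#' Sample follow-up durations
#'
#' Draws follow-up lengths (years) from a piecewise-linear quantile
#' function through (0, 1), (0.25, 1.6), (0.5, 3.25), (0.75, 6.5),
#' (1, 13): the population median is exactly 3.25 years and the IQR
#' exactly 4.9, on the eligible range 1-13 years.
#'
#' @param n Number of draws.
#' @return Numeric vector of follow-up durations in years.
#' @export
sample_followup <- function(n) {
  stats::approx(x = c(0, 0.25, 0.5, 0.75, 1),
                y = c(1, 1.6, 3.25, 6.5, 13),
                xout = stats::runif(n))$y
}

# draw one analyte value in the requested zone; "clear" keeps a 2% margin
# inside the open zone so scored results are never edge cases
draw_marker <- function(n, cutoff, direction, pathological, borderline, f) {
  stopifnot(length(pathological) == n, length(borderline) == n)
  lo_band <- cutoff * (1 - f)
  hi_band <- cutoff * (1 + f)
  loguni <- function(lo, hi) exp(stats::runif(length(lo), log(lo), log(hi)))
  path_clear <- if (direction == "low_is_pathological") {
    loguni(rep(0.40 * lo_band, n), rep(0.98 * lo_band, n))
  } else {
    loguni(rep(1.02 * hi_band, n), rep(2.50 * hi_band, n))
  }
  norm_clear <- if (direction == "low_is_pathological") {
    loguni(rep(1.02 * hi_band, n), rep(2.50 * hi_band, n))
  } else {
    loguni(rep(0.40 * lo_band, n), rep(0.98 * lo_band, n))
  }
  u <- stats::runif(n, 0.001, 0.999)
  path_border <- if (direction == "low_is_pathological") {
    lo_band + u * (cutoff - lo_band)    # (c(1-f), c): borderline, binary path
  } else {
    cutoff + u * (hi_band - cutoff)     # (c, c(1+f)): borderline, binary path
  }
  norm_border <- if (direction == "low_is_pathological") {
    cutoff + u * (hi_band - cutoff)     # [c, c(1+f)): borderline, binary normal
  } else {
    lo_band + u * (cutoff - lo_band)
  }
  ifelse(borderline,
         ifelse(pathological, path_border, norm_border),
         ifelse(pathological, path_clear, norm_clear))
}

#' Generate synthetic CSF biomarker profiles
#'
#' Draws a constellation per subject from the configured weights, then
#' places each analyte log-uniformly inside the zone the constellation
#' requires: clearly normal or clearly pathological (more than the
#' borderline fraction past the cut-off), or, with probability
#' `borderline_probability` per marker, inside the borderline half-band
#' on the constellation's side of the cut-off. Abeta1-40 is set so the
#' amyloid ratio lands clearly on the constellation's R side. By
#' construction, [constellation_of()] recovers the requested
#' constellation exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return Data.frame of profiles with the requested `constellation`.
#' @export
generate_biomarkers <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  panel <- config$panel
  f <- panel$borderline_fraction
  lab <- sample(names(config$constellation_weights), n, replace = TRUE,
                prob = config$constellation_weights)
  R <- substr(lab, 2, 2) == "+"
  A <- substr(lab, 4, 4) == "+"
  T_ <- substr(lab, 6, 6) == "+"
  N <- substr(lab, 8, 8) == "+"
  bp <- config$borderline_probability
  bl <- function() stats::runif(n) < bp
  ab42 <- draw_marker(n, panel$ab42_cutoff, "low_is_pathological", A, bl(), f)
  ptau <- draw_marker(n, panel$ptau_cutoff, "high_is_pathological", T_, bl(), f)
  ttau <- draw_marker(n, panel$ttau_cutoff, "high_is_pathological", N, bl(), f)
  ratio <- ifelse(R,
                  stats::runif(n, 0.5, 0.9) * panel$amyloid_ratio_cutoff,
                  stats::runif(n, 1.1, 2.0) * panel$amyloid_ratio_cutoff)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    ab42 = ab42, ab40 = ab42 / ratio, ptau = ptau, ttau = ttau,
    panel_id = panel$panel_id,
    constellation = lab
  )
}

#' Deterministic 259-subject fixture with the reference constellation counts
#'
#' Builds a clear-value cohort whose constellation counts equal
#' [table1_counts()] exactly: every analyte sits at a fixed representative
#' point more than 10% beyond its cut-off on the side its constellation
#' requires (0.5x / 1.5x the cut-off), so zone scores are unambiguous.
#' With `borderline_variant = TRUE` one subject with isolated
#' amyloid-ratio positivity plus tau pathology (R+A-T+N+) additionally
#' has Abeta1-42 placed in the borderline-normal band (1.05x its
#' cut-off), which lifts that subject's Erlangen Score from 3 to the
#' maximum of 4 -- the one cell of the reference cross-tabulation that
#' requires a borderline value.
#'
#' @param borderline_variant Place the single borderline subject (see
#'   above).
#' @param panel An [assay_panel()].
#' @return Data.frame of 259 profiles (no randomness involved).
#' @export
table1_fixture <- function(borderline_variant = FALSE, panel = default_panel()) {
  counts <- table1_counts()
  lab <- rep(names(counts), counts)
  R <- substr(lab, 2, 2) == "+"
  A <- substr(lab, 4, 4) == "+"
  T_ <- substr(lab, 6, 6) == "+"
  N <- substr(lab, 8, 8) == "+"
  ab42 <- ifelse(A, 0.5, 1.5) * panel$ab42_cutoff
  ptau <- ifelse(T_, 1.5, 0.5) * panel$ptau_cutoff
  ttau <- ifelse(N, 1.5, 0.5) * panel$ttau_cutoff
  ratio <- ifelse(R, 0.7, 1.4) * panel$amyloid_ratio_cutoff
  if (borderline_variant) {
    pick <- which(lab == "R+A-T+N+")[1]
    ab42[pick] <- 1.05 * panel$ab42_cutoff
  }
  data.frame(
    subject_id = sprintf("T%04d", seq_along(lab)),
    ab42 = ab42, ab40 = ab42 / ratio, ptau = ptau, ttau = ttau,
    panel_id = panel$panel_id,
    constellation = lab
  )
}

#' Generate longitudinal MMSE z-score visits
#'
#' Simulates annual visits at times 0, 1, 2, ... years, truncated at each
#' subject's follow-up end, from the mixed model documented in
#' [lmm_loglik()]: subject-level random intercept and slope drawn from
#' the configured covariance, stationary AR(1) residuals over the visit
#' order, and the fixed-effect mean using the binary group indicator
#' (1 = pathologic).
#'
#' @param subjects Data.frame with `subject_id`, `group` (factor or
#'   character; the *second* sorted level is the pathologic one, e.g.
#'   `"normal"`/`"pathologic"`) and `followup` (years).
#' @param config A [cohort_config()] supplying `lmm_truth`.
#' @param seed Optional integer seed.
#' @return Data.frame of visit records `subject_id`, `time`, `zmmse`.
#' @export
generate_trajectories <- function(subjects, config, seed = NULL) {
  stopifnot(all(c("subject_id", "group", "followup") %in% names(subjects)))
  if (!is.null(seed)) set.seed(seed)
  tr <- config$lmm_truth
  g <- as.integer(factor(subjects$group)) - 1L
  if (any(g > 1L)) stop_field("group", "trajectory truth is defined for two groups")
  G <- matrix(c(tr$var_u0, tr$cov_u01, tr$cov_u01, tr$var_u1), 2, 2)
  cg <- chol(G + diag(1e-12, 2))
  out <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    t_ <- seq(0, floor(subjects$followup[i]))
    u <- drop(crossprod(cg, stats::rnorm(2)))
    mu <- tr$beta[1] + tr$beta[2] * t_ + tr$beta[3] * g[i] + tr$beta[4] * g[i] * t_
    out[[i]] <- data.frame(
      subject_id = subjects$subject_id[i],
      time = t_,
      zmmse = mu + u[1] + u[2] * t_ + ar1_series(length(t_), tr$rho, tr$var_e)
    )
  }
  do.call(rbind, out)
}

#' Generate time-to-dementia outcomes
#'
#' Exponential conversion times with rate
#' `baseline_rate * exp(log_hr * group)` (group indicator 1 = pathologic),
#' censored at the subject's follow-up end; `event` records whether
#' conversion preceded censoring.
#'
#' @inheritParams generate_trajectories
#' @return Data.frame `subject_id`, `event` (0/1), `time` (years).
#' @export
generate_outcomes <- function(subjects, config, seed = NULL) {
  stopifnot(all(c("subject_id", "group", "followup") %in% names(subjects)))
  if (!is.null(seed)) set.seed(seed)
  hz <- config$hazard_truth
  g <- as.integer(factor(subjects$group)) - 1L
  rate <- hz$baseline_rate * exp(hz$log_hr * g)
  n <- nrow(subjects)
  tt <- if (all(rate == 0)) rep(Inf, n) else stats::rexp(n, pmax(rate, 1e-300))
  tt[rate == 0] <- Inf
  event <- tt <= subjects$followup
  data.frame(
    subject_id = subjects$subject_id,
    event = as.integer(event),
    time = pmin(tt, subjects$followup)
  )
}

#' Generate a complete synthetic cohort
#'
#' Draws biomarker profiles, scores them with the Erlangen Score to
#' assign the binary risk group, then simulates follow-up durations,
#' annual MMSE z-score visits and conversion outcomes. Output is fully
#' determined by `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (required for reproducibility).
#' @return An object of class `synthetic_cohort`: `profiles`, `groups`
#'   (per-subject group labels, Erlangen Score totals and follow-up),
#'   `visits`, `outcomes`, and the `config` echo.
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  profiles <- generate_biomarkers(config)
  ers <- ers_score(profiles, config$panel)
  subjects <- data.frame(
    subject_id = profiles$subject_id,
    group = factor(ifelse(ers$total > 1L, "pathologic", "normal"),
                   levels = c("normal", "pathologic")),
    ers_total = ers$total,
    followup = sample_followup(config$n_subjects)
  )
  visits <- generate_trajectories(subjects, config)
  outcomes <- generate_outcomes(subjects, config)
  structure(
    list(profiles = profiles, groups = subjects, visits = visits,
         outcomes = outcomes, config = config, seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic memory-clinic cohort (seed", x$seed, ")\n")
  cat(sprintf("  %d subjects, %d visits, %d conversions (%.1f%%)\n",
              nrow(x$groups), nrow(x$visits), sum(x$outcomes$event),
              100 * mean(x$outcomes$event)))
  cat("  risk groups:",
      paste(names(table(x$groups$group)), table(x$groups$group),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
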