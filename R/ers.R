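#' Tau sub-score: the higher of the pTau181 and total-tau zone scores
#'
#' Both tau markers are zone-scored against their own cut-offs (pathological
#' above); when they disagree the higher score carries, so a single clearly
#' elevated tau marker is enough for the maximum tau sub-score.
#'
#' @param ptau_score,ttau_score Integer zone scores in 0..2 from
#'   [classify_marker_zone()] with `high_is_pathological`.
#' @return Integer vector of tau sub-scores in 0..2.
#' @export
tau_subscore <- function(ptau_score, ttau_score) {
  stopifnot(all(ptau_score %in% 0:2), all(ttau_score %in% 0:2))
  as.integer(pmax(ptau_score, ttau_score))
}

#' Compute the Erlangen Score for a cohort of CSF profiles
#'
#' The Erlangen Score is an ordinal 0-4 CSF risk score. Abeta1-42
#' (amyloidopathy, pathological below its cut-off) and the tau pair
#' (pTau181 / total tau, pathological above, max rule) are each zone-scored
#' 0 (clearly normal), 1 (borderline, within +/-10% of the cut-off) or
#' 2 (clearly pathological); their sum ranges 0-4. When the
#' Abeta1-42/Abeta1-40 ratio is available it then adjusts the sum by +1
#' (ratio pathological) or -1 (ratio normal), and totals falling outside
#' 0-4 are clamped back to 0 or 4. A total above 1 is considered suspicious
#' for Alzheimer's disease ("high risk"). Without the ratio the unadjusted
#' sum is reported on a three-level risk scale: low (0-1), medium (2),
#' high (3-4).
#'
#' @param profiles A data.frame with columns `ab42`, `ptau`, `ttau` and
#'   optionally `ab40` and `subject_id`. All concentrations in pg/mL;
#'   `ab42`, `ptau`, `ttau` must be present and positive for every row.
#' @param panel An [assay_panel()] supplying the cut-offs.
#' @param use_ratio If `FALSE`, compute the ratio-free variant even when
#'   `ab40` is available.
#' @return An object of class `ers_score`: a data.frame with one row per
#'   profile and columns `subject_id`, `amyloid_subscore`, `tau_subscore`,
#'   `sum_score`, `ratio_adjustment` (0 only when the ratio is
#'   unavailable), `total`, `risk_class` (factor low/medium/high; medium
#'   only occurs without the ratio) and `suspicious_for_ad` (total > 1).
#' @examples
#' p <- default_panel()
#' ers_score(data.frame(ab42 = 450, ab40 = 12000, ptau = 90, ttau = 650), p)
#' @export
ers_score <- function(profiles, panel = default_panel(), use_ratio = TRUE) {
  for (col in c("ab42", "ptau", "ttau")) {
    if (!col %in% names(profiles)) {
      stop_field("profiles", paste("missing required column:", col))
    }
    if (anyNA(profiles[[col]])) {
      stop_field(col, "must be present for every subject (score undefined)")
    }
    check_positive(profiles[[col]], col)
  }
  if (!"ab40" %in% names(profiles)) profiles$ab40 <- NA_real_
  f <- panel$borderline_fraction

  a <- classify_marker_zone(profiles$ab42, panel$ab42_cutoff,
                            "low_is_pathological", f)$score
  t_ <- tau_subscore(
    classify_marker_zone(profiles$ptau, panel$ptau_cutoff,
                         "high_is_pathological", f)$score,
    classify_marker_zone(profiles$ttau, panel$ttau_cutoff,
                         "high_is_pathological", f)$score
  )
  sum_score <- a + t_

  ratio_path <- if (use_ratio) {
    amyloid_ratio_status(profiles$ab42, profiles$ab40, panel)
  } else {
    rep(NA, nrow(profiles))
  }
  adj <- ifelse(is.na(ratio_path), 0L, ifelse(ratio_path, 1L, -1L))
  total <- as.integer(clamp(sum_score + adj, 0L, 4L))

  risk <- ifelse(
    is.na(ratio_path),
    c("low", "low", "medium", "high", "high")[total + 1L],
    ifelse(total > 1L, "high", "low")
  )
  out <- data.frame(
    subject_id = profiles$subject_id %||% as.character(seq_len(nrow(profiles))),
    amyloid_subscore = as.integer(a),
    tau_subscore = t_,
    sum_score = as.integer(sum_score),
    ratio_adjustment = as.integer(adj),
    total = total,
    risk_class = factor(risk, levels = c("low", "medium", "high")),
    suspicious_for_ad = total > 1L
  )
  class(out) <- c("ers_score", "data.frame")
  out
}

#' @export
print.ers_score <- function(x, ...) {
  cat("Erlangen Score results for", nrow(x), "subject(s)\n")
  tab <- table(factor(x$total, levels = 0:4))
  cat("  score distribution:",
      paste(sprintf("%d:%d", 0:4, as.integer(tab)), collapse = "  "), "\n")
  cat("  high risk (total > 1):", sum(x$suspicious_for_ad), "\n\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, "more rows )\n")
  invisible(x)
}

#' Cross-tabulate constellations against a risk classification
#'
#' Reproduces the layout of the published cross-tabulation: one column per
#' observed ATN(R) constellation, one row per classifier level.
#'
#' @param constellation Character labels from [constellation_of()].
#' @param classification Factor or vector of classifier levels (e.g. ERS
#'   totals or low/high calls).
#' @return A table with a `Total` column appended.
#' @export
constellation_crosstab <- function(constellation, classification) {
  lev <- union(observed_constellations(), unique(constellation))
  tab <- table(
    classification,
    factor(constellation, levels = lev),
    dnn = c("class", "constellation")
  )
  cbind(tab, Total = rowSums(tab))
}
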