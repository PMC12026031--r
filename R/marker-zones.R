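#' Three-zone classification of a CSF marker against its cut-off
#'
#' Partitions the positive axis into three zones around an assay cut-off
#' `c` with borderline half-width `f*c`: clearly normal (score 0),
#' borderline (score 1, within the closed band `[c*(1-f), c*(1+f)]`), and
#' clearly pathological (score 2, more than `f*c` past the cut-off in the
#' pathological direction). Alongside the ordinal zone score the plain
#' binary status is returned: pathological iff the value is *strictly*
#' past the cut-off in the pathological direction, so a borderline value
#' can sit on either side of the binary cut. Values exactly on a zone edge
#' (`c`, `c*(1-f)`, `c*(1+f)`) fall in the borderline zone, and a value
#' exactly at `c` is binary-normal. These tie conventions are a package
#' choice; the scoring convention itself does not fix them.
#'
#' @param value Measured concentration(s), positive.
#' @param cutoff Assay decision limit, positive scalar.
#' @param direction `"low_is_pathological"` (Abeta1-42, amyloid ratio) or
#'   `"high_is_pathological"` (pTau181, total tau).
#' @param borderline_fraction Borderline half-width as a fraction of the
#'   cut-off (default 0.10).
#'
#' @return A data.frame with one row per value: `score` (integer 0/1/2) and
#'   `pathological` (logical binary status).
#' @examples
#' classify_marker_zone(c(700, 630, 500), 600, "low_is_pathological")
#' @export
classify_marker_zone <- function(value, cutoff,
                                 direction = c("low_is_pathological",
                                               "high_is_pathological"),
                                 borderline_fraction = 0.10) {
  direction <- match.arg(direction)
  check_positive(value, "value")
  check_positive(cutoff, "cutoff")
  if (length(cutoff) != 1L) stop_field("cutoff", "must be a scalar")
  if (!is.numeric(borderline_fraction) || borderline_fraction <= 0 ||
      borderline_fraction >= 1) {
    stop_field("borderline_fraction", "must lie strictly between 0 and 1")
  }
  lo <- cutoff * (1 - borderline_fraction)
  hi <- cutoff * (1 + borderline_fraction)
  if (direction == "low_is_pathological") {
    score <- ifelse(value > hi, 0L, ifelse(value < lo, 2L, 1L))
    pathological <- value < cutoff
  } else {
    score <- ifelse(value < lo, 0L, ifelse(value > hi, 2L, 1L))
    pathological <- value > cutoff
  }
  data.frame(score = score, pathological = pathological)
}

#' Binary amyloid-ratio status
#'
#' Classifies the Abeta1-42/Abeta1-40 ratio as pathological iff it lies
#' strictly below the panel's ratio cut-off. When Abeta1-40 was not
#' measured the ratio is unavailable and `NA` is returned (not a default
#' classification).
#'
#' @param ab42,ab40 Concentrations in pg/mL; `ab40` may be `NA`.
#' @param panel An [assay_panel()].
#' @return Logical vector: `TRUE` pathological, `FALSE` normal, `NA`
#'   ratio unavailable.
#' @export
amyloid_ratio_status <- function(ab42, ab40, panel = default_panel()) {
  check_positive(ab42, "ab42")
  check_positive(ab40, "ab40", allow_na = TRUE)
  ifelse(is.na(ab40), NA, (ab42 / ab40) < panel$amyloid_ratio_cutoff)
}

#' ATN(R) constellation of a biomarker profile
#'
#' Derives the four binary flags of the extended ATN scheme from the plain
#' cut-offs: R (amyloid ratio pathological), A (Abeta1-42 pathological,
#' i.e. below its cut-off), T (pTau181 above its cut-off), N (total tau
#' above its cut-off). All 16 combinations are representable; R is `NA`
#' when Abeta1-40 is missing.
#'
#' @param profiles A data.frame with columns `ab42`, `ab40`, `ptau`, `ttau`
#'   (any extra columns are carried through untouched).
#' @param panel An [assay_panel()].
#' @return The input data.frame with logical columns `R`, `A`, `T_`, `N`
#'   and a character `constellation` label such as `"R+A-T+N+"` appended.
#'   The tau flag column is named `T_` to avoid masking `TRUE`'s alias.
#' @export
constellation_of <- function(profiles, panel = default_panel()) {
  need <- c("ab42", "ptau", "ttau")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    stop_field("profiles", paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  if (!"ab40" %in% names(profiles)) profiles$ab40 <- NA_real_
  profiles$R <- amyloid_ratio_status(profiles$ab42, profiles$ab40, panel)
  profiles$A <- profiles$ab42 < panel$ab42_cutoff
  profiles$T_ <- profiles$ptau > panel$ptau_cutoff
  profiles$N <- profiles$ttau > panel$ttau_cutoff
  profiles$constellation <- constellation_label(
    profiles$R, profiles$A, profiles$T_, profiles$N
  )
  profiles
}

#' Format ATN(R) flags as a constellation label
#'
#' @param R,A,T_,N Logical flags; `R` may be `NA` (rendered `R?`).
#' @return Character labels like `"R+A-T+N+"`.
#' @export
constellation_label <- function(R, A, T_, N) {
  sgn <- function(x) ifelse(is.na(x), "?", ifelse(x, "+", "-"))
  paste0("R", sgn(R), "A", sgn(A), "T", sgn(T_), "N", sgn(N))
}

#' The 13 constellations observed in the reference cross-tabulation
#'
#' Column order of the published cross-tabulation: biomarker-negative,
#' the Alzheimer's-continuum constellations, then the three SNAP
#' (suspected non-Alzheimer pathology) constellations.
#'
#' @return Character vector of 13 labels.
#' @export
observed_constellations <- function() {
  c("R-A-T-N-",
    "R+A-T-N-", "R-A+T-N-", "R+A+T-N-", "R+A-T-N+", "R+A+T-N+",
    "R+A-T+N-", "R+A+T+N-", "R+A-T+N+", "R+A+T+N+",
    "R-A-T-N+", "R-A-T+N-", "R-A-T+N+")
}

#' SNAP constellations (normal amyloid, pathological tau markers)
#' @return Character vector of the three SNAP labels.
#' @export
snap_constellations <- function() c("R-A-T-N+", "R-A-T+N-", "R-A-T+N+")
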