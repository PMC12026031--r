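#' Assay panel: decision limits for the four CSF analytes and both ratios
#'
#' An assay panel bundles the decision limits (cut-offs) of one immunoassay
#' platform for the markers entering the Erlangen Score and the two ratio
#' classifiers. Cut-off values are platform-specific and supplied by the
#' user; the defaults describe a plausible synthetic platform, not any
#' particular commercial assay.
#'
#' Pathological sides are fixed by biology: Abeta1-42 and the
#' Abeta1-42/Abeta1-40 ratio are pathological *below* their cut-offs
#' (amyloidopathy lowers them), pTau181 and total tau *above* theirs.
#' The `borderline_fraction` is the half-width of the borderline band
#' around each analyte cut-off as a fraction of the cut-off (10% by
#' convention).
#'
#' @param panel_id Character label identifying the platform.
#' @param ab42_cutoff Abeta1-42 decision limit in pg/mL (pathological below).
#' @param ptau_cutoff pTau181 decision limit in pg/mL (pathological above).
#' @param ttau_cutoff Total tau decision limit in pg/mL (pathological above).
#' @param amyloid_ratio_cutoff Abeta1-42/Abeta1-40 decision limit
#'   (dimensionless, pathological below). 0.05 is the conventional manual
#'   immunoassay value; automated platforms use 0.06.
#' @param ptau_ab42_cutoff Optional pTau/Abeta1-42 decision limit
#'   (pathological above); usually produced by [calibrate_youden()] rather
#'   than supplied directly.
#' @param borderline_fraction Half-width of the borderline zone as a
#'   fraction of the cut-off, in (0, 1).
#'
#' @return An object of class `assay_panel` (a named list).
#' @seealso [classify_marker_zone()], [ers_score()], [default_panel()]
#' @export
assay_panel <- function(panel_id,
                        ab42_cutoff,
                        ptau_cutoff,
                        ttau_cutoff,
                        amyloid_ratio_cutoff = 0.05,
                        ptau_ab42_cutoff = NULL,
                        borderline_fraction = 0.10) {
  if (!is.character(panel_id) || length(panel_id) != 1L || !nzchar(panel_id)) {
    stop_field("panel_id", "must be a non-empty string")
  }
  check_positive(ab42_cutoff, "ab42_cutoff")
  check_positive(ptau_cutoff, "ptau_cutoff")
  check_positive(ttau_cutoff, "ttau_cutoff")
  check_positive(amyloid_ratio_cutoff, "amyloid_ratio_cutoff")
  if (!is.null(ptau_ab42_cutoff)) {
    check_positive(ptau_ab42_cutoff, "ptau_ab42_cutoff")
  }
  if (!is.numeric(borderline_fraction) || length(borderline_fraction) != 1L ||
      borderline_fraction <= 0 || borderline_fraction >= 1) {
    stop_field("borderline_fraction", "must lie strictly between 0 and 1")
  }
  structure(
    list(
      panel_id = panel_id,
      ab42_cutoff = ab42_cutoff,
      ptau_cutoff = ptau_cutoff,
      ttau_cutoff = ttau_cutoff,
      amyloid_ratio_cutoff = amyloid_ratio_cutoff,
      ptau_ab42_cutoff = ptau_ab42_cutoff,
      borderline_fraction = borderline_fraction
    ),
    class = "assay_panel"
  )
}

#' Default synthetic assay panel
#'
#' Concentration scales (Abeta1-42 600 pg/mL, pTau181 60 pg/mL, total tau
#' 400 pg/mL, amyloid ratio 0.05) are plausible round numbers for a manual
#' ELISA platform; real platform cut-offs should be supplied through
#' [assay_panel()] or a panel configuration file.
#'
#' @return An `assay_panel`.
#' @export
default_panel <- function() {
  assay_panel(
    panel_id = "synthetic-elisa",
    ab42_cutoff = 600,
    ptau_cutoff = 60,
    ttau_cutoff = 400,
    amyloid_ratio_cutoff = 0.05
  )
}

#' @export
print.assay_panel <- function(x, ...) {
  cat("Assay panel:", x$panel_id, "\n")
  cat(sprintf("  Abeta1-42 cut-off      %8.4g pg/mL (pathological below)\n",
              x$ab42_cutoff))
  cat(sprintf("  pTau181 cut-off        %8.4g pg/mL (pathological above)\n",
              x$ptau_cutoff))
  cat(sprintf("  total tau cut-off      %8.4g pg/mL (pathological above)\n",
              x$ttau_cutoff))
  cat(sprintf("  amyloid ratio cut-off  %8.4g (pathological below)\n",
              x$amyloid_ratio_cutoff))
  if (!is.null(x$ptau_ab42_cutoff)) {
    cat(sprintf("  pTau/Abeta1-42 cut-off %8.4g (pathological above)\n",
                x$ptau_ab42_cutoff))
  }
  cat(sprintf("  borderline band        +/-%d%% of cut-off\n",
              round(100 * x$borderline_fraction)))
  invisible(x)
}

#' Read a panel configuration file
#'
#' Reads a YAML or JSON file describing one or more assay panels and an
#' optional panel priority list. The file must contain a `panels` list of
#' [assay_panel()] field sets and may contain `panel_priority`, a character
#' vector ordered from most to least preferred platform (used by
#' [read_cohort_tables()] to pick one row per subject when several panels
#' measured the same subject).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `panels` (named list of `assay_panel`) and
#'   `panel_priority` (character).
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_field("path", "reading YAML panel configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (is.null(raw$panels)) stop_field("panels", "config must contain a 'panels' list")
  panels <- lapply(raw$panels, function(p) {
    do.call(assay_panel, p[intersect(names(p), names(formals(assay_panel)))])
  })
  names(panels) <- vapply(panels, `[[`, character(1), "panel_id")
  priority <- unlist(raw$panel_priority) %||% names(panels)
  unknown <- setdiff(priority, names(panels))
  if (length(unknown)) {
    stop_field("panel_priority", paste("unknown panel id(s):",
                                       paste(unknown, collapse = ", ")))
  }
  list(panels = panels, panel_priority = priority)
}
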