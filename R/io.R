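# Delimited-text readers/writers for the three cohort tables.
# Dialect: UTF-8, comma-separated, header row, "." decimal. Decimal-comma
# numerics (the source cohorts are often German) are rejected loudly
# rather than guessed.

read_cohort_csv <- function(path, numeric_cols, table_name) {
  if (!file.exists(path)) stop_field(table_name, paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in numeric_cols) {
    if (!col %in% names(df)) next
    v <- df[[col]]
    if (is.character(v)) {
      commas <- grepl(",", v, fixed = TRUE)
      if (any(commas)) {
        stop_field(table_name, sprintf(
          "column '%s' uses a decimal comma (first at line %d); re-export with '.' decimals",
          col, which(commas)[1] + 1L))
      }
      suppressWarnings(num <- as.numeric(v))
      bad <- !is.na(v) & v != "" & is.na(num)
      if (any(bad)) {
        stop_field(table_name, sprintf(
          "column '%s' is not numeric (first offending line %d: '%s')",
          col, which(bad)[1] + 1L, v[bad][1]))
      }
      num[v == ""] <- NA
      df[[col]] <- num
    }
  }
  df
}

require_columns <- function(df, cols, table_name) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_field(table_name, paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' Read a biomarker table
#'
#' One row per subject and panel: `subject_id, ab42, ab40, ptau, ttau,
#' panel_id`; empty cells mean missing (only `ab40` may be missing). When
#' a subject was measured on several panels, the single row from the
#' highest-priority panel is kept.
#'
#' @param path CSV path.
#' @param panel_priority Character vector of panel ids from most to least
#'   preferred; defaults to order of first appearance.
#' @return Data.frame of deduplicated profiles.
#' @export
read_biomarkers <- function(path, panel_priority = NULL) {
  df <- read_cohort_csv(path, c("ab42", "ab40", "ptau", "ttau"), "biomarkers")
  require_columns(df, c("subject_id", "ab42", "ptau", "ttau", "panel_id"),
                  "biomarkers")
  if (!"ab40" %in% names(df)) df$ab40 <- NA_real_
  for (col in c("ab42", "ptau", "ttau")) {
    if (anyNA(df[[col]])) {
      stop_field("biomarkers", sprintf(
        "column '%s' has a missing value at line %d",
        col, which(is.na(df[[col]]))[1] + 1L))
    }
    check_positive(df[[col]], col)
  }
  check_positive(df$ab40, "ab40", allow_na = TRUE)
  if (is.null(panel_priority)) panel_priority <- unique(df$panel_id)
  unknown <- setdiff(unique(df$panel_id), panel_priority)
  if (length(unknown)) {
    stop_field("biomarkers", paste("panel id(s) not in the priority list:",
                                   paste(unknown, collapse = ", ")))
  }
  pr <- match(df$panel_id, panel_priority)
  df <- df[order(df$subject_id, pr), ]
  dup <- duplicated(df$subject_id)
  df <- df[!dup, ]
  conflict <- duplicated(paste(df$subject_id, df$panel_id))
  if (any(conflict)) {
    stop_field("biomarkers", paste("duplicate subject-panel row for subject",
                                   df$subject_id[conflict][1]))
  }
  rownames(df) <- NULL
  df
}

#' Read a longitudinal visit table
#'
#' Columns `subject_id, time, zmmse` with time in years from baseline.
#' Each subject must have a baseline visit at time 0 and strictly
#' increasing visit times.
#'
#' @param path CSV path.
#' @return Data.frame of visit records.
#' @export
read_visits <- function(path) {
  df <- read_cohort_csv(path, c("time", "zmmse"), "visits")
  require_columns(df, c("subject_id", "time", "zmmse"), "visits")
  if (any(df$time < 0)) {
    stop_field("visits", sprintf("negative time at line %d",
                                 which(df$time < 0)[1] + 1L))
  }
  for (s in split(seq_len(nrow(df)), df$subject_id)) {
    t_ <- df$time[s]
    if (min(t_) != 0) {
      stop_field("visits", paste("subject", df$subject_id[s[1]],
                                 "has no baseline visit (time 0)"))
    }
    if (is.unsorted(t_, strictly = TRUE)) {
      stop_field("visits", paste("visit times for subject", df$subject_id[s[1]],
                                 "are not strictly increasing"))
    }
  }
  df
}

#' Read a time-to-dementia outcome table
#'
#' Columns `subject_id, event` (0/1), `time` (years, > 0), one row per
#' subject.
#'
#' @param path CSV path.
#' @return Data.frame of outcome records.
#' @export
read_outcomes <- function(path) {
  df <- read_cohort_csv(path, c("event", "time"), "outcomes")
  require_columns(df, c("subject_id", "event", "time"), "outcomes")
  if (!all(df$event %in% c(0, 1))) {
    stop_field("outcomes", sprintf("non-binary event flag at line %d",
                                   which(!df$event %in% c(0, 1))[1] + 1L))
  }
  if (any(df$time <= 0)) {
    stop_field("outcomes", sprintf("non-positive time at line %d",
                                   which(df$time <= 0)[1] + 1L))
  }
  if (anyDuplicated(df$subject_id)) {
    stop_field("outcomes", paste("duplicate outcome row for subject",
                                 df$subject_id[duplicated(df$subject_id)][1]))
  }
  df
}

#' Read and cross-validate the three cohort tables
#'
#' Loads biomarkers, visits and outcomes, applies the per-table schema
#' checks, deduplicates multi-panel subjects by panel priority, and
#' verifies referential integrity: every visit and outcome row must refer
#' to a subject present in the biomarker table.
#'
#' @param biomarkers,visits,outcomes CSV paths; `visits`/`outcomes` may be
#'   `NULL` for scoring-only workflows.
#' @param panel_config Optional path to a panel configuration file
#'   ([read_panel_config()]); supplies panels and the priority list.
#' @return A list of class `cohort_bundle` with `profiles`, `visits`,
#'   `outcomes`, `panels`, `panel_priority`.
#' @export
read_cohort_tables <- function(biomarkers, visits = NULL, outcomes = NULL,
                               panel_config = NULL) {
  cfg <- if (!is.null(panel_config)) read_panel_config(panel_config) else NULL
  profiles <- read_biomarkers(biomarkers, panel_priority = cfg$panel_priority)
  vis <- if (!is.null(visits)) read_visits(visits) else NULL
  out <- if (!is.null(outcomes)) read_outcomes(outcomes) else NULL
  known <- unique(profiles$subject_id)
  check_refs <- function(df, nm) {
    orphan <- !df$subject_id %in% known
    if (any(orphan)) {
      stop_field(nm, sprintf("line %d refers to unknown subject '%s'",
                             which(orphan)[1] + 1L, df$subject_id[orphan][1]))
    }
  }
  if (!is.null(vis)) check_refs(vis, "visits")
  if (!is.null(out)) check_refs(out, "outcomes")
  structure(
    list(profiles = profiles, visits = vis, outcomes = out,
         panels = cfg$panels, panel_priority = cfg$panel_priority),
    class = "cohort_bundle"
  )
}

#' Write a synthetic cohort to a directory of CSV tables
#'
#' Writes `biomarkers.csv`, `visits.csv`, `outcomes.csv` and
#' `truth.json` (the generating configuration and seed) in the dialect
#' the readers expect, so a write-read round trip is lossless.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("biomarkers.csv", "visits.csv", "outcomes.csv",
                            "truth.json"))
  utils::write.csv(cohort$profiles[c("subject_id", "ab42", "ab40", "ptau",
                                     "ttau", "panel_id")],
                   paths[1], row.names = FALSE)
  utils::write.csv(cohort$visits, paths[2], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[3], row.names = FALSE)
  truth <- cohort$config
  truth$panel <- unclass(truth$panel)
  jsonlite::write_json(
    list(seed = cohort$seed, n_subjects = truth$n_subjects,
         constellation_weights = as.list(truth$constellation_weights),
         borderline_probability = truth$borderline_probability,
         lmm_truth = truth$lmm_truth, hazard_truth = truth$hazard_truth,
         panel = truth$panel),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
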