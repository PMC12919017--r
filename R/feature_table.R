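#' @importFrom stats complete.cases
NULL

.covariate_cols <- function() c("age", "sex", "education", "zung", "euler", "motion")
.label_cols <- function() c("site", "cohort", "group", "hiv", "cu", "nci")

#' Canonical column order of a feature table
#'
#' Identifier, covariates, labels, then the 28 morphometric features in
#' fixed key order. Files written by [write_feature_table()] always use
#' this order, so output is byte-stable across runs for the same table.
#' @return character vector of column names.
#' @export
feature_table_columns <- function() {
  c("participant_id", .covariate_cols(), .label_cols(), feature_keys())
}

#' Validate a feature table against the pipeline schema
#'
#' Checks the invariants every downstream stage relies on: all 28 feature
#' columns present, unique participant ids, positive ages, non-negative
#' motion, no missing required values, and consistency of the disorder
#' count with the HIV and cocaine-use indicators (`group == hiv + cu`
#' whenever all three are present).
#'
#' @param table data.frame feature table.
#' @return character vector of violation messages; empty iff the table is
#'   valid (also carries a `"row_report"` attribute with per-row issues).
#' @export
validate_feature_table <- function(table) {
  stopifnot(is.data.frame(table))
  report <- character(0)
  row_report <- data.frame(row = integer(0), problem = character(0),
                           stringsAsFactors = FALSE)
  need <- c("participant_id", "site", .covariate_cols(), feature_keys())
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    report <- c(report, paste0("missing column: ", missing_cols))
    attr(report, "row_report") <- row_report
    return(report)
  }
  if (anyDuplicated(table$participant_id)) {
    dup <- unique(table$participant_id[duplicated(table$participant_id)])
    report <- c(report, paste0("duplicate participant_id: ", dup))
  }
  req <- c("participant_id", "site", .covariate_cols(), feature_keys())
  bad_rows <- which(!complete.cases(table[req]))
  for (i in bad_rows) {
    miss <- req[vapply(table[i, req], function(v) is.na(v), logical(1))]
    row_report <- rbind(row_report, data.frame(
      row = i, problem = paste0("missing required field(s): ",
                                paste(miss, collapse = ",")),
      stringsAsFactors = FALSE))
  }
  ok_age <- !is.na(table$age)
  if (any(table$age[ok_age] <= 0)) {
    report <- c(report, "age must be > 0 for all rows")
  }
  ok_mot <- !is.na(table$motion)
  if (any(table$motion[ok_mot] < 0)) {
    report <- c(report, "motion must be >= 0 for all rows")
  }
  if (all(c("group", "hiv", "cu") %in% names(table))) {
    full <- !is.na(table$group) & !is.na(table$hiv) & !is.na(table$cu)
    bad <- full & (table$group != table$hiv + table$cu)
    if (any(bad)) {
      report <- c(report, paste0(
        "group != hiv+cu for participant(s): ",
        paste(table$participant_id[bad], collapse = ", ")))
    }
  }
  if (nrow(row_report)) {
    report <- c(report, paste0(nrow(row_report), " row(s) with missing required fields"))
  }
  attr(report, "row_report") <- row_report
  report
}

#' Read a feature table from CSV
#'
#' Reads a participant-by-feature CSV, checks the schema, and drops (with a
#' per-row report) any row missing a required field. Required fields are the
#' participant id, site, the six covariates (age, sex, education, zung,
#' euler, motion) and all 28 morphometric features.
#'
#' @param path path to a CSV file.
#' @param cohort_hint `"training"` or `"clinical"`; used to fill the
#'   `cohort` column when the file does not carry one.
#' @return validated data.frame; rejected rows are reported via the
#'   `"row_report"` attribute.
#' @export
read_feature_table <- function(path, cohort_hint = c("training", "clinical")) {
  cohort_hint <- match.arg(cohort_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "site", .covariate_cols(), feature_keys())
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"cohort" %in% names(tab)) tab$cohort <- cohort_hint
  for (cc in setdiff(.label_cols(), names(tab))) tab[[cc]] <- NA
  tab$participant_id <- as.character(tab$participant_id)
  if (anyDuplicated(tab$participant_id)) {
    stop("integrity error: duplicate participant_id in ", path)
  }
  req <- c("participant_id", "site", .covariate_cols(), feature_keys())
  keep <- complete.cases(tab[req])
  row_report <- data.frame(row = which(!keep),
                           participant_id = tab$participant_id[!keep],
                           problem = rep("missing required field", sum(!keep)),
                           stringsAsFactors = FALSE)
  tab <- tab[keep, feature_table_columns(), drop = FALSE]
  rownames(tab) <- NULL
  rep <- validate_feature_table(tab)
  if (length(rep)) stop("invalid feature table: ", paste(rep, collapse = "; "))
  attr(tab, "row_report") <- row_report
  tab
}

#' Write a feature table to CSV
#'
#' Columns are written in the canonical order from
#' [feature_table_columns()] so output is deterministic.
#'
#' @param table validated feature table.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  rep <- validate_feature_table(table)
  if (length(rep)) stop("refusing to write invalid table: ",
                        paste(rep, collapse = "; "))
  cols <- intersect(feature_table_columns(), names(table))
  cols <- feature_table_columns()[feature_table_columns() %in% cols]
  out <- table[, cols, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Apply image-quality exclusions to a participant roster
#'
#' Drops participants whose cortical-surface reconstruction failed and
#' participants whose resting-state head motion (mean Euclidean displacement
#' between consecutive measurements) exceeds `motion_limit`. The motion cut
#' is strict: exactly `motion > motion_limit` is excluded.
#'
#' @param roster data.frame with at least columns `recon_ok` (logical or
#'   0/1) and `motion` (mm).
#' @param motion_limit exclusion threshold in mm (default 0.4).
#' @return the retained rows; excluded rows with a `reason` column are
#'   attached as attribute `"excluded"`.
#' @export
apply_qc_exclusions <- function(roster, motion_limit = 0.4) {
  stopifnot(is.data.frame(roster),
            all(c("recon_ok", "motion") %in% names(roster)))
  recon_ok <- as.logical(roster$recon_ok)
  fail_recon <- !recon_ok
  # motion is only assessable when reconstruction succeeded; failed
  # reconstructions are excluded first regardless of motion
  high_motion <- recon_ok & !is.na(roster$motion) & roster$motion > motion_limit
  excluded <- roster[fail_recon | high_motion, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- ifelse(!as.logical(excluded$recon_ok),
                              "reconstruction_failure", "high_motion")
  } else {
    excluded$reason <- character(0)
  }
  retained <- roster[!(fail_recon | high_motion), , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "excluded") <- excluded
  retained
}
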