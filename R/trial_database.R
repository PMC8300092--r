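#' @importFrom utils read.csv write.csv
NULL

trial_columns <- c("study_id", "n_obs", "stage", "forage_prop", "dmi",
                   "fa", "ee", "ndf", "ch4_mj", "technique", "subset")

trial_stages     <- c("lactating", "non-lactating")
trial_techniques <- c("tracer", "chamber", "headhood", "greenfeed")
trial_subsets    <- c("development", "evaluation")

#' Validate a feeding-trial treatment-mean table
#'
#' Checks the invariants of the basic-model database: strictly positive DMI
#' and CH4, forage proportion in \[0, 100\], fatty acids not exceeding ether
#' extract when both are present, at least one of FA/EE per record, and
#' recognised factor levels for stage, measurement technique and the
#' development/evaluation subset.
#'
#' @param records Data frame with the trial-table columns (see
#'   [read_trial_table()]).
#' @return The validated data frame (invisibly unchanged) with `study_id`,
#'   `stage`, `technique`, `subset` as character and numeric measurement
#'   columns. Errors mention the offending row numbers.
#' @export
validate_trial_records <- function(records) {
  missing_cols <- setdiff(setdiff(trial_columns, c("subset", "ee")),
                          names(records))
  if (length(missing_cols)) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"ee" %in% names(records)) records$ee <- NA_real_
  if (!"subset" %in% names(records)) records$subset <- "development"
  records$subset[is.na(records$subset) | records$subset == ""] <- "development"

  for (col in c("n_obs", "forage_prop", "dmi", "fa", "ee", "ndf", "ch4_mj")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  for (col in c("study_id", "stage", "technique", "subset")) {
    records[[col]] <- as.character(records[[col]])
  }

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop("invalid trial record(s) in row(s) ",
           paste(rows, collapse = ", "), ": ", what)
    }
  }
  bad(!is.finite(records$dmi) | records$dmi <= 0,
      "dmi must be a positive number (kg DM/day)")
  bad(!is.finite(records$ch4_mj) | records$ch4_mj <= 0,
      "ch4_mj must be a positive number (MJ/day)")
  bad(!is.finite(records$forage_prop) | records$forage_prop < 0 |
        records$forage_prop > 100,
      "forage_prop must lie in [0, 100] (% of DM)")
  bad(!is.finite(records$n_obs) | records$n_obs < 1 |
        records$n_obs != round(records$n_obs),
      "n_obs must be a positive integer")
  bad(is.na(records$fa) & is.na(records$ee),
      "at least one of fa or ee is required")
  bad(!is.na(records$fa) & records$fa < 0, "fa must be >= 0 (g/kg DM)")
  bad(!is.na(records$ee) & records$ee < 0, "ee must be >= 0 (g/kg DM)")
  bad(!is.na(records$fa) & !is.na(records$ee) & records$fa > records$ee,
      "fatty acids (fa) cannot exceed ether extract (ee)")
  bad(!is.finite(records$ndf) | records$ndf < 0, "ndf must be >= 0 (g/kg DM)")
  bad(!records$stage %in% trial_stages,
      paste("stage must be one of:", paste(trial_stages, collapse = ", ")))
  bad(!records$technique %in% trial_techniques,
      paste("technique must be one of:",
            paste(trial_techniques, collapse = ", ")))
  bad(!records$subset %in% trial_subsets,
      paste("subset must be one of:", paste(trial_subsets, collapse = ", ")))
  records[trial_columns]
}

#' Read a feeding-trial treatment-mean table from CSV
#'
#' One row per treatment mean. Required columns:
#' `study_id,n_obs,stage,forage_prop,dmi,fa,ee,ndf,ch4_mj,technique,subset`
#' (comma-separated, UTF-8, dot decimal). `ee` may be missing per record
#' (empty cell) as long as `fa` is present, and vice versa; an absent
#' `subset` column defaults to `"development"`.
#'
#' A packaged 99-record fixture emulating the published database summary
#' (29 studies; study-level means and ranges only — the per-treatment
#' source values are not public) ships as
#' `system.file("extdata", "synthetic_feeding_trials.csv", package = "metanor")`.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame of trial records.
#' @seealso [validate_trial_records()], [write_trial_table()]
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("trial table not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  validate_trial_records(raw)
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trial_table()]; the round trip preserves every field
#' for text-representable values.
#'
#' @param records Validated trial-record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(records, path) {
  records <- validate_trial_records(records)
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
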