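# Dataset and configuration I/O.
#
# Datasets are CSV files with NONMEM-compatible column semantics; the
# configuration is a single JSON file validated against the known keys.
# All times are hours in datasets; day-based regimen inputs are converted
# at the boundary (1 day = 24 h exactly).

.required_cols <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "MDV", "WT")
.optional_cols <- c("AGE", "BSE", "SCRN", "STUDYGRP", "JPN", "BLQ")

.validate_dataset <- function(df) {
  .assert(is.data.frame(df), "dataset must be a data.frame")
  missing_cols <- setdiff(.required_cols, names(df))
  .assert(length(missing_cols) == 0,
          "dataset is missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  .assert(all(df$TIME >= 0, na.rm = TRUE), "TIME must be non-negative")
  bad_dose <- df$EVID == 1L & df$MDV == 0L
  .assert(!any(bad_dose),
          "dose records (EVID=1) must have MDV=1; offending ID(s): ",
          paste(unique(df$ID[bad_dose]), collapse = ", "))
  unsorted <- vapply(split(df$TIME, df$ID), is.unsorted, logical(1))
  .assert(!any(unsorted),
          "times are not sorted within ID(s): ",
          paste(names(unsorted)[unsorted], collapse = ", "))
  invisible(df)
}

#' Read a NONMEM-style dataset from CSV
#'
#' Validates the required columns (`ID, TIME, EVID, AMT, DUR, DV, MDV,
#' WT`), that dose records carry `MDV = 1`, and that times are sorted
#' within each individual. Errors name the offending column or IDs.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.frame of class `fix_dataset`.
#' @seealso [write_fix_dataset()], [simulate_dataset()]
#' @export
read_fix_dataset <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_dataset(df)
  class(df) <- c("fix_dataset", "data.frame")
  df
}

#' Write a dataset to CSV
#'
#' @param data A dataset (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fix_dataset <- function(data, path) {
  .validate_dataset(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

# --- run configuration ----------------------------------------------------

.config_keys <- c("fixed_effects", "iiv", "residual", "cohort", "regimens",
                  "seed", "n_replicates", "output_dir")

#' Default run configuration
#'
#' A structured configuration bundling the model parameters (defaults are
#' the final-model estimates), the cohort specification, the regimen menu
#' and the seed. Serialized to JSON by [write_fix_config()]; unknown keys
#' are rejected on the way in and out.
#'
#' @param ... Overrides for any of the keys `fixed_effects`, `iiv`,
#'   `residual`, `cohort`, `regimens`, `seed`, `n_replicates`,
#'   `output_dir`.
#' @return A list of class `fix_config`.
#' @export
fix_config <- function(...) {
  cfg <- list(
    fixed_effects = unclass(fix_fixed_effects()),
    iiv = unclass(fix_iiv()),
    residual = unclass(fix_residual()),
    cohort = list(n = c("<6" = 12, "6-<12" = 15, "12-<18" = 5, ">=18" = 81),
                  weight_gcv = 0.2,
                  calibration = as.list(per_kg_cl_medians())),
    regimens = list(single_doses = c(25, 35, 40, 50, 75, 100),
                    steady_doses = c(25, 35, 40, 50, 75, 100, 150),
                    intervals_days = c(7, 10, 14, 21, 28),
                    infusion_duration = 1 / 6),
    seed = 1L, n_replicates = 1000L, output_dir = ".")
  dots <- list(...)
  unknown <- setdiff(names(dots), .config_keys)
  .assert(length(unknown) == 0,
          "unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "fix_config"
  cfg
}

#' @rdname fix_config
#' @param path JSON file path.
#' @export
read_fix_config <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .config_keys)
  .assert(length(unknown) == 0,
          "unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(fix_config, raw)
}

#' @rdname fix_config
#' @param config A `fix_config` object.
#' @export
write_fix_config <- function(config, path) {
  .assert(inherits(config, "fix_config"), "'config' must be a fix_config")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reproducibility metadata for a run
#'
#' Every simulation entry point can stamp its output with the configuration
#' hash, seed and package version, which is sufficient to reproduce the
#' output exactly.
#'
#' @param config A `fix_config` object.
#' @return A list with `config_md5`, `seed`, `package_version`,
#'   `r_version` and `timestamp`.
#' @export
run_metadata <- function(config = fix_config()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_fix_config(config, tmp)
  list(config_md5 = unname(tools::md5sum(tmp)),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("rixfp")),
       r_version = R.version.string,
       timestamp = format(Sys.time(), tz = "UTC"))
}

# --- report tables --------------------------------------------------------

# "12.5" -> "12.5", "20" -> "20" (printed tables drop trailing .0)
.fmt_half <- function(x) ifelse(x %% 1 == 0, sprintf("%d", as.integer(x)),
                                sprintf("%.1f", x))

#' Write regimen summary tables in the printed layouts
#'
#' Formats the long-form outputs of [simulate_duration_table()],
#' [simulate_trough_table()], [simulate_percent_table()] or an
#' [ethnicity_comparison()] into the familiar published layouts (regimen x
#' threshold rows, age-group columns) and writes CSV. Durations are
#' printed as `median (25th percentile)` in half-day units; troughs as
#' `median (90% PI)` with one decimal; percentages with one decimal.
#' Requested cells absent from `summaries` are written empty with a
#' warning, never invented.
#'
#' @param summaries Long-form summary data.frame (or `fix_comparison` for
#'   the exposure style).
#' @param style One of `"table3"` (single-dose durations), `"table4"`
#'   (steady-state troughs), `"table5"` (percent above cutoff), `"table7"`
#'   (exposure comparison).
#' @param path Output CSV path.
#' @return The formatted data.frame, invisibly.
#' @export
write_summary_tables <- function(summaries,
                                 style = c("table3", "table4", "table5",
                                           "table7"),
                                 path) {
  style <- match.arg(style)
  if (style == "table7") {
    .assert(inherits(summaries, "fix_comparison"),
            "table7 style expects an ethnicity_comparison() result")
    out <- summaries$table
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  .assert(is.data.frame(summaries), "'summaries' must be a data.frame")
  groups <- unique(summaries$group)
  cell <- function(sub) {
    if (nrow(sub) == 0) return(NA_character_)
    if (style == "table3")
      sprintf("%s (%s)", .fmt_half(sub$median), .fmt_half(sub$p25))
    else if (style == "table4")
      sprintf("%.1f (%.1f-%.1f)", sub$median, sub$lo, sub$hi)
    else sprintf("%.1f", sub$percent)
  }
  if (style == "table4") {
    keys <- unique(summaries[, c("dose_per_kg", "interval_days")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
      lab <- sprintf("%g IU/kg every %g days",
                     keys$dose_per_kg[i], keys$interval_days[i])
      vals <- vapply(groups, function(g)
        cell(summaries[summaries$dose_per_kg == keys$dose_per_kg[i] &
                         summaries$interval_days == keys$interval_days[i] &
                         summaries$group == g, , drop = FALSE]),
        character(1))
      c(regimen = lab, vals)
    })
  } else {
    keys <- unique(summaries[, c("dose_per_kg",
                                 intersect("interval_days", names(summaries)),
                                 "threshold")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
      has_int <- "interval_days" %in% names(keys)
      lab <- if (has_int)
        sprintf("%g IU/kg every %g days, >%g IU/dL", keys$dose_per_kg[i],
                keys$interval_days[i], keys$threshold[i])
      else sprintf("%g IU/kg, >%g IU/dL", keys$dose_per_kg[i],
                   keys$threshold[i])
      sel <- summaries$dose_per_kg == keys$dose_per_kg[i] &
        summaries$threshold == keys$threshold[i]
      if (has_int) sel <- sel & summaries$interval_days == keys$interval_days[i]
      vals <- vapply(groups, function(g)
        cell(summaries[sel & summaries$group == g, , drop = FALSE]),
        character(1))
      c(regimen = lab, vals)
    })
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (anyNA(out)) warning("missing summary cells written as empty")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}
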