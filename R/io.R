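PLATE_SCHEMA <- c("plate_id", "row", "col", "role", "compound_id",
                  "conc_um", "rfu")

#' Read a plate CSV
#'
#' Validates the documented schema (`plate_id, row, col, role, compound_id,
#' conc_um, rfu`), the letter-pair row labels, the 1-based column indices,
#' and well uniqueness within a plate.
#'
#' @param path CSV path.
#' @return Well table (data frame).
#' @export
read_plate_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(compound_id = "character"))
  miss <- setdiff(PLATE_SCHEMA, names(x))
  if (length(miss)) {
    stop_bad("plate CSV lacks column(s): %s", paste(miss, collapse = ", "))
  }
  x <- x[, PLATE_SCHEMA]
  if (!all(x$row %in% plate_row_labels(52))) {
    stop_bad("invalid row labels (expect A..Z, AA..)")
  }
  if (!is.numeric(x$col) || any(x$col < 1 | x$col > 48)) {
    stop_bad("column indices must be in 1..48")
  }
  if (!is.numeric(x$rfu)) stop_bad("rfu must be numeric")
  key <- paste(x$plate_id, x$row, x$col)
  if (anyDuplicated(key)) stop_bad("duplicate wells in plate CSV")
  x$compound_id[x$compound_id %in% c("", "NA")] <- NA_character_
  x
}

#' Write a plate CSV
#' @param wells Well table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(wells, path) {
  utils::write.csv(wells[, PLATE_SCHEMA], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read/write the auxiliary study tables
#'
#' CSV round-trips for the kinetic (`substrate, inhibitor, rate,
#' replicate`), pharmacokinetic (`matrix, time_h, conc, animal_id`),
#' grouped-count (`group, replicate, value`) and qPCR (`sample_id, group,
#' gene, ct_target, ct_reference`) tables.
#'
#' @param path CSV path.
#' @param x Table to write.
#' @return The table (readers) or `path` invisibly (writer).
#' @name study_io
NULL

read_table_checked <- function(path, need) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_bad("%s lacks column(s): %s", basename(path),
             paste(miss, collapse = ", "))
  }
  x
}

#' @rdname study_io
#' @export
read_kinetic_csv <- function(path) {
  read_table_checked(path, c("substrate", "inhibitor", "rate"))
}

#' @rdname study_io
#' @export
read_pk_csv <- function(path) {
  read_table_checked(path, c("matrix", "time_h", "conc"))
}

#' @rdname study_io
#' @export
read_grouped_csv <- function(path) {
  read_table_checked(path, c("group", "replicate", "value"))
}

#' @rdname study_io
#' @export
read_qpcr_csv <- function(path) {
  read_table_checked(path, c("sample_id", "group", "gene", "ct_target",
                             "ct_reference"))
}

#' @rdname study_io
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every tunable of the screening pipeline, grouped by module. Unknown keys
#' in a user configuration are rejected; missing keys fall back to these
#' defaults, and the materialised configuration is echoed into the run
#' summary.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    synth = list(
      n_compounds = 1440L,
      prop_true = 0.02, prop_counter_fp = 0.05, prop_promiscuous = 0.02,
      ic50_range = c(0.03, 10), efficacy_range = c(75, 100),
      counter_ic50_range = c(0.1, 50),
      noise_cv = 0.05, read_noise_sd = 27,
      primary_doses = list(top = 57, n = 4L, fold = 5),
      confirm_doses = list(top = 57, n = 7L, fold = 5),
      pos_series_ic50 = 27
    ),
    qc = list(positional_threshold = 0.2, z_min = 0.5),
    dose_response = list(high_efficacy = 80, partial_floor = 30,
                         r2_min = 0.9, asym_frac = 0.05,
                         extrapolation_logs = 1,
                         single_dose_activity = 50),
    triage = list(min_top_response = 50,
                  selectable_classes = c(-1.1, -1.2, -2.1, -2.2),
                  partial_floor = 30, pic50_gap = 1, counter_eff_max = 50,
                  counter_rule = "class", potency_gate = 10),
    pk = list(method = "linuplogdown", lambda_n = 3L)
  )
}

merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop_bad("config entry '%s' must be a mapping", path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop_bad("unknown config key(s): %s",
             paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) &&
                         !is.null(names(defaults[[k]]))) {
      merge_config(user[[k]], defaults[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' YAML key-value file mirroring [default_config()]; unknown keys are
#' rejected, missing keys are materialised from the defaults.
#'
#' @param path YAML file path (NULL = pure defaults).
#' @return Full configuration list.
#' @export
read_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_config(user, default_config())
}

#' Stable hash of a configuration
#' @param config Configuration list.
#' @return MD5 string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
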