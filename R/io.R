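# File formats and configuration: delimited-text torque series, session
# ledgers, and the JSON run configuration. All files are comma-separated
# UTF-8 with dot decimals.

torque_csv_cols <- c("time_s", "torque_nm", "angle_deg", "velocity_dps")

#' Read a torque series from CSV
#'
#' Expects header `time_s,torque_nm,angle_deg,velocity_dps`, one row per
#' sample. Missing columns, non-numeric or missing values, and
#' non-monotone time are reported as structured parse errors naming the
#' offending column or data line numbers.
#'
#' @param path file path.
#' @return A [torque_series()].
#' @export
read_torque_csv <- function(path) {
  if (!file.exists(path)) {
    ep_stop(paste("file not found:", path), "ep_parse_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(torque_csv_cols, names(df))
  if (length(miss)) {
    ep_stop(paste0("missing column(s): ", paste(miss, collapse = ", "),
                   " in ", path), "ep_parse_error")
  }
  bad <- which(!stats::complete.cases(df[torque_csv_cols]) |
                 !apply(df[torque_csv_cols], 1L, function(r) all(is.finite(as.numeric(r)))))
  if (length(bad)) {
    ep_stop(paste0("malformed row(s) at data line(s): ",
                   paste(utils::head(bad, 10L), collapse = ", ")),
            "ep_parse_error")
  }
  if (nrow(df) > 1L && any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1L] + 1L
    ep_stop(paste0("non-monotone time at data line ", bad), "ep_parse_error")
  }
  torque_series(df$time_s, df$torque_nm, df$angle_deg, df$velocity_dps)
}

#' Write a torque series to CSV
#'
#' @param series a [torque_series()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_torque_csv <- function(series, path) {
  stopifnot(inherits(series, "torque_series"))
  utils::write.csv(as.data.frame(series)[torque_csv_cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a session ledger
#'
#' Lossless CSV round-trip of a [progress_ledger()] with stable column
#' order. Duplicate session ids are an integrity error on read and on
#' append.
#'
#' @param path file path.
#' @return `read_ledger()` returns a [progress_ledger()];
#'   `write_ledger()` returns `path` invisibly.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) ep_stop(paste("file not found:", path), "ep_parse_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  progress_ledger(df)
}

#' @param ledger a [progress_ledger()] or compatible data frame.
#' @rdname read_ledger
#' @export
write_ledger <- function(ledger, path) {
  ledger <- progress_ledger(as.data.frame(ledger))
  utils::write.csv(ledger, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Append sessions to a ledger
#'
#' @param ledger existing [progress_ledger()].
#' @param rows data frame of new session records.
#' @return The combined `progress_ledger`; colliding session ids raise
#'   an error of class `ep_integrity_error`.
#' @export
append_ledger <- function(ledger, rows) {
  ledger <- progress_ledger(as.data.frame(ledger))
  rows <- as.data.frame(rows)
  clash <- intersect(ledger$session_id, rows$session_id)
  if (length(clash)) {
    ep_stop(paste("duplicate session id(s) on append:",
                  paste(clash, collapse = ", ")), "ep_integrity_error")
  }
  progress_ledger(rbind(as.data.frame(ledger)[names(ledger)],
                        rows[names(ledger)]))
}

#' Run configuration
#'
#' Bundles the tunable thresholds of the method with their protocol
#' defaults; serializes losslessly to JSON via [write_run_config()] /
#' [read_run_config()].
#'
#' @param cofactor eccentric/concentric estimation cofactor (1.35).
#' @param adjustment_mode `"multiplicative"` or `"additive_points"`.
#' @param plateau_threshold slope threshold for plateau labeling (10).
#' @param stoppage_vas VAS score above which exercise stops (8).
#' @param flag_delta VAS rise over baseline flagged for review (4).
#' @param recovery_policy `"light"` or `"rest"`.
#' @param seed integer seed or `NULL`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cofactor = 1.35,
                       adjustment_mode = c("multiplicative", "additive_points"),
                       plateau_threshold = 10, stoppage_vas = 8,
                       flag_delta = 4,
                       recovery_policy = c("light", "rest"), seed = NULL) {
  adjustment_mode <- match.arg(adjustment_mode)
  recovery_policy <- match.arg(recovery_policy)
  if (!is_num1(cofactor) || cofactor <= 0) {
    ep_stop("cofactor must be positive", "ep_invalid_config")
  }
  if (!is_num1(plateau_threshold) || plateau_threshold < 0) {
    ep_stop("plateau_threshold must be non-negative", "ep_invalid_config")
  }
  if (!is_num1(stoppage_vas) || stoppage_vas < 0 || stoppage_vas > 10) {
    ep_stop("stoppage_vas must lie in [0, 10]", "ep_invalid_config")
  }
  structure(list(cofactor = cofactor, adjustment_mode = adjustment_mode,
                 plateau_threshold = plateau_threshold,
                 stoppage_vas = stoppage_vas, flag_delta = flag_delta,
                 recovery_policy = recovery_policy, seed = seed),
            class = "run_config")
}

#' @param config a [run_config()].
#' @param path file path.
#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ep_stop(paste("file not found:", path), "ep_parse_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

#' Export a plan as a JSON document
#'
#' Serializes microcycles, their per-session set prescriptions, and the
#' scheduling parameters.
#'
#' @param plan an `ecc_plan`.
#' @param path optional file path; if `NULL`, the JSON string is
#'   returned.
#' @return `path` invisibly, or a JSON string.
#' @export
plan_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "ecc_plan"))
  doc <- list(
    model = plan$model,
    sessions_per_week = plan$sessions_per_week,
    min_rest_days = plan$min_rest_days,
    recovery_policy = plan$recovery_policy,
    microcycles = lapply(plan$microcycles, function(mc) {
      list(index = mc$index, phase = mc$phase, mesocycle = mc$mesocycle,
           target_mode = mc$target_mode,
           target_percent = mc$target_percent,
           sets = mc$sets)
    }))
  if (is.null(path)) {
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(path)
  }
}
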