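# Plain-text readers/writers for the package's CSV dialects (comma-separated,
# UTF-8, '.' decimal, header required) and JSON ground-truth sidecars.

#' Read a growth-curve time-series CSV
#'
#' Validates the curve dialect: required columns `clone`, `replicate`,
#' `channel`, `time_h`, `value` (extra columns such as `culture` pass
#' through); rows are sorted by series and time; negative or non-finite
#' values and duplicated times within a series are rejected with the
#' offending line numbers.
#'
#' @param path CSV file path.
#' @return Validated data frame of curves.
#' @export
read_timeseries_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("clone", "replicate", "channel", "time_h", "value")
  if (!all(need %in% names(df)))
    stop_clonefit("'%s': header must contain %s", path,
                  paste(need, collapse = ", "))
  lines <- seq_len(nrow(df)) + 1L   # header is line 1
  bad <- !is.finite(df$value) | df$value < 0
  if (any(bad))
    stop_clonefit("'%s': negative or non-finite values at line(s) %s", path,
                  paste(utils::head(lines[bad], 5), collapse = ", "))
  bad_t <- !is.finite(df$time_h)
  if (any(bad_t))
    stop_clonefit("'%s': non-finite times at line(s) %s", path,
                  paste(utils::head(lines[bad_t], 5), collapse = ", "))
  key <- interaction(df$clone, df$replicate, df$channel, drop = TRUE)
  for (lv in levels(key)) {
    idx <- which(key == lv)
    tt <- df$time_h[idx]
    if (anyDuplicated(tt))
      stop_clonefit("'%s': duplicated times in series %s at line(s) %s", path,
                    lv, paste(lines[idx][duplicated(tt)], collapse = ", "))
  }
  ord <- order(df$clone, df$replicate, df$channel, df$time_h)
  df <- df[ord, ]
  rownames(df) <- NULL
  df
}

#' Write a growth-curve table as CSV
#'
#' @param curves Curve data frame.
#' @param path Output path.
#' @export
write_timeseries_csv <- function(curves, path) {
  write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a screen plate-table CSV
#'
#' @param path CSV path with columns `plate_id`, `well`, `role`, `compound`,
#'   `dose_uM`, `count` (plus optional `row`, `col`, `cell_line`).
#' @return Validated data frame of wells.
#' @export
read_plate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "role", "compound", "dose_uM", "count")
  if (!all(need %in% names(df)))
    stop_clonefit("'%s': header must contain %s", path,
                  paste(need, collapse = ", "))
  if (any(!is.finite(df$count) | df$count < 0))
    stop_clonefit("'%s': counts must be finite and non-negative", path)
  ctrl <- df$role == "negative_control"
  if (any(!is.na(df$compound[ctrl])))
    stop_clonefit("'%s': negative-control wells must not carry a compound", path)
  df
}

#' @rdname read_plate_csv
#' @param wells Well data frame.
#' @export
write_plate_csv <- function(wells, path) {
  write.csv(wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell morphology feature CSV
#'
#' @param path CSV path with columns `cell_id`, `group`, `feat_*`.
#' @return Data frame of features.
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "group") %in% names(df)))
    stop_clonefit("'%s': header must contain cell_id and group", path)
  if (!length(feature_columns(df)))
    stop_clonefit("'%s': no feature columns found", path)
  df
}

#' @rdname read_features_csv
#' @param features Feature data frame.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a ground-truth sidecar as JSON
#'
#' The sidecar mirrors every generating parameter (including the seed), so
#' regenerating from it reproduces the data byte-for-byte.
#'
#' @param truth Ground-truth list from a generator.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
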