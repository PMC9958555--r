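#' Time-series tables
#'
#' All chairsts series are plain tibbles with a time column `t` in seconds,
#' uniformly sampled. Three kinds are used:
#'
#' * **distance** — `t, d_thigh_mm, d_trunk_mm, valid`: the two laser range
#'   readings (30 Hz in the reference setup).
#' * **angle** — `t, theta_trunk_deg, theta_thigh_deg, source, valid`:
#'   trunk angle from vertical (flexion positive) and thigh angle from
#'   horizontal; `source` is one of `chair-model`, `marker-based`,
#'   `ground-truth`.
#' * **marker** — `t` plus sagittal `(x, y)` mm positions of the four
#'   landmarks: `c7_x_mm, c7_y_mm, sacrum_x_mm, sacrum_y_mm,
#'   trochanter_x_mm, trochanter_y_mm, condyle_x_mm, condyle_y_mm`
#'   (100 Hz in the reference setup).
#'
#' @name series
NULL

series_cols <- list(
  distance = c("t", "d_thigh_mm", "d_trunk_mm"),
  angle    = c("t", "theta_trunk_deg", "theta_thigh_deg"),
  marker   = c("t", "c7_x_mm", "c7_y_mm", "sacrum_x_mm", "sacrum_y_mm",
               "trochanter_x_mm", "trochanter_y_mm",
               "condyle_x_mm", "condyle_y_mm")
)

series_value_cols <- function(df) {
  setdiff(names(df)[vapply(df, is.numeric, TRUE)], "t")
}

check_series <- function(df, kind = c("distance", "angle", "marker"),
                         arg = deparse(substitute(df))) {
  kind <- match.arg(kind)
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame", arg))
  need <- series_cols[[kind]]
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  if (nrow(df) >= 2L) {
    dt <- diff(df$t)
    if (any(dt <= 0)) abort(sprintf("`%s` has non-increasing time stamps", arg))
    if (max(dt) - min(dt) > 1e-6 * max(dt)) {
      abort(sprintf("`%s` is not uniformly sampled", arg))
    }
  }
  invisible(df)
}

#' Sampling rate of a series
#'
#' @param df A series tibble with a uniformly spaced `t` column (seconds).
#' @return Sampling rate in Hz.
#' @export
series_fs <- function(df) {
  if (!is.data.frame(df) || !"t" %in% names(df) || nrow(df) < 2L) {
    abort("`df` must be a series with at least two samples")
  }
  1 / median(diff(df$t))
}

#' Interpolate isolated invalid samples
#'
#' Linearly interpolates runs of up to `max_gap` consecutive invalid samples
#' in each numeric column (using the neighbouring valid samples) and marks
#' them valid. Longer runs, and invalid runs touching either end of the
#' series, are left untouched.
#'
#' @param df A series tibble with a logical `valid` column.
#' @param max_gap Longest invalid run (samples) that will be filled.
#' @return The series with isolated gaps filled.
#' @export
fill_invalid <- function(df, max_gap = 3L) {
  if (!"valid" %in% names(df)) return(df)
  valid <- as.logical(df$valid)
  if (all(valid)) return(df)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fill <- rep(FALSE, nrow(df))
  for (i in seq_along(r$values)) {
    if (!r$values[i] && r$lengths[i] <= max_gap &&
        i > 1L && i < length(r$values)) {
      fill[starts[i]:ends[i]] <- TRUE
    }
  }
  if (!any(fill)) return(df)
  for (col in series_value_cols(df)) {
    df[[col]][fill] <- approx(df$t[valid], df[[col]][valid],
                              xout = df$t[fill])$y
  }
  df$valid[fill] <- TRUE
  df
}

#' Read and write series CSV files
#'
#' CSV with the documented header for each kind (see [series]); leading
#' lines starting with `#` carry provenance (config, seed) and are skipped
#' on read. `read_series()` enforces the series invariants: required
#' columns, strictly increasing uniform time stamps, and a missing-value
#' density of at most 20% per value column.
#'
#' @param path CSV file path.
#' @param kind One of `"distance"`, `"angle"`, `"marker"`.
#' @return `read_series()` returns a tibble; `write_series()` returns
#'   `path` invisibly.
#' @export
read_series <- function(path, kind = c("distance", "angle", "marker")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- tryCatch(
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0L) abort(sprintf("%s contains no data rows", path))
  need <- series_cols[[kind]]
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("%s: header mismatch for kind '%s'; missing column(s): %s",
                  path, kind, paste(missing, collapse = ", ")))
  }
  num_cols <- intersect(need, names(df))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad)) {
      abort(sprintf("%s: malformed numeric value in column '%s' at data row(s) %s",
                    path, col, paste(head(bad, 5L), collapse = ", ")))
    }
    df[[col]] <- v
  }
  if ("valid" %in% names(df)) df$valid <- as.logical(df$valid)
  df <- as_tibble(df)
  check_series(df, kind, arg = path)
  vals <- setdiff(num_cols, "t")
  na_frac <- vapply(df[vals], function(v) mean(is.na(v)), 0)
  if (any(na_frac > 0.2)) {
    abort(sprintf("%s: more than 20%% missing values in column '%s'",
                  path, vals[which.max(na_frac)]))
  }
  df
}

#' @param df Series tibble to write.
#' @param meta Named list written as `# key: value` provenance comment lines.
#' @rdname read_series
#' @export
write_series <- function(df, path, kind = c("distance", "angle", "marker"),
                         meta = list()) {
  kind <- match.arg(kind)
  check_series(df, kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chairsts %s series", kind), con)
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, paste(format(meta[[nm]]), collapse = " ")), con)
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
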