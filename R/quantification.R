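#' Trapezoidal integration of a chromatogram over fixed peak windows
#'
#' Integrates a fluorescence trace over a fixed, shared set of 24 retention
#' windows (the "same intervals of integration for all samples" convention):
#' each peak area is the trapezoidal integral of intensity over its window,
#' with the boundary intensities obtained by linear interpolation, clipped
#' at zero. Optionally a straight baseline drawn between the two window
#' boundaries is subtracted first.
#'
#' @param trace A data.frame with numeric columns `time_min` (strictly
#'   increasing) and `intensity`.
#' @param windows A data.frame with columns `peak_id`, `start_min`,
#'   `end_min`; windows must be pairwise disjoint and lie inside the trace's
#'   time span.
#' @param baseline If `TRUE`, subtract a linear baseline anchored at the
#'   window boundaries (default `FALSE`: the raw trapezoid).
#' @param sample_id Sample identifier attached to the result.
#' @return A one-row data.frame: `sample_id` plus one non-negative area
#'   column per `peak_id`.
#' @examples
#' tr <- data.frame(time_min = c(0, 1, 2, 3), intensity = c(0, 2, 2, 0))
#' w <- data.frame(peak_id = "GP1", start_min = 0, end_min = 3)
#' integrate_fixed_windows(tr, w)
#' @export
integrate_fixed_windows <- function(trace, windows, baseline = FALSE,
                                    sample_id = "sample") {
  if (!all(c("time_min", "intensity") %in% names(trace)))
    glyconact_error("trace needs columns time_min and intensity",
                    "glyconact_schema_error")
  t <- as.numeric(trace$time_min); y <- as.numeric(trace$intensity)
  if (length(t) < 2L || any(!is.finite(t)) || any(!is.finite(y)))
    glyconact_error("trace must have >= 2 finite points",
                    "glyconact_input_error")
  if (any(diff(t) <= 0))
    glyconact_error("trace time must be strictly increasing",
                    "glyconact_input_error")
  if (!all(c("peak_id", "start_min", "end_min") %in% names(windows)))
    glyconact_error("windows need columns peak_id, start_min, end_min",
                    "glyconact_schema_error")
  w <- windows[order(windows$start_min), , drop = FALSE]
  if (any(w$end_min <= w$start_min))
    glyconact_error("each window must satisfy end_min > start_min",
                    "glyconact_input_error")
  if (nrow(w) > 1L && any(w$start_min[-1] < w$end_min[-nrow(w)]))
    glyconact_error("integration windows overlap", "glyconact_input_error")
  if (any(w$start_min < t[1]) || any(w$end_min > t[length(t)]))
    glyconact_error("integration window outside the trace time span",
                    "glyconact_coverage_error")

  area_one <- function(a, b) {
    inner <- t > a & t < b
    tt <- c(a, t[inner], b)
    yy <- c(stats::approx(t, y, a)$y, y[inner], stats::approx(t, y, b)$y)
    if (baseline) {
      yy <- yy - (yy[1] + (tt - tt[1]) / (tt[length(tt)] - tt[1]) *
                    (yy[length(yy)] - yy[1]))
    }
    max(sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2), 0)
  }
  areas <- mapply(area_one, w$start_min, w$end_min)
  out <- as.data.frame(as.list(stats::setNames(areas, w$peak_id)))
  cbind(data.frame(sample_id = sample_id, stringsAsFactors = FALSE), out)
}

#' Total-area normalization of raw peak areas
#'
#' Converts raw chromatographic peak areas into relative abundances by
#' dividing each peak area by the total area of the corresponding
#' chromatogram, expressed in percent so each sample's profile sums to 100.
#'
#' @param areas A data.frame with a `sample_id` column plus one raw-area
#'   column per panel peak, or a bare named numeric vector for one sample.
#' @param peak_ids Panel peak columns expected (default the 24-peak panel).
#' @return Same shape as the input with areas replaced by percentages.
#' @examples
#' normalize_areas(c(GP1 = 2, GP2 = 3, GP3 = 5), peak_ids = paste0("GP", 1:3))
#' @export
normalize_areas <- function(areas, peak_ids = panel_peak_ids()) {
  if (is.numeric(areas) && !is.data.frame(areas)) {
    x <- normalize_area_matrix(matrix(areas[peak_ids], nrow = 1,
                                      dimnames = list(NULL, peak_ids)))
    return(stats::setNames(as.numeric(x), peak_ids))
  }
  check_profile_columns(areas, peak_ids)
  m <- as.matrix(areas[, peak_ids, drop = FALSE])
  areas[, peak_ids] <- normalize_area_matrix(m)
  areas
}

normalize_area_matrix <- function(m) {
  if (any(is.na(m)) || any(!is.finite(m)))
    glyconact_error("peak areas must be finite and non-missing",
                    "glyconact_input_error")
  if (any(m < 0))
    glyconact_error("negative peak area", "glyconact_input_error")
  tot <- rowSums(m)
  if (any(tot <= 0))
    glyconact_error("degenerate sample: total peak area is zero",
                    "glyconact_degenerate_sample_error")
  100 * m / tot
}

check_profile_columns <- function(df, peak_ids = panel_peak_ids()) {
  if (!"sample_id" %in% names(df))
    glyconact_error("missing required column sample_id",
                    "glyconact_schema_error")
  missing <- setdiff(peak_ids, names(df))
  if (length(missing))
    glyconact_error(sprintf("missing peak column(s): %s",
                            paste(missing, collapse = ", ")),
                    "glyconact_schema_error")
  invisible(df)
}

#' Read / write per-sample peak tables (raw areas or percent profiles)
#'
#' CSV schema: `sample_id`, `GP1` ... `GP24`.
#'
#' @param path File path.
#' @param peak_ids Expected peak columns.
#' @return A validated data.frame.
#' @export
read_areas_csv <- function(path, peak_ids = panel_peak_ids()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_profile_columns(df, peak_ids)
  df
}

#' @rdname read_areas_csv
#' @param profiles Data.frame to write.
#' @export
write_profiles_csv <- function(profiles, path) {
  write_csv_atomic(profiles, path)
  invisible(path)
}

#' Read chromatogram traces (long CSV: sample_id, time_min, intensity)
#' @param path File path.
#' @return A data.frame.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_min", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    glyconact_error(sprintf("missing trace column(s): %s",
                            paste(missing, collapse = ", ")),
                    "glyconact_schema_error")
  df
}

#' Read an integration window set (CSV or JSON)
#'
#' CSV columns `peak_id`, `start_min`, `end_min`; or a JSON object mapping
#' peak id to `[start, end]`.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A data.frame with one row per window.
#' @export
read_windows <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    w <- data.frame(peak_id = names(raw),
                    start_min = vapply(raw, `[`, numeric(1), 1),
                    end_min = vapply(raw, `[`, numeric(1), 2),
                    stringsAsFactors = FALSE)
  } else {
    w <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("peak_id", "start_min", "end_min")
  missing <- setdiff(need, names(w))
  if (length(missing))
    glyconact_error(sprintf("missing window column(s): %s",
                            paste(missing, collapse = ", ")),
                    "glyconact_schema_error")
  w
}

# Atomic CSV/JSON writers: write to a temp file in the target directory,
# then rename, so an interrupted run never leaves a half-written artifact.
write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
}

write_json_atomic <- function(x, path, ...) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE, ...)
  file.rename(tmp, path)
}
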