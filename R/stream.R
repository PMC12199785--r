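#' Construct a sample stream
#'
#' A `sample_stream` is a data.frame with one row per eye-tracker sample on a
#' regular grid anchored at the trial's event clock (t = 0 at picture onset
#' for the preferential-looking task, at the experimenter button press for
#' the mismatch task). Gaps are represented as in-grid rows flagged invalid,
#' never as dropped rows, so gap lengths are countable in samples.
#'
#' @param t_ms Numeric sample times, strictly increasing on the nominal grid.
#' @param x_px,y_px Gaze coordinates in pixels (`NA` when missing).
#' @param pupil_left_mm Left-eye pupil diameter in mm (`NA` when missing).
#' @param valid Logical tracking-validity flag.
#' @param geometry A [screen_geometry()].
#' @return A `sample_stream` (data.frame with a `geometry` attribute).
#' @export
sample_stream <- function(t_ms, x_px, y_px, pupil_left_mm, valid, geometry) {
  n <- length(t_ms)
  stopifnot(length(x_px) == n, length(y_px) == n,
            length(pupil_left_mm) == n, length(valid) == n)
  if (n > 1 && any(diff(t_ms) <= 0))
    stop("sample timestamps must be strictly increasing")
  df <- data.frame(t_ms = as.numeric(t_ms), x_px = as.numeric(x_px),
                   y_px = as.numeric(y_px),
                   pupil_left_mm = as.numeric(pupil_left_mm),
                   valid = as.logical(valid))
  attr(df, "geometry") <- geometry
  class(df) <- c("sample_stream", "data.frame")
  df
}

stream_geometry <- function(stream) attr(stream, "geometry")

#' Invalid placeholder rows for a set of grid times
#' @noRd
invalid_rows <- function(t_ms) {
  data.frame(t_ms = t_ms, x_px = NA_real_, y_px = NA_real_,
             pupil_left_mm = NA_real_, valid = FALSE)
}

#' Snap a table of samples onto the nominal sampling grid
#'
#' Rows are matched to grid indices `round(t / period)`; grid positions with
#' no row become invalid placeholder samples, so the output always covers
#' `0 .. max index` contiguously.
#'
#' @param df data.frame with columns `t_ms, x_px, y_px, pupil_left_mm, valid`.
#' @param geometry A [screen_geometry()].
#' @return A [sample_stream()].
#' @export
regularize_stream <- function(df, geometry) {
  period <- geometry$sample_period_ms
  if (nrow(df) == 0)
    return(sample_stream(numeric(0), numeric(0), numeric(0), numeric(0),
                         logical(0), geometry))
  if (any(diff(df$t_ms) <= 0))
    stop("non-monotone timestamps in sample table")
  idx <- as.integer(round(df$t_ms / period))
  if (anyDuplicated(idx))
    stop("two samples map to the same grid position")
  n <- max(idx) + 1L
  out <- invalid_rows((seq_len(n) - 1L) * period)
  out$x_px[idx + 1L] <- df$x_px
  out$y_px[idx + 1L] <- df$y_px
  out$pupil_left_mm[idx + 1L] <- df$pupil_left_mm
  out$valid[idx + 1L] <- df$valid
  # a row whose gaze fields are all missing carries no information
  out$valid[is.na(out$valid)] <- FALSE
  sample_stream(out$t_ms, out$x_px, out$y_px, out$pupil_left_mm, out$valid,
                geometry)
}

#' Read a sample stream from a delimited text file
#'
#' Expects a CSV/TSV file with header columns
#' `t_ms, x_px, y_px, pupil_left_mm, valid`; blank fields are missing values.
#' The result is regularized to the nominal sampling grid (missing grid rows
#' become invalid placeholder samples).
#'
#' @param path File path.
#' @param geometry A [screen_geometry()].
#' @return A [sample_stream()].
#' @export
read_sample_stream <- function(path, geometry) {
  df <- tryCatch(
    data.table::fread(path, sep = "auto", na.strings = c("", "NA"),
                      data.table = FALSE),
    error = function(e) stop("parse error reading '", path, "': ",
                             conditionMessage(e)))
  need <- c("t_ms", "x_px", "y_px", "pupil_left_mm", "valid")
  if (!all(need %in% names(df)))
    stop("format error in '", path, "': missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!is.na(df$t_ms) & !is.finite(df$t_ms))
  if (length(bad))
    stop("parse error in '", path, "' at data line ", bad[1],
         ": non-numeric t_ms")
  if (any(diff(df$t_ms) <= 0))
    stop("format error in '", path, "': non-monotone timestamps")
  df$valid <- as.logical(df$valid)
  regularize_stream(df[need], geometry)
}

#' Write a sample stream to CSV
#'
#' Values are written at full precision so that
#' `read_sample_stream(write_sample_stream(s))` reproduces `s` exactly.
#'
#' @param stream A [sample_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_stream <- function(stream, path) {
  df <- as.data.frame(stream)
  data.table::fwrite(df, path, na = "", quote = FALSE)
  invisible(path)
}
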