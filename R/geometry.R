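#' Screen and recording geometry
#'
#' Describes the physical screen, its pixel resolution, the viewing distance,
#' and the eye-tracker sampling rate. Defaults correspond to a 22-inch 16:9
#' monitor viewed from 60 cm and a 120 Hz tracker.
#'
#' @param width_mm,height_mm Physical screen size in millimetres.
#' @param width_px,height_px Screen resolution in pixels.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#' @param sample_rate_hz Sampling rate of the eye tracker in Hz.
#'
#' @return An object of class `screen_geometry`: a list with the above fields
#'   plus `sample_period_ms = 1000 / sample_rate_hz`.
#' @export
#' @examples
#' geom <- screen_geometry()
#' geom$sample_period_ms
screen_geometry <- function(width_mm = 487, height_mm = 274,
                            width_px = 1920L, height_px = 1080L,
                            viewing_distance_mm = 600,
                            sample_rate_hz = 120) {
  vals <- c(width_mm, height_mm, width_px, height_px,
            viewing_distance_mm, sample_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen_geometry fields must be positive and finite")
  structure(list(
    width_mm = width_mm, height_mm = height_mm,
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    viewing_distance_mm = viewing_distance_mm,
    sample_rate_hz = sample_rate_hz,
    sample_period_ms = 1000 / sample_rate_hz
  ), class = "screen_geometry")
}

#' Convert a visual angle to an on-screen extent
#'
#' Uses the full-angle convention: an object subtending `angle_deg` at viewing
#' distance `D` spans `2 * D * tan(angle/2)` on the screen.
#'
#' @param angle_deg Visual angle in degrees, in (0, 90).
#' @param viewing_distance_mm Viewing distance in millimetres.
#' @return Extent in millimetres.
#' @export
#' @examples
#' deg_to_mm(11, 600)    # horizontal extent of an 11 degree stimulus
deg_to_mm <- function(angle_deg, viewing_distance_mm) {
  if (any(!is.finite(angle_deg)) || any(angle_deg <= 0) || any(angle_deg >= 90))
    stop("angle_deg must lie in (0, 90)")
  if (any(viewing_distance_mm <= 0))
    stop("viewing_distance_mm must be positive")
  2 * viewing_distance_mm * tan(angle_deg * pi / 360)
}

#' Area-of-interest layout in visual-angle units
#'
#' Two lateral rectangles (left/right of screen centre) covering the target
#' and distractor pictures. The horizontal offset of each AOI centre from the
#' screen centre is not a physical constant of the paradigm and is therefore
#' configurable; the default places the centres 8 degrees off-centre.
#'
#' @param width_deg,height_deg AOI extent in degrees of visual angle.
#' @param center_offset_deg Unsigned horizontal angle between screen centre
#'   and each AOI centre.
#' @return An `aoi_layout` object.
#' @export
aoi_layout <- function(width_deg = 11, height_deg = 13.6,
                       center_offset_deg = 8) {
  if (width_deg <= 0 || height_deg <= 0 || center_offset_deg <= 0)
    stop("AOI angles must be positive")
  if (center_offset_deg <= width_deg / 2)
    stop("AOIs would overlap: center_offset_deg must exceed width_deg / 2")
  structure(list(width_deg = width_deg, height_deg = height_deg,
                 center_offset_deg = center_offset_deg),
            class = "aoi_layout")
}

#' Pixel rectangles for the two AOIs
#'
#' Converts the visual-angle layout to half-open pixel rectangles
#' `[x0, x1) x [y0, y1)` with the origin at the top-left of the screen.
#'
#' @param layout An [aoi_layout()].
#' @param geometry A [screen_geometry()].
#' @return A list with elements `left` and `right`, each `c(x0, x1, y0, y1)`.
#' @export
aoi_rects <- function(layout, geometry) {
  ppmm_x <- geometry$width_px / geometry$width_mm
  ppmm_y <- geometry$height_px / geometry$height_mm
  w_px <- deg_to_mm(layout$width_deg, geometry$viewing_distance_mm) * ppmm_x
  h_px <- deg_to_mm(layout$height_deg, geometry$viewing_distance_mm) * ppmm_y
  off_px <- deg_to_mm(layout$center_offset_deg,
                      geometry$viewing_distance_mm) * ppmm_x
  cx <- geometry$width_px / 2
  cy <- geometry$height_px / 2
  rect <- function(cx_aoi) c(x0 = cx_aoi - w_px / 2, x1 = cx_aoi + w_px / 2,
                             y0 = cy - h_px / 2, y1 = cy + h_px / 2)
  out <- list(left = rect(cx - off_px), right = rect(cx + off_px))
  if (out$left[["x1"]] > out$right[["x0"]])
    stop("AOIs overlap on screen")
  if (out$left[["x0"]] < 0 || out$right[["x1"]] > geometry$width_px ||
      out$left[["y0"]] < 0 || out$left[["y1"]] > geometry$height_px)
    stop("AOIs extend beyond the screen")
  out
}

#' Classify gaze samples into AOIs
#'
#' Vectorised point-in-rectangle test with half-open rectangles: a sample on
#' the left/top edge of an AOI belongs to it; a sample on the right/bottom
#' edge does not.
#'
#' @param x_px,y_px Gaze coordinates in pixels (origin top-left).
#' @param layout An [aoi_layout()].
#' @param geometry A [screen_geometry()].
#' @return Character vector with values `"left"`, `"right"`, or `"none"`;
#'   `NA` coordinates yield `"none"`.
#' @export
aoi_hit <- function(x_px, y_px, layout, geometry) {
  r <- aoi_rects(layout, geometry)
  out <- rep("none", length(x_px))
  inrect <- function(rc) {
    !is.na(x_px) & !is.na(y_px) &
      x_px >= rc[["x0"]] & x_px < rc[["x1"]] &
      y_px >= rc[["y0"]] & y_px < rc[["y1"]]
  }
  out[inrect(r$left)] <- "left"
  out[inrect(r$right)] <- "right"
  out
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen_geometry: %gx%g mm, %dx%d px, D=%g mm, %g Hz (%.3f ms/sample)\n",
              x$width_mm, x$height_mm, x$width_px, x$height_px,
              x$viewing_distance_mm, x$sample_rate_hz, x$sample_period_ms))
  invisible(x)
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat(sprintf("aoi_layout: %g x %g deg, centres +/-%g deg off-centre\n",
              x$width_deg, x$height_deg, x$center_offset_deg))
  invisible(x)
}
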