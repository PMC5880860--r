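#' Screen and stimulus geometry
#'
#' Describes the physical viewing geometry needed to convert pixel
#' displacements into degrees of visual angle: screen and stimulus size in
#' pixels, stimulus size in mm, and a default eye-to-screen distance used when
#' a recording carries no per-sample distance. The stimulus is assumed to be
#' centered on the screen.
#'
#' @param screen_px numeric(2), screen width and height in pixels.
#' @param stimulus_px numeric(2), stimulus width and height in pixels.
#'   Defaults to the full screen.
#' @param stimulus_mm numeric(2), stimulus width and height in mm.
#' @param default_distance_mm scalar, fallback eye-to-screen distance in mm.
#'
#' @return An object of class `gaze_geometry`.
#' @examples
#' geometry(c(1280, 1024), stimulus_mm = c(340, 272))
#' @export
geometry <- function(screen_px, stimulus_px = screen_px, stimulus_mm,
                     default_distance_mm = 600) {
  stopifnot(length(screen_px) == 2, length(stimulus_px) == 2,
            length(stimulus_mm) == 2, length(default_distance_mm) == 1)
  if (any(screen_px <= 0) || any(stimulus_px <= 0) || any(stimulus_mm <= 0))
    stop("all geometry dimensions must be positive")
  if (any(stimulus_px > screen_px))
    stop("stimulus_px must not exceed screen_px")
  if (default_distance_mm <= 0)
    stop("default_distance_mm must be positive")
  structure(
    list(screen_px = as.numeric(screen_px),
         stimulus_px = as.numeric(stimulus_px),
         stimulus_mm = as.numeric(stimulus_mm),
         default_distance_mm = as.numeric(default_distance_mm)),
    class = "gaze_geometry")
}

#' @export
print.gaze_geometry <- function(x, ...) {
  cat(sprintf("<gaze_geometry> screen %gx%g px, stimulus %gx%g px / %gx%g mm, distance %g mm\n",
              x$screen_px[1], x$screen_px[2], x$stimulus_px[1], x$stimulus_px[2],
              x$stimulus_mm[1], x$stimulus_mm[2], x$default_distance_mm))
  invisible(x)
}

#' Default viewing geometry
#'
#' A 1280x1024 px full-screen stimulus of 340x272 mm viewed from 600 mm — a
#' typical 17-inch monitor setup subtending roughly 27 x 34 degrees.
#'
#' @return A [geometry()] object.
#' @export
default_geometry <- function() {
  geometry(c(1280, 1024), stimulus_mm = c(340, 272),
           default_distance_mm = 600)
}

#' Convert a pixel displacement to degrees of visual angle
#'
#' Each axis is scaled by its own mm-per-pixel factor (`stimulus_mm /
#' stimulus_px`, so anisotropic pixels are handled), the Euclidean displacement
#' in mm is formed, and the full two-point subtense formula
#' `2 * atan(d_mm / (2 * distance_mm))` gives the angle; no small-angle
#' approximation is used.
#'
#' @param dx,dy displacement in pixels (vectorised).
#' @param geometry a [geometry()] object.
#' @param distance_mm eye-to-screen distance in mm (scalar or vector).
#' @return Angle(s) in degrees of visual angle.
#' @examples
#' g <- geometry(c(1280, 1024), stimulus_mm = c(340, 272))
#' px_to_deg(128, 0, g, 600)
#' @export
px_to_deg <- function(dx, dy, geometry, distance_mm) {
  if (any(distance_mm <= 0, na.rm = TRUE))
    stop("distance_mm must be positive")
  mmpp <- geometry$stimulus_mm / geometry$stimulus_px
  d_mm <- sqrt((dx * mmpp[1])^2 + (dy * mmpp[2])^2)
  2 * atan(d_mm / (2 * distance_mm)) * 180 / pi
}

#' Convert an angle in degrees to a pixel extent along one axis
#'
#' Inverse of [px_to_deg()] for a displacement along a single axis; used by the
#' simulator to express angular noise in pixels and by the dispersion parser.
#'
#' @param deg angle in degrees.
#' @param geometry a [geometry()] object.
#' @param distance_mm eye-to-screen distance in mm.
#' @param axis 1 for x, 2 for y.
#' @return Extent in pixels.
#' @export
deg_to_px <- function(deg, geometry, distance_mm, axis = 1) {
  if (any(distance_mm <= 0, na.rm = TRUE))
    stop("distance_mm must be positive")
  mmpp <- geometry$stimulus_mm[axis] / geometry$stimulus_px[axis]
  d_mm <- 2 * distance_mm * tan(deg * pi / 360)
  d_mm / mmpp
}
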