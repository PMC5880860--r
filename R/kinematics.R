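#' Merge the two eyes into a cyclopean sample series
#'
#' When both eyes were tracked, the cyclopean gaze point is the mean of the two
#' eyes' x- and y-coordinates; where only one eye has data, that eye's
#' coordinates are used directly, so a sample is missing only when both eyes
#' are. The same rule is applied to the eye-to-screen distance, with remaining
#' missing distances filled by the trial's median distance and finally by the
#' geometry's default distance (distance varies slowly relative to gaze, so
#' these fallbacks are benign). Monocular recordings pass through unchanged.
#'
#' @param recording a [gaze_recording()].
#' @return A data frame with columns `trial`, `time`, `x`, `y`, `distance`,
#'   `missing` (logical) and `interpolated` (all `FALSE`; set later by
#'   [interpolate_gaps()]).
#' @export
cyclopean_merge <- function(recording) {
  s <- recording$samples
  lv <- !is.na(s$x_left) & !is.na(s$y_left)
  rv <- !is.na(s$x_right) & !is.na(s$y_right)
  x <- ifelse(lv & rv, (s$x_left + s$x_right) / 2,
              ifelse(lv, s$x_left, s$x_right))
  y <- ifelse(lv & rv, (s$y_left + s$y_right) / 2,
              ifelse(lv, s$y_left, s$y_right))
  dlv <- !is.na(s$distance_left)
  drv <- !is.na(s$distance_right)
  d <- ifelse(dlv & drv, (s$distance_left + s$distance_right) / 2,
              ifelse(dlv, s$distance_left, s$distance_right))
  out <- data.frame(trial = s$trial, time = s$time, x = x, y = y, distance = d,
                    missing = !(lv | rv), interpolated = FALSE)
  out$x[out$missing] <- NA_real_
  out$y[out$missing] <- NA_real_
  for (tr in unique(out$trial)) {
    i <- out$trial == tr
    di <- out$distance[i]
    if (anyNA(di)) {
      med <- stats::median(di, na.rm = TRUE)
      if (is.na(med)) med <- recording$geometry$default_distance_mm
      di[is.na(di)] <- med
      out$distance[i] <- di
    }
  }
  out
}

#' Per-sample eye speed in degrees per second
#'
#' The speed at sample i is the Euclidean distance between the preceding and
#' succeeding gaze points, converted to degrees of visual angle at sample i's
#' eye-to-screen distance, divided by the time elapsed between those
#' neighbours. The first and last sample of every trial have no central
#' difference and are invalid, as is any sample whose neighbour (or itself) is
#' missing. No prefiltering is applied; noise handling is left to the adaptive
#' threshold.
#'
#' @param series a cyclopean series from [cyclopean_merge()] (optionally after
#'   [interpolate_gaps()]).
#' @param geometry a [geometry()] object.
#' @return `series` with columns `speed` (deg/s, `NA` where invalid) and
#'   `valid` (logical) appended. Trials with fewer than 3 samples are entirely
#'   invalid.
#' @export
speed_profile <- function(series, geometry) {
  n <- nrow(series)
  speed <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (tr in unique(series$trial)) {
    idx <- which(series$trial == tr)
    m <- length(idx)
    if (m < 3) next
    i <- idx[2:(m - 1)]
    ok <- !series$missing[i - 1] & !series$missing[i] & !series$missing[i + 1]
    dx <- series$x[i + 1] - series$x[i - 1]
    dy <- series$y[i + 1] - series$y[i - 1]
    dt <- (series$time[i + 1] - series$time[i - 1]) / 1000
    ang <- px_to_deg(dx, dy, geometry, series$distance[i])
    sp <- ang / dt
    speed[i[ok]] <- sp[ok]
    valid[i] <- ok
  }
  series$speed <- speed
  series$valid <- valid
  series
}
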