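#' Local speed maxima of a trial
#'
#' Samples whose speed is strictly higher than both the preceding and
#' succeeding sample's speed are local maxima; the comparison is made only
#' between mutually valid samples, so a peak flanked by an invalid sample does
#' not qualify, and plateaus never do.
#'
#' @param profile a single-trial [speed_profile()] data frame.
#' @return Numeric vector of local-maximum speeds (possibly empty), in sample
#'   order.
#' @export
local_maxima <- function(profile) {
  sp <- profile$speed
  v <- profile$valid
  n <- length(sp)
  if (n < 3) return(numeric())
  i <- 2:(n - 1)
  ok <- v[i] & v[i - 1] & v[i + 1] &
    sp[i] > sp[i - 1] & sp[i] > sp[i + 1]
  ok[is.na(ok)] <- FALSE
  sp[i][ok]
}

#' Gap statistic of local speed maxima against a uniform null
#'
#' On an evenly spaced grid of candidate speeds v over the observed range of
#' local maxima, the observed exceedance count `S_obs(v) = #\{m > v\}` is
#' compared to the count expected under a uniform null on the same range,
#' `S_null(v) = n * (max - v) / (max - min)`. The gap is the difference of the
#' two exceedance distributions on the proportion scale,
#' `gap(v) = (S_null(v) - S_obs(v)) / n`
#' (equivalently the difference of the observed and uniform CDFs): it grows
#' while the observed density of local maxima still exceeds the uniform
#' density and peaks exactly where the dense noise-driven cluster hands over
#' to the sparse saccade-driven tail — the natural threshold location.
#'
#' @param maxima numeric vector from [local_maxima()].
#' @param grid_size number of evenly spaced candidates (default 512).
#' @return A data frame `(speed, gap)`, or `NULL` when the range is degenerate
#'   (all maxima equal).
#' @export
gap_curve <- function(maxima, grid_size = 512) {
  rng <- range(maxima)
  if (!all(is.finite(rng)) || diff(rng) <= 0) return(NULL)
  v <- seq(rng[1], rng[2], length.out = grid_size)
  s_obs <- vapply(v, function(vi) sum(maxima > vi), numeric(1))
  s_null <- length(maxima) * (rng[2] - v) / (rng[2] - rng[1])
  data.frame(speed = v, gap = (s_null - s_obs) / length(maxima))
}

#' Default loess span schedule
#'
#' Increasing bandwidths tried by [smooth_until_unimodal()]: 0.10 to 1.00 in
#' steps of 0.05, then 1.25, 1.5, 2 and 3. Spans above 1 are meaningful in
#' loess — all points enter every local fit with progressively flatter tricube
#' weights, so the fit approaches a single global quadratic, which guarantees
#' the schedule can always reach a unimodal curve for non-degenerate input.
#'
#' @return Numeric vector of spans.
#' @export
default_span_schedule <- function() {
  c(seq(0.10, 1.00, by = 0.05), 1.25, 1.5, 2, 3)
}

count_interior_modes <- function(y) {
  n <- length(y)
  if (n < 3) return(0L)
  i <- 2:(n - 1)
  sum(y[i] > y[i - 1] & y[i] > y[i + 1])
}

#' Smooth a gap curve until it is unimodal
#'
#' Fits locally weighted quadratic regressions (loess, degree 2, tricube
#' weights) to the raw gap curve over the increasing span schedule of
#' [default_span_schedule()] and returns the first fit with exactly one
#' interior local maximum. If even the largest span is not unimodal, that fit
#' is returned flagged invalid.
#'
#' @param gap a data frame from [gap_curve()].
#' @param spans increasing span schedule.
#' @return A list with `fitted` (smoothed gap values on the grid), `span`, and
#'   `valid` (`TRUE` iff the returned fit has exactly one interior maximum).
#' @export
smooth_until_unimodal <- function(gap, spans = default_span_schedule()) {
  stopifnot(nrow(gap) >= 10)
  last <- NULL
  for (s in spans) {
    fit <- try(suppressWarnings(
      stats::loess(gap ~ speed, data = gap, span = s, degree = 2,
                   family = "gaussian")), silent = TRUE)
    if (inherits(fit, "try-error")) next
    y <- stats::predict(fit, newdata = gap)
    last <- list(fitted = y, span = s,
                 valid = count_interior_modes(y) == 1L)
    if (last$valid) return(last)
  }
  if (is.null(last))
    last <- list(fitted = rep(NA_real_, nrow(gap)), span = NA_real_,
                 valid = FALSE)
  last
}

#' Estimate a per-trial velocity threshold
#'
#' Composes [local_maxima()], [gap_curve()] and [smooth_until_unimodal()]: the
#' candidate speed at the unique maximum of the smoothed gap curve is the
#' trial's velocity threshold. With fewer than `n_min` local maxima, a
#' degenerate speed range, or no unimodal smooth at any span, the estimate
#' is flagged invalid and the threshold is `NA` (the trial is reported as
#' having too little data to estimate a threshold). Ties at the smoothed
#' maximum resolve to the smallest candidate speed.
#'
#' @param profile a single-trial [speed_profile()] data frame.
#' @param grid_size grid resolution for the gap curve.
#' @param n_min minimum number of local maxima needed to attempt estimation.
#' @param spans span schedule for [smooth_until_unimodal()].
#' @return An object of class `threshold_estimate`: list with `threshold`
#'   (deg/s or `NA`), `valid`, `n_local_maxima`, `bandwidth_used`, and
#'   `gap_curve` (data frame `speed, gap, smoothed`, or `NULL`).
#' @export
estimate_threshold <- function(profile, grid_size = 512, n_min = 10,
                               spans = default_span_schedule()) {
  out <- structure(list(threshold = NA_real_, valid = FALSE,
                        n_local_maxima = 0L, bandwidth_used = NA_real_,
                        gap_curve = NULL),
                   class = "threshold_estimate")
  mx <- local_maxima(profile)
  out$n_local_maxima <- length(mx)
  if (length(mx) < n_min) return(out)
  gc <- gap_curve(mx, grid_size)
  if (is.null(gc)) return(out)
  sm <- smooth_until_unimodal(gc, spans)
  gc$smoothed <- sm$fitted
  out$gap_curve <- gc
  out$bandwidth_used <- sm$span
  if (!sm$valid) return(out)
  best <- which(sm$fitted == max(sm$fitted, na.rm = TRUE))[1]
  out$threshold <- gc$speed[best]
  out$valid <- out$threshold > min(mx) && out$threshold < max(mx)
  if (!out$valid) out$threshold <- NA_real_
  out
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<threshold_estimate> %.2f deg/s (n_maxima = %d, span = %.2f)\n",
                x$threshold, x$n_local_maxima, x$bandwidth_used))
  else
    cat(sprintf("<threshold_estimate> invalid (n_maxima = %d): not enough data to estimate a threshold\n",
                x$n_local_maxima))
  invisible(x)
}

#' Data-driven duration threshold from initial fixation durations
#'
#' Applies the same gap-statistic-plus-smoothing machinery to the distribution
#' of log initial fixation durations (the candidate fixations produced by
#' velocity classification, before duration filtering): the duration at the
#' smoothed gap maximum separates the short spurious fixations from real ones.
#' This estimator needs a lot of data; with fewer than `n_min` durations or a
#' degenerate distribution it falls back to the fixed default with a warning
#' flag. Only the "mould" parsing method uses it.
#'
#' @param durations_ms initial fixation durations in ms.
#' @param default_ms fallback duration threshold (default 100 ms).
#' @param n_min minimum number of durations to attempt estimation.
#' @param grid_size,spans passed to the gap machinery.
#' @return List with `threshold_ms` and `data_driven` (`FALSE` when the
#'   fallback was used).
#' @export
duration_threshold_data_driven <- function(durations_ms, default_ms = 100,
                                           n_min = 10, grid_size = 512,
                                           spans = default_span_schedule()) {
  fallback <- list(threshold_ms = default_ms, data_driven = FALSE)
  d <- durations_ms[is.finite(durations_ms) & durations_ms > 0]
  if (length(d) < n_min) {
    warning("too few initial fixation durations; falling back to the fixed duration threshold")
    return(fallback)
  }
  gc <- gap_curve(log(d), grid_size)
  if (is.null(gc)) {
    warning("degenerate initial fixation durations; falling back to the fixed duration threshold")
    return(fallback)
  }
  sm <- smooth_until_unimodal(gc, spans)
  if (!sm$valid) {
    warning("no unimodal gap curve for durations; falling back to the fixed duration threshold")
    return(fallback)
  }
  best <- which(sm$fitted == max(sm$fitted, na.rm = TRUE))[1]
  list(threshold_ms = exp(gc$speed[best]), data_driven = TRUE)
}

#' Export per-trial threshold diagnostics
#'
#' @param estimates named list of `threshold_estimate`s (names = trial ids).
#' @param path CSV output path.
#' @return Data frame `(trial, speed, gap, smoothed, threshold, valid)`,
#'   written to `path` when given; mirrors a "visualize threshold" view.
#' @export
threshold_diagnostics <- function(estimates, path = NULL) {
  rows <- lapply(names(estimates), function(tr) {
    e <- estimates[[tr]]
    if (is.null(e$gap_curve))
      return(data.frame(trial = tr, speed = NA_real_, gap = NA_real_,
                        smoothed = NA_real_, threshold = e$threshold,
                        valid = e$valid))
    cbind(data.frame(trial = tr), e$gap_curve,
          data.frame(threshold = e$threshold, valid = e$valid))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  out
}
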