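#' Robustness of a trial
#'
#' Mean duration of the maximal contiguous runs of valid (non-missing,
#' pre-interpolation) samples in a trial, in ms; a run of k samples at the
#' nominal rate counts as k sample periods. High values mean an uninterrupted
#' signal; 0 means no valid sample at all.
#'
#' @param missing logical vector, the trial's per-sample missingness mask.
#' @param sampling_rate nominal sampling rate, Hz.
#' @return Mean valid-segment length in ms.
#' @export
robustness <- function(missing, sampling_rate) {
  if (!any(!missing)) return(0)
  r <- rle(missing)
  mean(r$lengths[!r$values]) * 1000 / sampling_rate
}

#' Precision of a trial
#'
#' The signal is smoothed by averaging the x- and y-coordinates of the valid
#' samples in consecutive fixed time windows (default 100 ms, aligned to trial
#' start). Each window's score is the mean Euclidean distance between its raw
#' samples and the window mean; the trial's precision is the mean of the
#' window scores over windows with at least 2 valid samples. Low values
#' indicate high precision.
#'
#' @param series_t a single-trial cyclopean series (pre-interpolation).
#' @param window_ms smoothing window length, ms.
#' @return Mean deviation in px, or `NA` when no window has 2 valid samples.
#' @export
precision <- function(series_t, window_ms = 100) {
  ok <- !series_t$missing
  if (sum(ok) < 2) return(NA_real_)
  win <- floor((series_t$time - series_t$time[1]) / window_ms)
  scores <- vapply(split(which(ok), win[ok]), function(i) {
    if (length(i) < 2) return(NA_real_)
    mx <- mean(series_t$x[i]); my <- mean(series_t$y[i])
    mean(sqrt((series_t$x[i] - mx)^2 + (series_t$y[i] - my)^2))
  }, numeric(1))
  if (all(is.na(scores))) return(NA_real_)
  mean(scores, na.rm = TRUE)
}

#' Per-trial data-quality table
#'
#' Robustness and precision per trial, computed on the raw (pre-interpolation)
#' cyclopean signal so that gap interpolation cannot launder data quality.
#'
#' @param recording a [gaze_recording()].
#' @param window_ms precision window, ms.
#' @param path optional CSV output path.
#' @return Data frame `(participant, trial, robustness_ms, precision_px,
#'   n_valid, n_total)`.
#' @export
trial_quality <- function(recording, window_ms = 100, path = NULL) {
  series <- cyclopean_merge(recording)
  rows <- lapply(unique(series$trial), function(tr) {
    s <- series[series$trial == tr, , drop = FALSE]
    data.frame(participant = recording$participant, trial = tr,
               robustness_ms = robustness(s$missing, recording$sampling_rate),
               precision_px = precision(s, window_ms),
               n_valid = sum(!s$missing), n_total = nrow(s))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  out
}

#' Within-fixation position statistics
#'
#' Centroid, standard deviation of point of gaze (`sdPOG`, the pooled
#' two-dimensional SD `sqrt(var(x) + var(y))` in px, n-1 estimator) and the
#' root-mean-square of successive-sample displacements within the fixation,
#' expressed in degrees of visual angle (the conventional unit for precision
#' reporting). A single-sample fixation has `sdPOG = 0` and undefined RMS.
#'
#' @param x,y fixation sample coordinates, px.
#' @param distance_mm per-sample eye-to-screen distances, mm.
#' @param geometry a [geometry()] object.
#' @return List `(mean_x, mean_y, sdPOG, RMS)`.
#' @export
fixation_stats <- function(x, y, distance_mm, geometry) {
  n <- length(x)
  if (n == 0)
    return(list(mean_x = NA_real_, mean_y = NA_real_, sdPOG = NA_real_,
                RMS = NA_real_))
  if (n == 1)
    return(list(mean_x = x, mean_y = y, sdPOG = 0, RMS = NA_real_))
  step_deg <- px_to_deg(diff(x), diff(y), geometry,
                        (distance_mm[-1] + distance_mm[-n]) / 2)
  list(mean_x = mean(x), mean_y = mean(y),
       sdPOG = sqrt(stats::var(x) + stats::var(y)),
       RMS = sqrt(mean(step_deg^2)))
}

#' Saccade amplitude in degrees of visual angle
#'
#' Angular distance between the saccade's first and last valid sample,
#' converted at the mean of their eye-to-screen distances. Only the endpoints
#' matter, so curved and straight saccades with the same endpoints agree.
#'
#' @inheritParams fixation_stats
#' @return Amplitude in degrees, or `NA` with fewer than 2 valid samples.
#' @export
saccade_amplitude <- function(x, y, distance_mm, geometry) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  i <- which(ok)[1]
  j <- which(ok)[sum(ok)]
  px_to_deg(x[j] - x[i], y[j] - y[i], geometry,
            (distance_mm[i] + distance_mm[j]) / 2)
}

#' Correlation between data quality and fixation duration
#'
#' Pearson correlations of per-participant precision and robustness with the
#' per-participant median fixation duration. Strong correlations indicate that
#' data quality drives the parsed durations (spurious short fixations in noisy
#' data); a quality-adaptive parser should bring them towards zero. A
#' zero-variance input yields `NA` with a flag rather than an error.
#'
#' @param quality data frame with one row per participant: columns
#'   `precision`, `robustness`, `median_duration`.
#' @return List `(r_precision, r_robustness, defined)`.
#' @export
quality_outcome_correlation <- function(quality) {
  stopifnot(all(c("precision", "robustness", "median_duration") %in%
                  names(quality)))
  if (nrow(quality) < 3)
    stop("at least 3 participants are required")
  safe_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  rp <- safe_cor(quality$precision, quality$median_duration)
  rr <- safe_cor(quality$robustness, quality$median_duration)
  list(r_precision = rp, r_robustness = rr,
       defined = is.finite(rp) && is.finite(rr))
}
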