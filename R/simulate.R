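#' Specification of a synthetic gaze recording
#'
#' Generative parameters of the ground-truth scanpath simulator. A trial is an
#' alternating tiling fixation-saccade-...-fixation: fixation centers are
#' drawn uniformly over the stimulus subject to a minimum saccade amplitude;
#' fixation durations follow a lognormal law; saccades run along straight
#' lines with a raised-cosine speed profile and a main-sequence duration
#' `duration_ms = main_seq_a * amplitude_deg + main_seq_b`. Precision is
#' degraded by additive isotropic Gaussian noise (per-axis SD in degrees,
#' converted to px at the default viewing distance), robustness by a two-state
#' valid/missing flicker process applied to each eye independently. The right
#' eye is the left eye plus a fixed interocular offset, before noise.
#'
#' With `n_fixations` set, the drawn fixation durations are rescaled so the
#' events tile `trial_duration_ms` exactly and every trial contains exactly
#' that many fixations (the regime used for parameter-recovery validation);
#' with `n_fixations = NULL` events are drawn until the trial is full.
#'
#' @param sampling_rate Hz (60–500 are the regimes of interest).
#' @param n_trials trials per recording.
#' @param trial_duration_ms trial length, ms.
#' @param n_fixations fixations per trial, or `NULL` to fill freely.
#' @param fixation_median_ms,fixation_sdlog lognormal fixation-duration law.
#' @param min_saccade_deg minimum amplitude between successive fixation
#'   centers, degrees.
#' @param main_seq_a,main_seq_b main-sequence coefficients (ms/deg and ms).
#' @param noise_sd_deg per-axis precision noise SD, degrees.
#' @param flicker `NULL` for none, or `list(mean_valid_ms=, mean_missing_ms=)`.
#' @param interocular_offset_px numeric(2) right-minus-left offset, px.
#' @param geometry a [geometry()] object.
#' @param seed RNG seed; a fixed seed reproduces the recording exactly.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(sampling_rate = 500, n_trials = 5,
                            trial_duration_ms = 8000, n_fixations = 10,
                            fixation_median_ms = 300, fixation_sdlog = 0.4,
                            min_saccade_deg = 2,
                            main_seq_a = 2.2, main_seq_b = 21,
                            noise_sd_deg = 0.15, flicker = NULL,
                            interocular_offset_px = c(10, 0),
                            geometry = default_geometry(),
                            seed = 1) {
  stopifnot(sampling_rate > 0, n_trials > 0, trial_duration_ms > 0,
            fixation_median_ms > 0, fixation_sdlog > 0, min_saccade_deg > 0,
            main_seq_a > 0, main_seq_b > 0,
            inherits(geometry, "gaze_geometry"))
  if (noise_sd_deg < 0) stop("noise_sd_deg must be non-negative")
  if (!is.null(flicker)) {
    stopifnot(is.list(flicker),
              all(c("mean_valid_ms", "mean_missing_ms") %in% names(flicker)))
    if (flicker$mean_valid_ms <= 0 || flicker$mean_missing_ms <= 0)
      stop("flicker mean run lengths must be positive")
  }
  structure(as.list(environment()), class = "simulation_spec")
}

# draw fixation centers with minimum inter-center amplitude (px distance
# computed from the angular minimum at the default distance)
draw_centers <- function(n, spec) {
  g <- spec$geometry
  off <- (g$screen_px - g$stimulus_px) / 2
  min_px <- px_min_saccade(spec)
  cx <- numeric(n); cy <- numeric(n)
  cx[1] <- off[1] + runif(1) * g$stimulus_px[1]
  cy[1] <- off[2] + runif(1) * g$stimulus_px[2]
  for (k in seq_len(n)[-1]) {
    for (try in 1:200) {
      x <- off[1] + runif(1) * g$stimulus_px[1]
      y <- off[2] + runif(1) * g$stimulus_px[2]
      if (sqrt((x - cx[k - 1])^2 + (y - cy[k - 1])^2) >= min_px) break
    }
    cx[k] <- x; cy[k] <- y
  }
  cbind(cx, cy)
}

px_min_saccade <- function(spec) {
  deg_to_px(spec$min_saccade_deg, spec$geometry,
            spec$geometry$default_distance_mm, axis = 1)
}

# true event list for one trial (fixation/saccade tiling)
draw_trial_events <- function(spec) {
  g <- spec$geometry
  d <- g$default_distance_mm
  if (!is.null(spec$n_fixations)) {
    n <- spec$n_fixations
    ctr <- draw_centers(n, spec)
    fdur <- rlnorm(n, log(spec$fixation_median_ms), spec$fixation_sdlog)
    amp <- px_to_deg(diff(ctr[, 1]), diff(ctr[, 2]), g, d)
    sdur <- spec$main_seq_a * amp + spec$main_seq_b
    room <- spec$trial_duration_ms - sum(sdur)
    if (room <= n * 10)
      stop("fixation-duration law cannot fill trial_duration_ms: saccades leave no room for fixations")
    fdur <- fdur * room / sum(fdur)
  } else {
    ctr <- matrix(numeric(0), ncol = 2)
    fdur <- numeric(); sdur <- numeric(); amp <- numeric()
    t_used <- 0
    repeat {
      ctr <- rbind(ctr, draw_centers_next(ctr, spec))
      n <- nrow(ctr)
      fd <- rlnorm(1, log(spec$fixation_median_ms), spec$fixation_sdlog)
      if (n > 1) {
        a <- px_to_deg(ctr[n, 1] - ctr[n - 1, 1], ctr[n, 2] - ctr[n - 1, 2],
                       g, d)
        sd_ms <- spec$main_seq_a * a + spec$main_seq_b
        if (t_used + sd_ms + 10 > spec$trial_duration_ms) {
          ctr <- ctr[-n, , drop = FALSE]
          fdur[length(fdur)] <- fdur[length(fdur)] +
            (spec$trial_duration_ms - t_used)
          break
        }
        amp <- c(amp, a); sdur <- c(sdur, sd_ms); t_used <- t_used + sd_ms
      }
      if (t_used + fd > spec$trial_duration_ms) fd <- spec$trial_duration_ms - t_used
      fdur <- c(fdur, fd); t_used <- t_used + fd
      if (t_used >= spec$trial_duration_ms) break
    }
    if (length(fdur) == 0) stop("fixation-duration law cannot fill trial_duration_ms")
  }
  n <- length(fdur)
  kind <- character(0); dur <- numeric(0); cx <- numeric(0); cy <- numeric(0)
  for (k in seq_len(n)) {
    kind <- c(kind, "f"); dur <- c(dur, fdur[k])
    cx <- c(cx, ctr[k, 1]); cy <- c(cy, ctr[k, 2])
    if (k < n) {
      kind <- c(kind, "s"); dur <- c(dur, sdur[k])
      cx <- c(cx, NA_real_); cy <- c(cy, NA_real_)
    }
  }
  en <- cumsum(dur)
  data.frame(kind = kind, start = c(0, en[-length(en)]), end = en,
             duration = dur, cx = cx, cy = cy)
}

draw_centers_next <- function(ctr, spec) {
  g <- spec$geometry
  off <- (g$screen_px - g$stimulus_px) / 2
  min_px <- px_min_saccade(spec)
  for (try in 1:200) {
    x <- off[1] + runif(1) * g$stimulus_px[1]
    y <- off[2] + runif(1) * g$stimulus_px[2]
    if (nrow(ctr) == 0 ||
        sqrt((x - ctr[nrow(ctr), 1])^2 + (y - ctr[nrow(ctr), 2])^2) >= min_px)
      break
  }
  c(x, y)
}

# noiseless cyclopean trajectory sampled at the spec's rate
trajectory <- function(events, spec) {
  period <- 1000 / spec$sampling_rate
  t <- seq(0, spec$trial_duration_ms - period / 2, by = period)
  x <- numeric(length(t)); y <- numeric(length(t)); lab <- character(length(t))
  fx <- events[events$kind == "f", , drop = FALSE]
  for (i in seq_along(t)) {
    k <- which(events$start <= t[i] & t[i] < events$end)[1]
    if (is.na(k)) k <- nrow(events)
    if (events$kind[k] == "f") {
      x[i] <- events$cx[k]; y[i] <- events$cy[k]; lab[i] <- "f"
    } else {
      u <- (t[i] - events$start[k]) / events$duration[k]
      s <- u - sin(2 * pi * u) / (2 * pi)    # raised-cosine speed integral
      p0 <- c(events$cx[k - 1], events$cy[k - 1])
      p1 <- c(events$cx[k + 1], events$cy[k + 1])
      x[i] <- p0[1] + s * (p1[1] - p0[1])
      y[i] <- p0[2] + s * (p1[2] - p0[2])
      lab[i] <- "s"
    }
  }
  data.frame(time = t, x = x, y = y, label = lab)
}

# two-state flicker mask: TRUE = missing
flicker_mask <- function(n, flicker, sampling_rate) {
  if (is.null(flicker)) return(rep(FALSE, n))
  period <- 1000 / sampling_rate
  p_vm <- min(1, period / flicker$mean_valid_ms)
  p_mv <- min(1, period / flicker$mean_missing_ms)
  m <- logical(n)
  state <- runif(1) < p_vm / (p_vm + p_mv)  # stationary start
  for (i in seq_len(n)) {
    m[i] <- state
    state <- if (state) runif(1) >= p_mv else runif(1) < p_vm
  }
  m
}

#' Simulate a binocular gaze recording with known ground truth
#'
#' @param spec a [simulation_spec()].
#' @param participant participant id of the generated recording.
#' @return List with `recording` (a [gaze_recording()]) and `truth` (list
#'   `events`: data frame `trial, kind, start, end, duration, cx, cy`;
#'   `labels`: per-sample data frame `trial, time, label`).
#' @examples
#' sim <- simulate_gaze(simulation_spec(n_trials = 2, seed = 42))
#' sim$recording
#' head(sim$truth$events)
#' @export
simulate_gaze <- function(spec, participant = "sim") {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  g <- spec$geometry
  d <- g$default_distance_mm
  sd_px <- c(deg_to_px(spec$noise_sd_deg, g, d, axis = 1),
             deg_to_px(spec$noise_sd_deg, g, d, axis = 2))
  samples <- list(); truth_ev <- list(); truth_lab <- list()
  for (tr in seq_len(spec$n_trials)) {
    ev <- draw_trial_events(spec)
    tj <- trajectory(ev, spec)
    n <- nrow(tj)
    xl <- tj$x + rnorm(n, 0, sd_px[1])
    yl <- tj$y + rnorm(n, 0, sd_px[2])
    xr <- tj$x + spec$interocular_offset_px[1] + rnorm(n, 0, sd_px[1])
    yr <- tj$y + spec$interocular_offset_px[2] + rnorm(n, 0, sd_px[2])
    ml <- flicker_mask(n, spec$flicker, spec$sampling_rate)
    mr <- flicker_mask(n, spec$flicker, spec$sampling_rate)
    xl[ml] <- NA; yl[ml] <- NA
    xr[mr] <- NA; yr[mr] <- NA
    dl <- ifelse(ml, NA_real_, d)
    dr <- ifelse(mr, NA_real_, d)
    samples[[tr]] <- data.frame(trial = tr, time = tj$time,
                                x_left = xl, y_left = yl,
                                x_right = xr, y_right = yr,
                                distance_left = dl, distance_right = dr)
    truth_ev[[tr]] <- cbind(data.frame(trial = tr), ev)
    truth_lab[[tr]] <- data.frame(trial = tr, time = tj$time, label = tj$label)
  }
  rec <- gaze_recording(do.call(rbind, samples), participant,
                        spec$sampling_rate, g)
  list(recording = rec,
       truth = list(events = do.call(rbind, truth_ev),
                    labels = do.call(rbind, truth_lab),
                    spec = spec))
}

#' Degrade an existing recording
#'
#' Adds precision noise and/or flicker missingness to a recording, leaving the
#' input untouched so paired pristine/degraded comparisons are possible.
#' Degrading twice with noise SDs s1 and s2 is equivalent (in distribution) to
#' once with `sqrt(s1^2 + s2^2)`; flicker-only degradation leaves surviving
#' coordinates unchanged.
#'
#' @param recording a [gaze_recording()].
#' @param noise_sd_deg additional per-axis noise SD, degrees.
#' @param flicker `NULL` or `list(mean_valid_ms=, mean_missing_ms=)`, applied
#'   per eye independently.
#' @param seed RNG seed.
#' @return A new degraded [gaze_recording()].
#' @export
degrade <- function(recording, noise_sd_deg = 0, flicker = NULL, seed = 1) {
  stopifnot(inherits(recording, "gaze_recording"), noise_sd_deg >= 0)
  set.seed(seed)
  s <- recording$samples
  g <- recording$geometry
  d <- g$default_distance_mm
  n <- nrow(s)
  if (noise_sd_deg > 0) {
    sd_px <- c(deg_to_px(noise_sd_deg, g, d, axis = 1),
               deg_to_px(noise_sd_deg, g, d, axis = 2))
    s$x_left <- s$x_left + rnorm(n, 0, sd_px[1])
    s$y_left <- s$y_left + rnorm(n, 0, sd_px[2])
    s$x_right <- s$x_right + rnorm(n, 0, sd_px[1])
    s$y_right <- s$y_right + rnorm(n, 0, sd_px[2])
  }
  if (!is.null(flicker)) {
    for (tr in unique(s$trial)) {
      i <- which(s$trial == tr)
      ml <- flicker_mask(length(i), flicker, recording$sampling_rate)
      mr <- flicker_mask(length(i), flicker, recording$sampling_rate)
      s$x_left[i][ml] <- NA; s$y_left[i][ml] <- NA
      s$distance_left[i][ml] <- NA
      s$x_right[i][mr] <- NA; s$y_right[i][mr] <- NA
      s$distance_right[i][mr] <- NA
    }
  }
  out <- recording
  out$samples <- s
  out
}

#' Insert missing-data dropouts inside true fixations
#'
#' Targeted robustness degradation: picks `n` distinct ground-truth fixations
#' long enough to host a dropout plus two classifiable remnants, and blanks a
#' centred window of the drawn duration in both eyes. Used to probe whether a
#' parser's fixation count survives signal loss.
#'
#' @param recording a [gaze_recording()] from [simulate_gaze()].
#' @param truth the matching ground truth.
#' @param n dropouts per trial.
#' @param dur_range_ms dropout duration range, ms.
#' @param margin_ms minimum remnant on each side of the dropout, ms.
#' @param seed RNG seed.
#' @return List `(recording, dropouts)` where `dropouts` is a data frame
#'   `trial, start, end` of the blanked windows.
#' @export
insert_dropouts <- function(recording, truth, n = 3,
                            dur_range_ms = c(80, 200), margin_ms = 150,
                            seed = 1) {
  set.seed(seed)
  s <- recording$samples
  drops <- list()
  for (tr in unique(s$trial)) {
    fx <- truth$events[truth$events$trial == tr &
                         truth$events$kind == "f", , drop = FALSE]
    eligible <- fx[fx$duration >= dur_range_ms[2] + 2 * margin_ms, ,
                   drop = FALSE]
    if (!nrow(eligible)) next
    pick <- eligible[sample(nrow(eligible), min(n, nrow(eligible))), ,
                     drop = FALSE]
    for (k in seq_len(nrow(pick))) {
      dur <- runif(1, dur_range_ms[1], dur_range_ms[2])
      mid <- (pick$start[k] + pick$end[k]) / 2
      w0 <- mid - dur / 2; w1 <- mid + dur / 2
      i <- which(s$trial == tr & s$time >= w0 & s$time < w1)
      s$x_left[i] <- NA; s$y_left[i] <- NA; s$distance_left[i] <- NA
      s$x_right[i] <- NA; s$y_right[i] <- NA; s$distance_right[i] <- NA
      drops[[length(drops) + 1]] <- data.frame(trial = tr, start = w0,
                                               end = w1)
    }
  }
  out <- recording
  out$samples <- s
  list(recording = out,
       dropouts = if (length(drops)) do.call(rbind, drops) else
         data.frame(trial = integer(), start = numeric(), end = numeric()))
}

#' Write a simulation to disk in the raw-sample dialect
#'
#' Writes the recording via [write_recording()] (readable back with
#' [simulated_column_map()]) and the ground-truth event list as a second CSV.
#'
#' @param sim result of [simulate_gaze()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raw <- file.path(dir, paste0(sim$recording$participant, ".csv"))
  tru <- file.path(dir, paste0(sim$recording$participant, "_truth.csv"))
  write_recording(sim$recording, raw)
  utils::write.table(sim$truth$events, tru, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(c(raw = raw, truth = tru))
}
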