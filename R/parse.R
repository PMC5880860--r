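#' Parser configuration
#'
#' Bundles the tunable parameters of the five parsing methods:
#'
#' * `gazepath`: per-trial adaptive velocity threshold, interpolation of short
#'   missing-data runs, spatial-overlap merging of successive fixations, fixed
#'   duration threshold.
#' * `mould`: adaptive velocity threshold plus a data-driven duration
#'   threshold estimated from initial fixation durations; no interpolation, no
#'   overlap merge.
#' * `mouldDur`: as `mould` but with the fixed duration threshold.
#' * `velocity`: fixed velocity threshold (35 deg/s) and fixed duration
#'   threshold (100 ms); no interpolation, no merge.
#' * `dispersion`: I-DT-style — a fixation grows while every sample stays
#'   within `dispersion_radius_deg` of the running centroid, ends when
#'   exceeded; 100-ms minimum duration.
#'
#' @param method one of `"gazepath"`, `"mould"`, `"mouldDur"`,
#'   `"dispersion"`, `"velocity"`.
#' @param interpolation_max_gap_ms missing-data runs strictly shorter than
#'   this are candidates for interpolation (default 250 ms, shorter than the
#'   ~200 ms it takes to program a saccade).
#' @param duration_threshold_ms minimum fixation duration (default 100 ms;
#'   fixations are kept iff duration >= threshold).
#' @param fixed_velocity_threshold velocity threshold of the `velocity`
#'   method, deg/s.
#' @param dispersion_radius_deg dispersion radius of the `dispersion` method,
#'   degrees.
#' @param grid_size,n_min,spans passed to [estimate_threshold()].
#' @return An object of class `parser_config`.
#' @export
parser_config <- function(method = c("gazepath", "mould", "mouldDur",
                                     "dispersion", "velocity"),
                          interpolation_max_gap_ms = 250,
                          duration_threshold_ms = 100,
                          fixed_velocity_threshold = 35,
                          dispersion_radius_deg = 0.9,
                          grid_size = 512, n_min = 10,
                          spans = default_span_schedule()) {
  method <- match.arg(method)
  stopifnot(interpolation_max_gap_ms > 0, duration_threshold_ms > 0,
            fixed_velocity_threshold > 0, dispersion_radius_deg > 0)
  structure(list(method = method,
                 interpolation_max_gap_ms = interpolation_max_gap_ms,
                 duration_threshold_ms = duration_threshold_ms,
                 fixed_velocity_threshold = fixed_velocity_threshold,
                 dispersion_radius_deg = dispersion_radius_deg,
                 grid_size = grid_size, n_min = n_min, spans = spans),
            class = "parser_config")
}

#' Interpolate short missing-data runs
#'
#' Missing-data runs strictly shorter than `max_gap_ms` are filled by linear
#' interpolation of x and y between the flanking measured samples, but only
#' when the bridging velocity (the angular distance between the last sample
#' before and the first sample after the run, divided by the elapsed time)
#' does not exceed the trial's velocity threshold — ensuring no saccade took
#' place during the signal loss. Runs touching a trial edge are never filled.
#' A run of k missing samples at the nominal rate counts as k sample periods.
#'
#' @param series a cyclopean series ([cyclopean_merge()]).
#' @param threshold velocity threshold in deg/s (from a valid
#'   [estimate_threshold()]); interpolation requires a defined threshold.
#' @param max_gap_ms maximum gap duration (exclusive), default 250 ms.
#' @param geometry a [geometry()] object.
#' @param sampling_rate nominal sampling rate, Hz.
#' @return `series` with qualifying runs filled and flagged
#'   `interpolated = TRUE`.
#' @export
interpolate_gaps <- function(series, threshold, max_gap_ms = 250, geometry,
                             sampling_rate) {
  if (!is.finite(threshold)) return(series)
  period <- 1000 / sampling_rate
  for (tr in unique(series$trial)) {
    idx <- which(series$trial == tr)
    miss <- series$missing[idx]
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      if (a == 1 || b == length(idx)) next      # no flank at a trial edge
      i0 <- idx[a - 1]; i1 <- idx[b + 1]        # flanking measured samples
      gap_ms <- series$time[i1] - series$time[i0] - period
      if (gap_ms >= max_gap_ms) next
      dt_s <- (series$time[i1] - series$time[i0]) / 1000
      ang <- px_to_deg(series$x[i1] - series$x[i0],
                       series$y[i1] - series$y[i0], geometry,
                       (series$distance[i0] + series$distance[i1]) / 2)
      if (ang / dt_s > threshold) next          # a saccade may have occurred
      g <- idx[a:b]
      w <- (series$time[g] - series$time[i0]) /
        (series$time[i1] - series$time[i0])
      series$x[g] <- series$x[i0] + w * (series$x[i1] - series$x[i0])
      series$y[g] <- series$y[i0] + w * (series$y[i1] - series$y[i0])
      series$missing[g] <- FALSE
      series$interpolated[g] <- TRUE
    }
  }
  series
}

#' Classify samples by velocity and extract candidate events
#'
#' Valid samples with speed strictly below the threshold are fixation
#' candidates (`"f"`), samples at or above it saccade candidates (`"s"`);
#' missing or invalid-speed samples are gaps (`"g"`). Maximal runs of equal
#' labels become candidate events; gap runs terminate events on both sides.
#'
#' @param profile a [speed_profile()] data frame (single or multi trial).
#' @param threshold velocity threshold in deg/s.
#' @return List with `labels` (per-sample character vector) and `events`
#'   (data frame `trial, kind, i0, i1` of row indices into `profile`, gaps
#'   excluded).
#' @export
classify_by_velocity <- function(profile, threshold) {
  stopifnot(is.finite(threshold))
  lab <- ifelse(!profile$valid | profile$missing, "g",
                ifelse(profile$speed < threshold, "f", "s"))
  events <- run_events(lab, profile$trial)
  list(labels = lab, events = events)
}

# maximal runs of equal labels within trial; "g" runs dropped
run_events <- function(labels, trial) {
  out <- list()
  for (tr in unique(trial)) {
    idx <- which(trial == tr)
    r <- rle(labels[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != "g"
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      trial = tr, kind = r$values[keep],
      i0 = idx[starts[keep]], i1 = idx[ends[keep]])
  }
  if (!length(out))
    return(data.frame(trial = integer(), kind = character(),
                      i0 = integer(), i1 = integer()))
  do.call(rbind, out)
}

#' Merge successive fixations that overlap in space
#'
#' A polygon (the convex hull of its sample coordinates; degenerate hulls use
#' a small disc around the centroid, radius one median intra-fixation RMS) is
#' drawn around every candidate fixation. When two successive fixations —
#' ignoring intervening saccade or gap material — have intersecting polygons,
#' they are merged into one fixation together with everything between them.
#' The check is repeated until no successive pair overlaps, so chains collapse
#' to a fixpoint.
#'
#' @param events candidate events from [classify_by_velocity()].
#' @param series the cyclopean series the indices refer to.
#' @param geometry a [geometry()] object (unused by the hull test itself,
#'   kept for interface symmetry).
#' @return Events with overlapping successive fixations merged; saccade
#'   events absorbed by a merge are removed.
#' @export
merge_overlapping_fixations <- function(events, series, geometry = NULL) {
  if (!nrow(events)) return(events)
  out <- list()
  for (tr in unique(events$trial)) {
    ev <- events[events$trial == tr, , drop = FALSE]
    fx <- ev[ev$kind == "f", , drop = FALSE]
    if (nrow(fx) < 2) { out[[length(out) + 1]] <- ev; next }
    fix_pts <- function(k) {      # measured samples only (a merged span may
      i <- fx$i0[k]:fx$i1[k]      # contain gap material)
      i[!series$missing[i]]
    }
    rms_px <- vapply(seq_len(nrow(fx)), function(k) {
      i <- fix_pts(k)
      if (length(i) < 2) return(NA_real_)
      sqrt(mean(diff(series$x[i])^2 + diff(series$y[i])^2))
    }, numeric(1))
    disc_r <- stats::median(rms_px, na.rm = TRUE)
    if (!is.finite(disc_r)) disc_r <- 0
    poly <- lapply(seq_len(nrow(fx)), function(k) {
      i <- fix_pts(k)
      fixation_polygon(series$x[i], series$y[i], disc_r)
    })
    repeat {
      merged <- FALSE
      k <- 1
      while (k < nrow(fx)) {
        if (convex_polygons_intersect(poly[[k]], poly[[k + 1]])) {
          fx$i1[k] <- fx$i1[k + 1]
          fx <- fx[-(k + 1), , drop = FALSE]
          i <- fix_pts(k)
          poly[[k]] <- fixation_polygon(series$x[i], series$y[i], disc_r)
          poly[[k + 1]] <- NULL
          merged <- TRUE
        } else k <- k + 1
      }
      if (!merged) break
    }
    # rebuild: merged fixations plus the saccades not swallowed by a merge
    sc <- ev[ev$kind == "s", , drop = FALSE]
    if (nrow(sc))
      sc <- sc[!vapply(seq_len(nrow(sc)), function(k)
        any(sc$i0[k] >= fx$i0 & sc$i1[k] <= fx$i1), logical(1)), ,
        drop = FALSE]
    ev2 <- rbind(fx, sc)
    out[[length(out) + 1]] <- ev2[order(ev2$i0), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove fixations shorter than the duration threshold
#'
#' Fixations with duration below `min_duration_ms` are relabelled as
#' unclassified (dropped from the event list; their samples rejoin no event).
#' Saccades are unaffected, and surviving events keep their start/end
#' unchanged. The boundary is inclusive: a fixation exactly at the threshold
#' is kept.
#'
#' @param events candidate events (`trial, kind, i0, i1`).
#' @param min_duration_ms duration threshold, default 100 ms.
#' @param series the cyclopean series (for timestamps).
#' @param period one nominal sample period in ms (event duration uses the
#'   half-open convention: last sample's timestamp + one period).
#' @return Filtered events.
#' @export
apply_duration_threshold <- function(events, min_duration_ms = 100, series,
                                     period) {
  if (!nrow(events)) return(events)
  dur <- series$time[events$i1] - series$time[events$i0] + period
  keep <- events$kind != "f" | dur >= min_duration_ms
  res <- events[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# run one trial's pipeline on its cyclopean series; returns candidate events
# (before any duration threshold for the adaptive/velocity family) plus
# diagnostics
parse_trial_core <- function(series_t, geometry, sampling_rate, config) {
  period <- 1000 / sampling_rate
  prof <- speed_profile(series_t, geometry)
  est <- NULL
  if (config$method %in% c("gazepath", "mould", "mouldDur")) {
    est <- estimate_threshold(prof, grid_size = config$grid_size,
                              n_min = config$n_min, spans = config$spans)
    if (!est$valid)
      return(list(events = run_events(character(0), integer(0)),
                  estimate = est, series = series_t, period = period))
    thr <- est$threshold
  } else if (config$method == "velocity") {
    thr <- config$fixed_velocity_threshold
  }

  if (config$method == "dispersion") {
    ev <- dispersion_events(series_t, geometry, config$dispersion_radius_deg,
                            config$duration_threshold_ms, period)
    return(list(events = ev, estimate = NULL, series = series_t,
                period = period))
  }

  if (config$method == "gazepath") {
    series_t <- interpolate_gaps(series_t, thr,
                                 config$interpolation_max_gap_ms, geometry,
                                 sampling_rate)
    prof <- speed_profile(series_t, geometry)
  }
  cls <- classify_by_velocity(prof, thr)
  ev <- cls$events
  if (config$method == "gazepath")
    ev <- merge_overlapping_fixations(ev, prof, geometry)
  list(events = ev, estimate = est, series = prof, period = period)
}

# I-DT-style dispersion parser: fixation grows while each sample stays within
# radius_deg of the running centroid; missing samples end the window; windows
# >= min_dur_ms are fixations, the remaining measured material saccades.
dispersion_events <- function(series_t, geometry, radius_deg, min_dur_ms,
                              period) {
  n <- nrow(series_t)
  lab <- rep("g", n)
  i <- 1
  while (i <= n) {
    if (series_t$missing[i]) { i <- i + 1; next }
    j <- i
    cx <- series_t$x[i]; cy <- series_t$y[i]
    while (j < n && !series_t$missing[j + 1]) {
      dx <- series_t$x[j + 1] - cx
      dy <- series_t$y[j + 1] - cy
      ang <- px_to_deg(dx, dy, geometry, series_t$distance[j + 1])
      if (ang > radius_deg) break
      j <- j + 1
      m <- j - i + 1
      cx <- cx + (series_t$x[j] - cx) / m
      cy <- cy + (series_t$y[j] - cy) / m
    }
    dur <- series_t$time[j] - series_t$time[i] + period
    lab[i:j] <- if (dur >= min_dur_ms) "f" else "s"
    i <- j + 1
  }
  run_events(lab, series_t$trial)
}

#' Parse a single trial
#'
#' Runs the configured pipeline on one trial and returns its classified
#' events. For the `mould` method the data-driven duration threshold needs the
#' whole recording, so this convenience wrapper estimates it from this trial's
#' initial fixation durations alone; use [parse_recording()] for the pooled
#' estimate.
#'
#' @param recording a [gaze_recording()].
#' @param trial trial id.
#' @param config a [parser_config()].
#' @return Event table rows for that trial (see [parse_recording()]).
#' @export
parse_trial <- function(recording, trial, config = parser_config("gazepath")) {
  keep <- recording$samples$trial == trial
  if (!any(keep)) stop("no such trial: ", trial)
  rec1 <- recording
  rec1$samples <- recording$samples[keep, , drop = FALSE]
  parse_recording(rec1, config)
}

#' Parse a recording into an event table
#'
#' Runs the selected parsing method over every trial of a recording and
#' returns the event table in the fixed output schema: `Participant`, `Value`
#' (`"f"`/`"s"`), `Duration`, `Start`, `End` (ms from trial start; end = last
#' sample + one nominal period), `mean_x`, `mean_y` (px centroid),
#' `sdPOGsacAMP` (standard deviation of point of gaze in px for fixations;
#' saccade amplitude in degrees for saccades), `RMS` (root-mean-square
#' sample-to-sample displacement within fixations, degrees), `Order` (1-based
#' within trial), `Trial`, then any per-trial extra variables. Trials whose
#' adaptive threshold cannot be estimated yield no events and are flagged in
#' the diagnostics attribute.
#'
#' For the `mould` method the duration threshold is first estimated from the
#' initial fixation durations pooled over the whole recording
#' ([duration_threshold_data_driven()]); all other methods use the fixed
#' `duration_threshold_ms`.
#'
#' @param recording a [gaze_recording()].
#' @param config a [parser_config()].
#' @return The event table, with attributes `diagnostics` (per-trial data
#'   frame: trial, threshold, n_local_maxima, bandwidth, valid, n_events) and
#'   `thresholds` (named list of [estimate_threshold()] results).
#' @examples
#' sim <- simulate_gaze(simulation_spec(n_trials = 1, seed = 7))
#' ev <- parse_recording(sim$recording, parser_config("gazepath"))
#' head(ev)
#' @export
parse_recording <- function(recording, config = parser_config("gazepath")) {
  stopifnot(inherits(recording, "gaze_recording"),
            inherits(config, "parser_config"))
  series <- cyclopean_merge(recording)
  trials <- unique(series$trial)
  period <- 1000 / recording$sampling_rate

  cores <- lapply(trials, function(tr)
    parse_trial_core(series[series$trial == tr, , drop = FALSE],
                     recording$geometry, recording$sampling_rate, config))
  names(cores) <- as.character(trials)

  if (config$method == "mould") {
    init_dur <- unlist(lapply(cores, function(cr) {
      f <- cr$events[cr$events$kind == "f", , drop = FALSE]
      if (!nrow(f)) return(numeric())
      cr$series$time[f$i1] - cr$series$time[f$i0] + cr$period
    }))
    dur_thr <- suppressWarnings(
      duration_threshold_data_driven(init_dur,
                                     default_ms = config$duration_threshold_ms))$threshold_ms
  } else dur_thr <- config$duration_threshold_ms

  rows <- list()
  diags <- list()
  for (tr in trials) {
    cr <- cores[[as.character(tr)]]
    ev <- if (config$method == "dispersion") cr$events else
      apply_duration_threshold(cr$events, dur_thr, cr$series, cr$period)
    diags[[length(diags) + 1]] <- data.frame(
      trial = tr,
      threshold = if (is.null(cr$estimate)) NA_real_ else cr$estimate$threshold,
      n_local_maxima = if (is.null(cr$estimate)) NA_integer_ else cr$estimate$n_local_maxima,
      bandwidth = if (is.null(cr$estimate)) NA_real_ else cr$estimate$bandwidth_used,
      valid = if (is.null(cr$estimate)) TRUE else cr$estimate$valid,
      n_events = nrow(ev))
    if (!nrow(ev)) next
    ev <- ev[order(ev$i0), , drop = FALSE]
    st <- cr$series$time[ev$i0]
    en <- cr$series$time[ev$i1] + cr$period
    stats_m <- t(vapply(seq_len(nrow(ev)), function(k) {
      i <- ev$i0[k]:ev$i1[k]
      s <- cr$series[i, , drop = FALSE]
      s <- s[!s$missing, , drop = FALSE]
      if (ev$kind[k] == "f") {
        fs <- fixation_stats(s$x, s$y, s$distance, recording$geometry)
        c(fs$mean_x, fs$mean_y, fs$sdPOG, fs$RMS)
      } else {
        amp <- saccade_amplitude(s$x, s$y, s$distance, recording$geometry)
        c(mean(s$x), mean(s$y), amp, NA_real_)
      }
    }, numeric(4)))
    rows[[length(rows) + 1]] <- data.frame(
      Participant = recording$participant,
      Value = ev$kind,
      Duration = en - st,
      Start = st, End = en,
      mean_x = stats_m[, 1], mean_y = stats_m[, 2],
      sdPOGsacAMP = stats_m[, 3], RMS = stats_m[, 4],
      Order = seq_len(nrow(ev)),
      Trial = tr)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(event_schema))),
                    event_schema)
  rownames(out) <- NULL
  if (!is.null(recording$extras) && nrow(out)) {
    idx <- match(out$Trial, recording$extras$trial)
    for (nm in setdiff(names(recording$extras), "trial"))
      out[[nm]] <- recording$extras[[nm]][idx]
  }
  attr(out, "diagnostics") <- do.call(rbind, diags)
  attr(out, "thresholds") <- lapply(cores, `[[`, "estimate")
  out
}
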