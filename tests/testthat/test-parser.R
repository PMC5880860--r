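g60 <- function(...) simulation_spec(sampling_rate = 60, ...)

test_that("gap interpolation honours duration and bridging-velocity guards", {
  geom <- test_geometry()
  stationary_gap <- function(gap_ms, sep_px = 0) {
    # 1000 Hz so gap durations land on exact milliseconds
    n_gap <- gap_ms
    x <- c(rep(100, 50), rep(NA, n_gap), rep(100 + sep_px, 50))
    rec <- make_recording(x, rep(100, length(x)), rate = 1000, geom = geom)
    cyclopean_merge(rec)
  }
  # 249-ms stationary gap: filled with the constant flank position
  s1 <- interpolate_gaps(stationary_gap(249), threshold = 35,
                         max_gap_ms = 250, geometry = geom,
                         sampling_rate = 1000)
  expect_false(any(s1$missing))
  expect_true(all(s1$x[51:299] == 100))
  expect_true(all(s1$interpolated[51:299]))

  # 251-ms gap: untouched
  s2 <- interpolate_gaps(stationary_gap(251), threshold = 35,
                         max_gap_ms = 250, geometry = geom,
                         sampling_rate = 1000)
  expect_equal(sum(s2$missing), 251)

  # 100-ms gap with ~10 degree flank separation: bridging speed >> threshold
  sep <- deg_to_px(10, geom, 600, axis = 1)
  s3 <- interpolate_gaps(stationary_gap(100, sep_px = sep), threshold = 35,
                         max_gap_ms = 250, geometry = geom,
                         sampling_rate = 1000)
  expect_equal(sum(s3$missing), 100)
})

test_that("velocity classification yields runs with exact boundaries", {
  prof <- make_profile(c(5, 5, 5, 90, 95, 92, 5, 5, 5))
  cls <- classify_by_velocity(prof, 50)
  expect_equal(cls$events$kind, c("f", "s", "f"))
  expect_equal(cls$events$i0, c(1, 4, 7))
  expect_equal(cls$events$i1, c(3, 6, 9))

  # gap run splits a fixation into two candidates
  profg <- make_profile(c(5, 5, 5, NA, NA, 5, 5, 5),
                        valid = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                                  TRUE))
  clsg <- classify_by_velocity(profg, 50)
  expect_equal(clsg$events$kind, c("f", "f"))
  expect_equal(nrow(clsg$events), 2)

  # all below threshold: one fixation run over the valid span
  cls0 <- classify_by_velocity(make_profile(rep(1, 6)), 50)
  expect_equal(nrow(cls0$events), 1)
})

test_that("spatial-overlap merge combines, chains, and is idempotent", {
  geom <- test_geometry()
  set.seed(11)
  mk_series <- function(centers, n_each = 20, jitter = 2) {
    x <- unlist(lapply(centers[, 1], function(c) c + rnorm(n_each, 0, jitter)))
    y <- unlist(lapply(centers[, 2], function(c) c + rnorm(n_each, 0, jitter)))
    ser <- cyclopean_merge(make_recording(x, y, geom = geom))
    ser
  }
  events <- function(n_fix, n_each = 20)
    data.frame(trial = 1, kind = "f",
               i0 = seq(1, by = n_each, length.out = n_fix),
               i1 = seq(n_each, by = n_each, length.out = n_fix))

  # far-apart fixations stay apart
  far <- mk_series(cbind(c(100, 800), c(100, 800)))
  m1 <- merge_overlapping_fixations(events(2), far, geom)
  expect_equal(nrow(m1), 2)

  # same-point fixations merge into one spanning both
  near <- mk_series(cbind(c(400, 401), c(400, 399)))
  m2 <- merge_overlapping_fixations(events(2), near, geom)
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$i0, m2$i1), c(1, 40))

  # chain A~B, (A u B)~C collapses fully
  chain <- mk_series(cbind(c(400, 404, 408), c(400, 400, 400)), jitter = 3)
  m3 <- merge_overlapping_fixations(events(3), chain, geom)
  expect_equal(nrow(m3), 1)

  # idempotence: running merge on its own output changes nothing
  expect_identical(merge_overlapping_fixations(m3, chain, geom), m3)
})

test_that("duration threshold keeps the boundary fixation and only filters", {
  ser <- cyclopean_merge(make_recording(rep(0, 250), rep(0, 250), rate = 1000))
  # durations at 1000 Hz are i1 - i0 + 1 ms: 99 ms, 3 ms, 100 ms
  ev <- data.frame(trial = 1, kind = c("f", "s", "f"),
                   i0 = c(1, 100, 103), i1 = c(99, 102, 202))
  out <- apply_duration_threshold(ev, 100, ser, period = 1)
  expect_equal(out$kind, c("s", "f"))
  expect_equal(out$i0[out$kind == "f"], 103)   # survivors unchanged
  expect_equal(nrow(apply_duration_threshold(ev[0, ], 100, ser, 1)), 0)
})

test_that("all methods agree on clean recordings", {
  # exactly noiseless: the fixed-threshold parsers recover the truth
  # (the adaptive estimator needs noise-generated local maxima, so it is
  # exercised at near-zero noise below)
  sim0 <- simulate_gaze(simulation_spec(n_trials = 1, noise_sd_deg = 0,
                                        n_fixations = 5,
                                        trial_duration_ms = 4000, seed = 21))
  prof0 <- speed_profile(cyclopean_merge(sim0$recording),
                         sim0$recording$geometry)
  lab0 <- sim0$truth$labels$label
  n0 <- length(lab0)
  core_f <- lab0 == "f" & c("", lab0[-n0]) == "f" & c(lab0[-1], "") == "f"
  expect_true(all(prof0$speed[core_f & prof0$valid] == 0, na.rm = TRUE))
  for (m in c("dispersion", "velocity"))
    expect_equal(sum(parse_recording(sim0$recording,
                                     parser_config(m))$Value == "f"), 5)

  # near-noiseless: all five methods agree on the fixation count
  sim <- simulate_gaze(simulation_spec(n_trials = 1, noise_sd_deg = 0.02,
                                       n_fixations = 5,
                                       trial_duration_ms = 4000, seed = 21))
  counts <- sapply(c("gazepath", "mould", "mouldDur", "dispersion",
                     "velocity"),
                   function(m) {
                     ev <- parse_recording(sim$recording, parser_config(m))
                     sum(ev$Value == "f")
                   })
  expect_true(all(counts == 5))
})

test_that("flicker inside a fixation splits fixed-threshold parses only", {
  spec <- g60(n_trials = 1, noise_sd_deg = 0.15, seed = 31)
  sim <- simulate_gaze(spec)
  drop <- insert_dropouts(sim$recording, sim$truth, n = 3,
                          dur_range_ms = c(80, 80), seed = 32)
  gp <- parse_recording(drop$recording, parser_config("gazepath"))
  ve <- parse_recording(drop$recording, parser_config("velocity"))
  base <- sum(parse_recording(sim$recording,
                              parser_config("velocity"))$Value == "f")
  expect_equal(sum(gp$Value == "f"),
               sum(sim$truth$events$kind == "f"))
  expect_gt(sum(ve$Value == "f"), base)
})

test_that("low precision inflates dispersion counts relative to gazepath", {
  more <- 0
  for (seed in 1:10) {
    sim <- simulate_gaze(g60(n_trials = 1, noise_sd_deg = 0.5, seed = seed))
    nd <- sum(parse_recording(sim$recording,
                              parser_config("dispersion"))$Value == "f")
    ng <- sum(parse_recording(sim$recording,
                              parser_config("gazepath"))$Value == "f")
    more <- more + (nd > ng)
  }
  expect_gte(more, 6)   # majority of seeds
})

test_that("parsing is deterministic and events never overlap", {
  sim <- simulate_gaze(simulation_spec(n_trials = 2, noise_sd_deg = 0.3,
                                       seed = 13,
                                       flicker = list(mean_valid_ms = 500,
                                                      mean_missing_ms = 50)))
  e1 <- parse_recording(sim$recording, parser_config("gazepath"))
  e2 <- parse_recording(sim$recording, parser_config("gazepath"))
  expect_identical(e1, e2)
  for (tr in unique(e1$Trial)) {
    ev <- e1[e1$Trial == tr, ]
    ev <- ev[order(ev$Start), ]
    expect_true(all(diff(ev$Order) == 1))
    if (nrow(ev) > 1)
      expect_true(all(ev$Start[-1] >= ev$End[-nrow(ev)] - 1e-9))
    expect_true(all(ev$End <= max(sim$recording$samples$time[
      sim$recording$samples$trial == tr]) + 1000 / 500 + 1e-9))
    expect_equal(ev$Duration, ev$End - ev$Start)
  }
})

test_that("unknown trial or method are configuration errors", {
  sim <- simulate_gaze(simulation_spec(n_trials = 1,
                                       trial_duration_ms = 1000,
                                       n_fixations = 2, seed = 1))
  expect_error(parse_trial(sim$recording, 99), "no such trial")
  expect_error(parser_config("fancy"))
})

test_that("fixation splits and unmatched fixations are flagged", {
  a <- data.frame(Participant = "p", Value = c("f", "s", "f"),
                  Duration = c(300, 40, 200), Start = c(0, 300, 340),
                  End = c(300, 340, 540), mean_x = 0, mean_y = 0,
                  sdPOGsacAMP = 0, RMS = 0, Order = 1:3, Trial = 1)
  expect_true(all(!compare_parsings(a, a, 2)$split))
  expect_true(all(!compare_parsings(a, a, 2)$unmatched))

  # first fixation of b cut at its midpoint
  b <- data.frame(Participant = "p", Value = c("f", "f", "s", "f"),
                  Duration = c(148, 148, 40, 200),
                  Start = c(0, 152, 300, 340), End = c(148, 300, 340, 540),
                  mean_x = 0, mean_y = 0, sdPOGsacAMP = 0, RMS = 0,
                  Order = 1:4, Trial = 1)
  cmp <- compare_parsings(a, b, 2)
  expect_equal(cmp$contained[1], 2)
  expect_true(cmp$split[1])

  # fixation absent from b entirely
  b2 <- b[b$Start < 300, ]
  cmp2 <- compare_parsings(a, b2, 2)
  expect_true(cmp2$unmatched[2])

  # mismatched trial sets error out
  a2 <- a; a2$Trial <- 2
  expect_error(compare_parsings(a, a2, 2), "different trial sets")

  s <- compare_summary(a, b, 2)
  expect_equal(s$n_fixations, c(2, 3))
  expect_equal(s$n_split, c(1, 0))
  expect_equal(s$n_extra, c(1, 0))
})
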