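test_that("local maxima require strict dominance over valid neighbours", {
  expect_equal(local_maxima(make_profile(c(1, 2, 3, 4, 5))), numeric(0))
  expect_equal(local_maxima(make_profile(c(1, 3, 2, 5, 4))), c(3, 5))
  expect_equal(local_maxima(make_profile(c(1, 3, 3, 1))), numeric(0))
  # invalid neighbour blocks the comparison
  expect_equal(local_maxima(make_profile(c(1, 5, 2, 9, 2),
                                         valid = c(TRUE, TRUE, FALSE, TRUE,
                                                   TRUE))),
               numeric(0))
})

test_that("gap curve matches its definition and flags degeneracy", {
  # uniform sample: observed matches the null almost everywhere
  set.seed(1)
  u <- runif(1000, 10, 200)
  gc <- gap_curve(u)
  expect_lt(max(abs(gc$gap)), 0.1)

  # two tight clusters: raw argmax strictly between them
  lo <- rnorm(200, 5, 0.2)
  hi <- rnorm(20, 80, 0.5)
  m <- c(lo, hi)
  gc2 <- gap_curve(m)
  expect_equal(gc2$gap, oracle_gap(m), tolerance = 1e-12)
  peak <- gc2$speed[which.max(gc2$gap)]
  expect_gt(peak, stats::quantile(lo, 0.95))
  expect_lt(peak, min(hi))

  expect_null(gap_curve(rep(3, 50)))
})

test_that("smoothing stops at the first unimodal span", {
  x <- seq(0, 1, length.out = 200)
  uni <- data.frame(speed = x, gap = exp(-(x - 0.4)^2 / 0.02))
  sm <- smooth_until_unimodal(uni)
  expect_true(sm$valid)
  expect_equal(sm$span, 0.10)
  expect_lt(abs(uni$speed[which.max(sm$fitted)] - 0.4), 2 / 200)

  # two unequal modes with jitter: smoothed mode within their hull
  set.seed(2)
  bim <- data.frame(speed = x,
                    gap = exp(-(x - 0.25)^2 / 0.004) +
                      0.6 * exp(-(x - 0.7)^2 / 0.004) + rnorm(200, 0, 0.02))
  sm2 <- smooth_until_unimodal(bim)
  expect_true(sm2$valid)
  expect_equal(oracle_mode_count(sm2$fitted), 1L)
  mode <- bim$speed[which.max(sm2$fitted)]
  expect_gt(mode, 0.25 - 0.05)
  expect_lt(mode, 0.70 + 0.05)

  # constant curve has no strict interior maximum at any span
  flat <- data.frame(speed = x, gap = rep(1, 200))
  expect_false(smooth_until_unimodal(flat)$valid)
})

test_that("threshold estimation separates noise from saccade speeds", {
  sim <- simulate_gaze(simulation_spec(n_trials = 1, noise_sd_deg = 0.15,
                                       seed = 9))
  g <- sim$recording$geometry
  ser <- cyclopean_merge(sim$recording)
  prof <- speed_profile(ser, g)
  est <- estimate_threshold(prof)
  expect_true(est$valid)

  lab <- sim$truth$labels$label
  n <- length(lab)
  interior_f <- which(lab == "f" & c("x", lab[-n]) == "f" &
                        c(lab[-1], "x") == "f")
  intra <- prof$speed[interior_f]
  p95 <- stats::quantile(intra[is.finite(intra)], 0.95)
  sac_runs <- rle(lab == "s")
  ends <- cumsum(sac_runs$lengths)
  starts <- ends - sac_runs$lengths + 1
  peaks <- mapply(function(a, b) max(prof$speed[a:b], na.rm = TRUE),
                  starts[sac_runs$values], ends[sac_runs$values])
  expect_gt(est$threshold, p95)
  expect_lt(est$threshold, min(peaks))
})

test_that("threshold estimation degrades gracefully and reacts to noise", {
  # all-missing trial: invalid, threshold undefined
  rec <- make_recording(x = rep(NA_real_, 50), y = rep(NA_real_, 50))
  est <- estimate_threshold(speed_profile(cyclopean_merge(rec),
                                          test_geometry()))
  expect_false(est$valid)
  expect_true(is.na(est$threshold))

  # doubling the noise raises the estimate in nearly all paired seeds
  wins <- 0
  for (seed in 1:10) {
    t1 <- attr(parse_recording(simulate_gaze(
      simulation_spec(n_trials = 1, noise_sd_deg = 0.15, seed = seed)
    )$recording, parser_config("gazepath")), "diagnostics")$threshold
    t2 <- attr(parse_recording(simulate_gaze(
      simulation_spec(n_trials = 1, noise_sd_deg = 0.30, seed = seed)
    )$recording, parser_config("gazepath")), "diagnostics")$threshold
    wins <- wins + (t2 > t1)
  }
  expect_gte(wins, 9)
})

test_that("threshold is stable under duplication, reordering, leave-one-out", {
  est_from <- function(m) {
    gc <- gap_curve(m)
    sm <- smooth_until_unimodal(gc)
    gc$speed[which.max(sm$fitted)]
  }
  set.seed(7)
  m <- c(abs(rnorm(250, 40, 12)), runif(30, 150, 600))
  t0 <- est_from(m)
  expect_equal(est_from(sample(m)), t0)     # order-free
  expect_equal(est_from(c(m, m)), t0)       # duplication-free
  for (k in sample(seq_along(m), 8))        # leave-one-out stability < 5%
    expect_lt(abs(est_from(m[-k]) - t0) / t0, 0.05)
})

test_that("duration threshold separates a short/long mixture or falls back", {
  set.seed(3)
  mix <- c(runif(500, 30, 60), runif(500, 200, 400))
  res <- duration_threshold_data_driven(mix)
  expect_true(res$data_driven)
  expect_gt(res$threshold_ms, 60)
  expect_lt(res$threshold_ms, 200)

  expect_warning(r5 <- duration_threshold_data_driven(c(80, 90, 100, 110, 120)),
                 "falling back")
  expect_equal(r5$threshold_ms, 100)
  expect_false(r5$data_driven)

  expect_warning(rid <- duration_threshold_data_driven(rep(150, 50)),
                 "falling back")
  expect_equal(rid$threshold_ms, 100)
})
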