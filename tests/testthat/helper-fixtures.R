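# Shared fixtures: tiny recordings and independent brute-force oracles.

test_geometry <- function() {
  geometry(c(1280, 1024), stimulus_mm = c(320, 256), default_distance_mm = 600)
}

# recording from explicit cyclopean coordinates (left eye only)
make_recording <- function(x, y, rate = 500, trial = 1, distance = 600,
                           geom = test_geometry(), participant = "t") {
  n <- length(x)
  period <- 1000 / rate
  samples <- data.frame(
    trial = rep(trial, length.out = n),
    time = 0,
    x_left = x, y_left = y, x_right = NA_real_, y_right = NA_real_,
    distance_left = rep(distance, length.out = n),
    distance_right = NA_real_)
  samples$time <- (ave(seq_len(n), samples$trial, FUN = seq_along) - 1) * period
  gaze_recording(samples, participant, rate, geom)
}

# hand-built speed profile for threshold unit tests
make_profile <- function(speeds, valid = NULL, missing = NULL, trial = 1) {
  n <- length(speeds)
  data.frame(trial = rep(trial, length.out = n),
             time = seq_len(n),
             x = 0, y = 0, distance = 600,
             missing = if (is.null(missing)) rep(FALSE, n) else missing,
             interpolated = FALSE,
             speed = speeds,
             valid = if (is.null(valid)) rep(TRUE, n) else valid)
}

# --- independent oracles -------------------------------------------------

# brute-force gap statistic straight from its definition
oracle_gap <- function(maxima, grid_size = 512) {
  lo <- min(maxima); hi <- max(maxima)
  v <- seq(lo, hi, length.out = grid_size)
  n <- length(maxima)
  sapply(v, function(vi) {
    s_null <- n * (hi - vi) / (hi - lo)
    s_obs <- sum(maxima > vi)
    (s_null - s_obs) / n
  })
}

# interior-mode count by sign changes of successive differences
oracle_mode_count <- function(y) {
  d <- diff(y)
  d <- d[d != 0]
  if (length(d) < 2) return(0L)
  sum(d[-length(d)] > 0 & d[-1] < 0)
}

# exact convex-polygon intersection: vertex containment or edge crossing
oracle_polys_intersect <- function(a, b) {
  inside <- function(p, poly) {
    n <- nrow(poly)
    s <- sapply(seq_len(n), function(k) {
      q <- poly[k, ]; r <- poly[if (k == n) 1 else k + 1, ]
      (r[1] - q[1]) * (p[2] - q[2]) - (r[2] - q[2]) * (p[1] - q[1])
    })
    all(s >= -1e-9) || all(s <= 1e-9)
  }
  seg_cross <- function(p1, p2, p3, p4) {
    o <- function(a, b, c)
      sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    o(p1, p2, p3) != o(p1, p2, p4) && o(p3, p4, p1) != o(p3, p4, p2)
  }
  if (any(apply(a, 1, inside, poly = b))) return(TRUE)
  if (any(apply(b, 1, inside, poly = a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) for (j in seq_len(nb))
    if (seg_cross(a[i, ], a[if (i == na) 1 else i + 1, ],
                  b[j, ], b[if (j == nb) 1 else j + 1, ])) return(TRUE)
  FALSE
}

# containment-based split/unmatched flags, written independently
oracle_compare <- function(a, b, tol) {
  fa <- a[a$Value == "f", ]
  fb <- b[b$Value == "f", ]
  out <- data.frame(contained = integer(nrow(fa)), split = logical(nrow(fa)),
                    unmatched = logical(nrow(fa)))
  for (k in seq_len(nrow(fa))) {
    cnt <- 0; ovl <- 0
    for (j in seq_len(nrow(fb))) {
      if (fb$Trial[j] != fa$Trial[k]) next
      if (fb$Start[j] >= fa$Start[k] - tol && fb$End[j] <= fa$End[k] + tol)
        cnt <- cnt + 1
      if (fb$Start[j] < fa$End[k] && fb$End[j] > fa$Start[k]) ovl <- ovl + 1
    }
    out$contained[k] <- cnt
    out$split[k] <- cnt >= 2
    out$unmatched[k] <- ovl == 0
  }
  out
}

# random tiny event table for comparison tests
random_event_table <- function(n_fix, trial = 1, tmax = 5000) {
  bounds <- sort(runif(2 * n_fix, 0, tmax))
  st <- bounds[seq(1, 2 * n_fix, by = 2)]
  en <- bounds[seq(2, 2 * n_fix, by = 2)]
  data.frame(Participant = "r", Value = "f", Duration = en - st,
             Start = st, End = en, mean_x = 0, mean_y = 0,
             sdPOGsacAMP = 0, RMS = 0, Order = seq_len(n_fix), Trial = trial)
}
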