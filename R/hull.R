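# Convex-polygon helpers for the spatial-overlap merge step.
# No geometry package is used: the separating-axis test below is a dozen
# lines and exact for convex polygons.

# Convex hull of a fixation's samples as an (n x 2) vertex matrix in CCW
# order. Fewer than 3 distinct points (or a collinear set) gives a degenerate
# hull; those are replaced by a 16-gon disc of radius `disc_radius` around the
# centroid, so every fixation has a genuine polygon.
fixation_polygon <- function(x, y, disc_radius) {
  pts <- unique(cbind(x, y))
  h <- if (nrow(pts) >= 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
  degenerate <- nrow(h) < 3 || polygon_area(h) == 0
  if (degenerate) {
    cx <- mean(x); cy <- mean(y)
    r <- max(disc_radius, 1e-9)
    a <- seq(0, 2 * pi, length.out = 17)[-17]
    h <- cbind(cx + r * cos(a), cy + r * sin(a))
  }
  h
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Separating-axis test: convex polygons intersect iff no edge normal of
# either polygon separates their vertex projections. Touching counts as
# intersecting.
convex_polygons_intersect <- function(a, b) {
  axes <- function(p) {
    n <- nrow(p)
    e <- p[c(2:n, 1), , drop = FALSE] - p
    cbind(-e[, 2], e[, 1])
  }
  for (ax in list(axes(a), axes(b))) {
    for (k in seq_len(nrow(ax))) {
      axk <- ax[k, ]
      if (all(axk == 0)) next
      pa <- a %*% axk
      pb <- b %*% axk
      if (max(pa) < min(pb) || max(pb) < min(pa)) return(FALSE)
    }
  }
  TRUE
}
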