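# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: areas come from dense polygonal discretization or
# rejection sampling, never from the package's exact integrals.

# Flatten a rounded outline into a dense polygon (chords per arc) and take
# its shoelace area.
discretized_outline_area <- function(outline, chords_per_arc = 2000L) {
  pts <- list()
  for (e in outline$elements) {
    if (e$type == "segment") {
      pts[[length(pts) + 1L]] <- matrix(e$from, ncol = 2)
    } else {
      th <- e$theta_start + e$sweep * seq(0, 1, length.out = chords_per_arc + 1L)
      th <- th[-length(th)] # endpoint belongs to the next element
      pts[[length(pts) + 1L]] <- cbind(e$center[1] + e$radius * cos(th),
                                       e$center[2] + e$radius * sin(th))
    }
  }
  v <- do.call(rbind, pts)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# Rejection-sampling (point-in-polygon) area estimate with its standard error.
mc_polygon_area <- function(poly, n_points = 1e6, seed = 99L) {
  v <- unclass(poly)
  set.seed(seed)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  px <- runif(n_points, xr[1], xr[2])
  py <- runif(n_points, yr[1], yr[2])
  n <- nrow(v)
  inside <- logical(n_points)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  p_hat <- mean(inside)
  box <- diff(xr) * diff(yr)
  list(area = box * p_hat,
       se = box * sqrt(p_hat * (1 - p_hat) / n_points))
}

# Closed-form area of a regular n-gon (circumradius r) with all corners
# rounded at radius rr: per-vertex cut rr^2 * (cot(alpha/2) - (pi - alpha)/2)
# with interior angle alpha = (n - 2) * pi / n.
regular_rounded_area <- function(n, r = 1, rr = 0) {
  alpha <- (n - 2) * pi / n
  (n / 2) * sin(2 * pi / n) * r^2 -
    n * rr^2 * (1 / tan(alpha / 2) - (pi - alpha) / 2)
}

# Direct Boltzmann-inversion estimate of a free-energy profile from
# unbiased samples (oracle for single-window WHAM).
boltzmann_invert <- function(samples, temperature, n_bins = 80L) {
  h <- hist(samples, breaks = n_bins, plot = FALSE)
  keep <- h$counts > 0
  F_z <- -kBT(temperature) * log(h$density[keep])
  list(z = h$mids[keep], free_energy = F_z - min(F_z))
}

# RMSE between a recovered profile and a truth function after removing the
# arbitrary additive offset (a PMF is defined up to a constant).  An optional
# z_range restricts the comparison to a sub-interval (e.g. the well-sampled
# core, away from sparse tail bins).
pmf_rmse <- function(profile, truth_fn, z_range = NULL) {
  keep <- is.finite(profile$free_energy)
  if (!is.null(z_range)) {
    keep <- keep & profile$z >= z_range[1] & profile$z <= z_range[2]
  }
  delta <- profile$free_energy[keep] - truth_fn(profile$z[keep])
  sqrt(mean((delta - mean(delta))^2))
}

# A fixed non-convex (one reflex vertex) CCW test polygon.
reflex_polygon <- function() {
  irregular_polygon(cbind(c(0, 4, 4, 2, 0), c(0, 0, 4, 1.2, 4)))
}
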