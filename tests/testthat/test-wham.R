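test_that("a single nearly unbiased window reduces to Boltzmann inversion", {
  pmf <- true_pmf_spec("harmonic", curvature = 8, z_min = 0,
                       z_range = c(-1.5, 1.5))
  w <- sample_umbrella_windows(pmf, centers = 0, force_constant = 1e-4,
                               n_per_window = 40000, seed = 31)
  prof <- wham_solve(w, n_bins = 60)
  # oracle: direct histogram inversion of the same (unbiased) samples;
  # compare over the well-sampled core (within ~2 sd of the minimum)
  core <- c(-0.55, 0.55)
  inv <- boltzmann_invert(w$samples[[1]], w$temperature, n_bins = 60)
  expect_lt(pmf_rmse(prof, pmf$fn, core), 0.1)
  expect_lt(pmf_rmse(pmf_profile(inv$z, inv$free_energy), pmf$fn, core), 0.1)
})

test_that("WHAM recovers a known harmonic profile from overlapping windows", {
  pmf <- true_pmf_spec("harmonic", curvature = 15, z_min = 0,
                       z_range = c(-1.3, 1.3))
  centers <- seq(-0.9, 0.9, by = 0.2)
  w <- sample_umbrella_windows(pmf, centers, force_constant = 100,
                               n_per_window = 5000, seed = 17)
  prof <- wham_solve(w, n_bins = 150)
  expect_true(attr(prof, "converged"))
  expect_gt(attr(prof, "iterations"), 1L)
  # core spanned by the bias centers; sparse tail bins beyond the outermost
  # windows are excluded
  expect_lt(pmf_rmse(prof, pmf$fn, c(-0.9, 0.9)), 0.12)
  expect_equal(min(prof$free_energy, na.rm = TRUE), 0) # min-referenced
})

test_that("duplicating a window equals pooling its samples (weight additivity)", {
  pmf <- true_pmf_spec("harmonic", curvature = 10, z_min = 0,
                       z_range = c(-1, 1))
  s <- sample_umbrella_windows(pmf, centers = 0.1, force_constant = 50,
                               n_per_window = 4000, seed = 5)$samples[[1]]
  t_K <- 298.15
  # shared explicit histogram grid so both variants bin identically; the
  # 1e-9 center offset (centers must be strictly ordered) is immaterial
  breaks <- seq(-0.6, 0.8, length.out = 101)
  counts <- tabulate(findInterval(s, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = 100)
  dup <- umbrella_windows(c(0.1, 0.1 + 1e-9), 50, t_K,
                          histograms = list(breaks = breaks,
                                            counts = rbind(counts, counts)))
  pooled <- umbrella_windows(0.1, 50, t_K,
                             histograms = list(breaks = breaks,
                                               counts = rbind(2 * counts)))
  p1 <- wham_solve(dup, n_bins = 100)
  p2 <- wham_solve(pooled, n_bins = 100)
  expect_equal(p1$free_energy, p2$free_energy, tolerance = 1e-6)
})

test_that("shifting all centers and samples shifts the grid but not the PMF shape", {
  pmf <- true_pmf_spec("harmonic", curvature = 12, z_min = 0,
                       z_range = c(-1, 1))
  centers <- seq(-0.6, 0.6, by = 0.2)
  w <- sample_umbrella_windows(pmf, centers, force_constant = 80,
                               n_per_window = 3000, seed = 8)
  delta <- 2.5
  w_shift <- umbrella_windows(w$centers + delta, w$force_constant,
                              w$temperature,
                              samples = lapply(w$samples, function(s) s + delta))
  p0 <- wham_solve(w, n_bins = 120)
  p1 <- wham_solve(w_shift, n_bins = 120)
  expect_equal(p1$z, p0$z + delta, tolerance = 1e-12)
  expect_equal(p1$free_energy, p0$free_energy, tolerance = 1e-8)
})

test_that("temperature rescaling with regenerated samples recovers the same truth", {
  pmf <- true_pmf_spec("harmonic", curvature = 15, z_min = 0,
                       z_range = c(-1.3, 1.3))
  centers <- seq(-0.8, 0.8, by = 0.2)
  for (t_K in c(298.15, 596.3)) {
    w <- sample_umbrella_windows(pmf, centers, force_constant = 100,
                                 temperature = t_K, n_per_window = 5000,
                                 seed = 21)
    expect_lt(pmf_rmse(wham_solve(w, n_bins = 150), pmf$fn, c(-0.8, 0.8)), 0.2)
  }
})

test_that("non-overlapping windows fail loudly, naming the gap", {
  pmf <- true_pmf_spec("harmonic", curvature = 5, z_min = 0,
                       z_range = c(-6, 6))
  w <- sample_umbrella_windows(pmf, centers = c(-4, 4), force_constant = 400,
                               n_per_window = 500, seed = 3)
  expect_error(wham_solve(w), "do not overlap")
})

test_that("exceeding the iteration cap is an error, not a silent result", {
  pmf <- true_pmf_spec("harmonic", curvature = 15, z_min = 0,
                       z_range = c(-1.3, 1.3))
  w <- sample_umbrella_windows(pmf, seq(-0.9, 0.9, by = 0.3),
                               force_constant = 100, n_per_window = 1000,
                               seed = 12)
  expect_error(wham_solve(w, max_iter = 2), "did not converge")
})

test_that("pre-binned histogram input matches sample input on the same grid", {
  pmf <- true_pmf_spec("harmonic", curvature = 12, z_min = 0,
                       z_range = c(-1.2, 1.2))
  centers <- seq(-0.6, 0.6, by = 0.3)
  w <- sample_umbrella_windows(pmf, centers, force_constant = 60,
                               n_per_window = 3000, seed = 44)
  p_samples <- wham_solve(w, n_bins = 100)
  # rebuild the same histograms externally (rule span clipped to the data)
  sigma <- sqrt(kBT(w$temperature) / w$force_constant)
  rng <- range(unlist(w$samples))
  breaks <- seq(max(min(centers) - 3 * sigma, rng[1]),
                min(max(centers) + 3 * sigma, rng[2]),
                length.out = 101)
  counts <- t(vapply(w$samples, function(s) {
    s <- s[s >= breaks[1] & s <= breaks[length(breaks)]]
    tabulate(findInterval(s, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = 100)
  }, numeric(100)))
  w_hist <- umbrella_windows(centers, 60, w$temperature,
                             histograms = list(breaks = breaks, counts = counts))
  p_hist <- wham_solve(w_hist, n_bins = 100)
  expect_equal(p_hist$free_energy, p_samples$free_energy, tolerance = 1e-10)
})
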