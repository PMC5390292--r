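make_calib <- function(slope, blank = 0, noise = 0, seed = 1) {
  conc <- c(0, 5, 10, 15, 20)
  set.seed(seed)
  data.frame(concentration = conc,
             intensity = blank + slope * conc + rnorm(5, 0, noise))
}

test_that("calibration slope is the OLS slope, with the 0-point as blank", {
  # exact linear data: silence lm's perfect-fit note
  fit <- function(...) suppressWarnings(calibration_slope(...))
  expect_equal(fit(make_calib(2))$slope, 2, tolerance = 1e-12)
  expect_equal(fit(make_calib(0, blank = 7))$slope, 0, tolerance = 1e-12)
  expect_equal(fit(make_calib(3, blank = 40))$blank, 40)
  expect_error(calibration_slope(
    data.frame(concentration = c(5, 5), intensity = c(1, 2))), "distinct")
})

test_that("noisy calibration slopes fall within 3 analytic standard errors", {
  s_true <- 1.8
  sigma <- 0.5
  conc <- rep(c(0, 5, 10, 15, 20), each = 3)
  se_analytic <- sigma / sqrt(sum((conc - mean(conc))^2))
  hits <- vapply(1:50, function(i) {
    set.seed(400 + i)
    d <- data.frame(concentration = conc,
                    intensity = 10 + s_true * conc + rnorm(length(conc), 0, sigma))
    abs(calibration_slope(d)$slope - s_true) <= 3 * se_analytic
  }, logical(1))
  expect_gte(mean(hits), 0.9) # ~99.7% nominal; allow sampling slack
})

test_that("normalization divides by the type slope and is idempotent and invertible", {
  sim <- simulate_assay(assay_design(), seed = 10)
  raw <- sim$assay
  slopes <- c(prickly = 4, round = 2)
  norm <- normalize_assay(raw, slopes)
  expect_equal(norm$intensity[norm$nd_type == "prickly"],
               raw$intensity[raw$nd_type == "prickly"] / 4)
  expect_equal(norm$intensity[norm$nd_type == "round"],
               raw$intensity[raw$nd_type == "round"] / 2)
  # round-trip back to raw
  back <- norm$intensity * ifelse(norm$nd_type == "prickly", 4, 2)
  expect_equal(back, raw$intensity, tolerance = 1e-12)
  # applying again is a no-op
  expect_warning(norm2 <- normalize_assay(norm, slopes), "already normalized")
  expect_identical(norm2$intensity, norm$intensity)
  expect_error(normalize_assay(raw, c(prickly = 4)), "round")
  expect_error(normalize_assay(raw, c(prickly = -1, round = 2)), "positive")
})

test_that("equal slopes preserve the cross-type rank order", {
  sim <- simulate_assay(assay_design(), seed = 2)
  norm <- normalize_assay(sim$assay, c(prickly = 3, round = 3))
  expect_equal(order(norm$intensity), order(sim$assay$intensity))
})

test_that("the temperature-split subtraction identity holds exactly", {
  sim <- simulate_assay(assay_design(), seed = 20)
  res <- quantify_uptake(sim$assay)
  s <- res$summary
  expect_equal(s$anchored_mean + s$internalized_mean, s$total_mean,
               tolerance = 1e-12)
  expect_true(all(s$internalized_sd >= 0))
  expect_true(all(res$comparisons$p_anchored >= 0 &
                    res$comparisons$p_anchored <= 1))
})

test_that("quantification recovers hand-built means and flags negatives", {
  mk <- function(ty, cond, t, vals) {
    data.frame(nd_type = ty, condition = cond, time_hr = t,
               replicate = seq_along(vals), intensity = vals)
  }
  assay <- rbind(mk("a", "4C", 1, c(4, 4, 4)), mk("a", "37C", 1, c(10, 10, 10)),
                 mk("b", "4C", 1, c(5, 6, 7)), mk("b", "37C", 1, c(5, 6, 7)))
  res <- quantify_uptake(assay)
  s <- res$summary
  expect_equal(s$internalized_mean[s$nd_type == "a"], 6)
  expect_equal(s$internalized_mean[s$nd_type == "b"], 0)
  # negative estimate is reported, not clipped, and flagged
  assay2 <- rbind(mk("a", "4C", 1, c(10, 11, 12)), mk("a", "37C", 1, c(4, 5, 5)),
                  mk("b", "4C", 1, c(1, 2, 3)), mk("b", "37C", 1, c(4, 5, 6)))
  expect_warning(res2 <- quantify_uptake(assay2), "negative internalized")
  s2 <- res2$summary
  expect_lt(s2$internalized_mean[s2$nd_type == "a"], 0)
  expect_true(s2$qc_negative_internalized[s2$nd_type == "a"])
  # missing condition errors
  expect_error(quantify_uptake(rbind(mk("a", "4C", 1, c(1, 2, 3)))),
               "missing the 37C")
})

test_that("all quantities are invariant to a common intensity rescaling", {
  sim <- simulate_assay(assay_design(), seed = 30)
  calib <- rbind(
    cbind(nd_type = "prickly", make_calib(4, blank = 10, noise = 0.3, seed = 41)),
    cbind(nd_type = "round", make_calib(2, blank = 5, noise = 0.3, seed = 42))
  )
  run <- function(scale) {
    a <- sim$assay
    a$intensity <- a$intensity * scale
    cal <- calib
    cal$intensity <- cal$intensity * scale
    quantify_uptake(normalize_assay(a, calibration_slopes(cal)))
  }
  r1 <- run(1)
  r2 <- run(137.5)
  expect_equal(r2$summary$internalized_mean, r1$summary$internalized_mean,
               tolerance = 1e-10)
  expect_equal(r2$comparisons$internalized_ratio, r1$comparisons$internalized_ratio,
               tolerance = 1e-10)
  expect_equal(r2$comparisons$p_total, r1$comparisons$p_total, tolerance = 1e-10)
})

test_that("t-test p-values match stats::t.test on raw data and a permutation oracle", {
  set.seed(55)
  a <- rnorm(6, 1, 1)
  b <- rnorm(7, 0.2, 1.6)
  expect_equal(two_sample_p(a, b, "pooled"),
               t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(two_sample_p(a, b, "welch"),
               t.test(a, b)$p.value, tolerance = 1e-12)
  # summary input reproduces the raw-data result
  expect_equal(two_sample_p(list(mean = mean(a), sd = sd(a), n = length(a)),
                            list(mean = mean(b), sd = sd(b), n = length(b)),
                            "pooled"),
               two_sample_p(a, b, "pooled"), tolerance = 1e-12)
  # identical groups
  expect_equal(two_sample_p(c(1, 2, 3), c(1, 2, 3)), 1)
  # permutation oracle on small groups (mean difference statistic)
  set.seed(77)
  x <- rnorm(3, 0, 1)
  y <- rnorm(3, 1, 1)
  p_t <- two_sample_p(x, y, "pooled")
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  n_perm <- 20000
  set.seed(5)
  exceed <- replicate(n_perm, {
    idx <- sample(6, 3)
    abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
  })
  p_perm <- mean(exceed)
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  # n = 3 + 3 permutation p is discrete; agree within a generous MC band
  expect_lt(abs(p_perm - p_t), max(0.15, 5 * mc_se))
})

test_that("degenerate variance cases are handled explicitly", {
  expect_equal(two_sample_p(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_warning(p <- two_sample_p(c(2, 2, 2), c(3, 3, 3)), "undefined")
  expect_true(is.na(p))
})

test_that("the reported zeta-potential summaries give the printed p-value", {
  p <- two_sample_p(list(mean = -41.9033, sd = 1.6671, n = 3),
                    list(mean = -41.5567, sd = 6.93695, n = 3),
                    variant = "pooled")
  expect_equal(p, 0.937, tolerance = 0.002)
})
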