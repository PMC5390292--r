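#' Free-energy depth of a PMF profile
#'
#' Depth is the bulk plateau level minus the profile minimum, where the bulk
#' level is the mean free energy over the populated bins in the top
#' `bulk_fraction` of the reaction-coordinate range (a plateau average is
#' robust to per-bin noise).  Invariant to the profile's additive reference.
#'
#' @param profile A [pmf_profile()] covering both the minimum and a
#'   large-distance plateau.
#' @param bulk_fraction Fraction of the z-range, counted from the top,
#'   averaged as "bulk" (default 0.1).
#' @return Depth in kcal/mol (non-negative).
#' @export
pmf_depth <- function(profile, bulk_fraction = 0.1) {
  stopifnot(inherits(profile, "pmf_profile"),
            bulk_fraction > 0, bulk_fraction <= 1)
  fin <- is.finite(profile$free_energy)
  if (!any(fin)) stop("profile has no populated bins")
  z <- profile$z[fin]
  f <- profile$free_energy[fin]
  z_lo <- max(z) - bulk_fraction * (max(z) - min(z))
  bulk <- z >= z_lo
  if (!any(bulk)) stop("bulk region (top of the z range) has no populated bins")
  mean(f[bulk]) - min(f)
}

#' Bootstrap uncertainty of the PMF depth
#'
#' Resamples each umbrella window's samples with replacement, re-runs WHAM
#' and recomputes the depth.  The spread of the resampled depths is a
#' declared uncertainty estimate for the depth, not a claim about any
#' particular published error bar.
#'
#' @inheritParams wham_solve
#' @inheritParams pmf_depth
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return List with elements `depth` (point estimate), `se` (bootstrap
#'   standard deviation) and `boot` (the replicate depths).
#' @export
pmf_depth_boot <- function(windows, n_bins = 200L, bulk_fraction = 0.1,
                           n_boot = 200L, seed = 1L,
                           tol = 1e-6, max_iter = 100000L) {
  stopifnot(inherits(windows, "umbrella_windows"), !is.null(windows$samples),
            n_boot >= 2)
  point <- pmf_depth(wham_solve(windows, n_bins, tol, max_iter), bulk_fraction)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(substream_seed(seed, b))
    res <- lapply(windows$samples, function(s) sample(s, length(s), replace = TRUE))
    wb <- umbrella_windows(windows$centers, windows$force_constant,
                           windows$temperature, samples = res)
    boot[b] <- pmf_depth(wham_solve(wb, n_bins, tol, max_iter), bulk_fraction)
  }
  list(depth = point, se = stats::sd(boot), boot = boot)
}

#' Rectangular slab contact-area specification
#'
#' @param length_x,length_y Slab edge lengths (nm).
#' @return A `slab_spec` with `area = length_x * length_y` (nm^2).
#' @examples
#' slab_spec(2, 2)$area # 4
#' @export
slab_spec <- function(length_x, length_y) {
  stopifnot(length_x > 0, length_y > 0)
  structure(list(length_x = length_x, length_y = length_y,
                 area = length_x * length_y),
            class = "slab_spec")
}

#' Unit adhesion strength from a free-energy depth
#'
#' The unit adhesion strength is the adhesion free energy per unit contact
#' area: `k_ad = depth / slab area`.
#'
#' @param depth Free-energy depth (kcal/mol), `>= 0`.
#' @param slab A [slab_spec()].
#' @return An `adhesion_estimate` with fields `depth`, `k_ad`
#'   (kcal/mol/nm^2) and `slab`.
#' @examples
#' k_ad_from_depth(9.93, slab_spec(2, 2))$k_ad   # 2.4825
#' k_ad_from_depth(37.39, slab_spec(4, 4))$k_ad  # 2.336875
#' @export
k_ad_from_depth <- function(depth, slab) {
  stopifnot(length(depth) == 1L, is.finite(depth), depth >= 0,
            inherits(slab, "slab_spec"))
  if (slab$area <= 0) stop("slab area must be positive")
  structure(list(depth = depth, k_ad = depth / slab$area, slab = slab),
            class = "adhesion_estimate")
}

#' @export
print.adhesion_estimate <- function(x, ...) {
  cat(sprintf(
    "Adhesion estimate: depth %.4g kcal/mol over a %g x %g nm slab -> k_ad = %.4g kcal/mol/nm^2\n",
    x$depth, x$slab$length_x, x$slab$length_y, x$k_ad
  ))
  invisible(x)
}

#' Average unit adhesion strength across systems
#'
#' @param estimates Numeric vector of `k_ad` values, or a list of
#'   `adhesion_estimate` objects.
#' @return Arithmetic mean (kcal/mol/nm^2).
#' @examples
#' average_k_ad(c(2.48, 2.33, 2.22)) # 2.343333...
#' @export
average_k_ad <- function(estimates) {
  if (is.list(estimates)) {
    estimates <- vapply(estimates, function(e) {
      stopifnot(inherits(e, "adhesion_estimate"))
      e$k_ad
    }, numeric(1))
  }
  stopifnot(is.numeric(estimates), all(is.finite(estimates)))
  if (length(estimates) == 0L) stop("at least one adhesion estimate is required")
  mean(estimates)
}
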