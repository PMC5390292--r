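#' Umbrella-sampling window set
#'
#' Container for a ladder of harmonically biased sampling windows along a
#' one-dimensional reaction coordinate (here the slab-bilayer distance, nm).
#' Each window `w` was sampled under the bias
#' `U_w(z) = 1/2 * k * (z - z0_w)^2`.
#'
#' @param centers Strictly increasing bias centers `z0` (nm).
#' @param force_constant Harmonic bias stiffness `k` (kcal/mol/nm^2).
#' @param temperature Kelvin.
#' @param samples List (one element per window) of sampled reaction
#'   coordinate values (nm), or `NULL` if `histograms` is given.
#' @param histograms Optional pre-binned input: `list(breaks = <shared bin
#'   edges>, counts = <windows x bins matrix>)`.
#' @return An object of class `umbrella_windows`.
#' @export
umbrella_windows <- function(centers, force_constant, temperature = 298.15,
                             samples = NULL, histograms = NULL) {
  stopifnot(
    is.numeric(centers), length(centers) >= 1L, all(is.finite(centers)),
    !is.unsorted(centers, strictly = TRUE),
    length(force_constant) == 1L, force_constant > 0,
    length(temperature) == 1L, temperature > 0
  )
  if (is.null(samples) && is.null(histograms)) {
    stop("one of `samples` or `histograms` must be supplied")
  }
  if (!is.null(samples)) {
    stopifnot(is.list(samples), length(samples) == length(centers))
    ok <- vapply(samples, function(s) is.numeric(s) && length(s) >= 1L &&
                   all(is.finite(s)), logical(1))
    if (!all(ok)) stop("every window needs at least one finite sample")
  }
  if (!is.null(histograms)) {
    stopifnot(
      is.list(histograms), !is.null(histograms$breaks), !is.null(histograms$counts),
      nrow(histograms$counts) == length(centers),
      ncol(histograms$counts) == length(histograms$breaks) - 1L,
      all(histograms$counts >= 0), all(rowSums(histograms$counts) > 0)
    )
  }
  structure(
    list(centers = centers, force_constant = force_constant,
         temperature = temperature, samples = samples, histograms = histograms),
    class = "umbrella_windows"
  )
}

#' @export
print.umbrella_windows <- function(x, ...) {
  n <- if (!is.null(x$samples)) {
    sum(lengths(x$samples))
  } else {
    sum(x$histograms$counts)
  }
  cat(sprintf(
    "Umbrella windows: %d windows on [%.3g, %.3g] nm, k = %g kcal/mol/nm^2, T = %g K, %d samples\n",
    length(x$centers), min(x$centers), max(x$centers),
    x$force_constant, x$temperature, n
  ))
  invisible(x)
}

#' One-dimensional free-energy profile
#'
#' @param z Strictly ascending reaction-coordinate grid (nm), typically
#'   histogram bin centers.
#' @param free_energy Free energy (kcal/mol); `NA` on unpopulated bins.
#' @param error Optional per-bin uncertainty (kcal/mol).
#' @param reference Zero-point convention label (default `"min"`: the
#'   minimum over populated bins is 0).
#' @return An object of class `pmf_profile`.
#' @export
pmf_profile <- function(z, free_energy, error = NULL, reference = "min") {
  stopifnot(is.numeric(z), !is.unsorted(z, strictly = TRUE),
            length(free_energy) == length(z))
  if (!is.null(error)) stopifnot(length(error) == length(z))
  structure(
    list(z = z, free_energy = free_energy, error = error,
         reference = reference),
    class = "pmf_profile"
  )
}

#' @export
print.pmf_profile <- function(x, ...) {
  fin <- is.finite(x$free_energy)
  cat(sprintf(
    "PMF profile: %d bins on [%.3g, %.3g] nm (%d populated), depth-to-min range %.3g kcal/mol, reference '%s'\n",
    length(x$z), min(x$z), max(x$z), sum(fin),
    diff(range(x$free_energy[fin])), x$reference
  ))
  if (!is.null(attr(x, "converged"))) {
    cat(sprintf("  WHAM: converged = %s after %d iterations\n",
                attr(x, "converged"), attr(x, "iterations")))
  }
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  d <- data.frame(z = x$z, free_energy = x$free_energy)
  if (!is.null(x$error)) d$error <- x$error
  d
}

# Histogram window samples onto a common grid; returns counts matrix and
# bin centers.  The declared span [min center - 3*sigma, max center + 3*sigma]
# is clipped to the observed sample range so a weak bias (sigma comparable to
# or larger than the sampled support) cannot blow the grid up.
wham_grid <- function(windows, n_bins) {
  sigma <- sqrt(kBT(windows$temperature) / windows$force_constant)
  all_range <- range(unlist(windows$samples))
  lo <- max(min(windows$centers) - 3 * sigma, all_range[1])
  hi <- min(max(windows$centers) + 3 * sigma, all_range[2])
  if (lo >= hi) {
    lo <- all_range[1]
    hi <- all_range[2]
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- matrix(0, nrow = length(windows$centers), ncol = n_bins)
  dropped <- 0L
  for (w in seq_along(windows$samples)) {
    s <- windows$samples[[w]]
    inside <- s >= lo & s <= hi
    dropped <- dropped + sum(!inside)
    counts[w, ] <- tabulate(findInterval(s[inside], breaks,
                                         rightmost.closed = TRUE,
                                         all.inside = TRUE),
                            nbins = n_bins)
  }
  list(mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
       breaks = breaks, counts = counts, dropped = dropped)
}

#' Weighted histogram analysis (WHAM) of umbrella windows
#'
#' Self-consistently combines the biased window histograms into one unbiased
#' free-energy profile.  With bias `U_w(z)`, window free energies `f_w` and
#' per-bin unbiased probabilities `p_b`, the iteration is
#' \deqn{p_b \propto \frac{\sum_w n_{wb}}{\sum_w N_w e^{-\beta (U_w(z_b) - f_w)}},
#'       \quad f_w = -k_BT \ln \sum_b p_b e^{-\beta U_w(z_b)}}
#' repeated until the largest change in any `f_w` falls below `tol`.  The
#' returned profile is `F(z_b) = -k_BT ln p_b`, min-referenced.
#'
#' @param windows An [umbrella_windows()] object.  Sample input is binned on
#'   a uniform grid spanning `[min(centers) - 3*sigma, max(centers) +
#'   3*sigma]` with `sigma = sqrt(k_BT/k)`; pre-binned input is used as is.
#' @param n_bins Number of histogram bins (sample input only).
#' @param tol Convergence tolerance on the window free energies (kcal/mol).
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A [pmf_profile()] with attributes `converged`, `iterations`,
#'   `window_free_energies` and `counts`.
#' @examples
#' pmf <- true_pmf_spec("harmonic", curvature = 15, z_min = 0, z_range = c(-1.2, 1.2))
#' w <- sample_umbrella_windows(pmf, seq(-0.9, 0.9, by = 0.3),
#'                              force_constant = 100, n_per_window = 2000, seed = 1)
#' prof <- wham_solve(w, n_bins = 120)
#' @export
wham_solve <- function(windows, n_bins = 200L, tol = 1e-6, max_iter = 100000L) {
  stopifnot(inherits(windows, "umbrella_windows"),
            n_bins >= length(windows$centers), tol > 0, max_iter >= 1)
  beta <- 1 / kBT(windows$temperature)
  k <- windows$force_constant
  if (!is.null(windows$histograms)) {
    br <- windows$histograms$breaks
    grid <- list(mids = (br[-1L] + br[-length(br)]) / 2,
                 counts = windows$histograms$counts, dropped = 0L)
  } else {
    grid <- wham_grid(windows, as.integer(n_bins))
  }
  counts <- grid$counts
  mids <- grid$mids
  W <- nrow(counts)
  # pairwise overlap check: adjacent windows must share a populated bin
  if (W > 1L) {
    for (w in seq_len(W - 1L)) {
      if (!any(counts[w, ] > 0 & counts[w + 1L, ] > 0)) {
        stop(sprintf(
          "umbrella windows %d (center %.4g) and %d (center %.4g) do not overlap: no shared populated bin",
          w, windows$centers[w], w + 1L, windows$centers[w + 1L]
        ))
      }
    }
  }
  N_w <- rowSums(counts)
  n_b <- colSums(counts)
  # bias energy matrix U[w, b]
  U <- 0.5 * k * outer(windows$centers, mids, function(c0, z) (z - c0)^2)
  expU <- exp(-beta * U)
  f <- numeric(W)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- colSums((N_w * exp(beta * f)) * expU)
    p <- n_b / denom
    p[n_b == 0] <- 0
    p <- p / sum(p)
    f_new <- -log(as.vector(expU %*% p)) / beta
    f_new <- f_new - f_new[1L]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("WHAM did not converge within %d iterations (last max |df| = %.3g kcal/mol)",
                 as.integer(max_iter), delta))
  }
  F_z <- ifelse(p > 0, -log(p) / beta, NA_real_)
  F_z <- F_z - min(F_z, na.rm = TRUE)
  prof <- pmf_profile(mids, F_z, reference = "min")
  attr(prof, "converged") <- converged
  attr(prof, "iterations") <- iter
  attr(prof, "window_free_energies") <- f
  attr(prof, "counts") <- counts
  attr(prof, "n_dropped") <- grid$dropped
  prof
}
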