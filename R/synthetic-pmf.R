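#' Specify a known ("true") free-energy profile
#'
#' Ground-truth profiles for validating the umbrella-sampling / WHAM
#' pipeline:
#' \describe{
#'   \item{`"well"`}{Morse-like attractive well with a large-distance
#'     plateau at 0: `F(z) = depth * ((1 - exp(-(z - z_min)/width))^2 - 1)`.
#'     Minimum `-depth` at `z_min`, steep repulsive wall at short distance.}
#'   \item{`"harmonic"`}{`F(z) = 1/2 * curvature * (z - z_min)^2`.}
#'   \item{`"tabulated"`}{Linear interpolation of a supplied `(z, F)` table
#'     (constant extrapolation outside).}
#' }
#'
#' @param form One of `"well"`, `"harmonic"`, `"tabulated"`.
#' @param depth Well depth (kcal/mol, `>= 0`; `"well"` form).
#' @param z_min Position of the minimum (nm).
#' @param width Decay length of the well (nm; `"well"` form).
#' @param curvature Stiffness (kcal/mol/nm^2; `"harmonic"` form).
#' @param z_range Reaction-coordinate support (nm) over which sampling
#'   densities are evaluated.
#' @param table Data frame with columns `z` and `free_energy`
#'   (`"tabulated"` form).
#' @return A `true_pmf` object whose `$fn` evaluates F(z) (kcal/mol).
#' @examples
#' pmf <- true_pmf_spec("well", depth = 9.93, z_min = 0.5, width = 0.3,
#'                      z_range = c(0.2, 2.6))
#' pmf$fn(0.5) # -9.93
#' @export
true_pmf_spec <- function(form = c("well", "harmonic", "tabulated"),
                          depth = 9.93, z_min = 0.5, width = 0.3,
                          curvature = NULL, z_range = c(0.2, 2.6),
                          table = NULL) {
  form <- match.arg(form)
  stopifnot(length(z_range) == 2L, z_range[1] < z_range[2])
  fn <- switch(form,
    well = {
      stopifnot(depth >= 0, width > 0)
      function(z) depth * ((1 - exp(-(z - z_min) / width))^2 - 1)
    },
    harmonic = {
      stopifnot(!is.null(curvature), curvature > 0)
      function(z) 0.5 * curvature * (z - z_min)^2
    },
    tabulated = {
      stopifnot(!is.null(table), all(c("z", "free_energy") %in% names(table)))
      stats::approxfun(table$z, table$free_energy, rule = 2)
    }
  )
  structure(
    list(form = form, depth = depth, z_min = z_min, width = width,
         curvature = curvature, z_range = z_range, fn = fn),
    class = "true_pmf"
  )
}

#' Sample umbrella windows from a known free-energy profile
#'
#' Draws i.i.d. samples from the exact biased Boltzmann density of each
#' window, `p_w(z) \propto exp(-beta * (F_true(z) + k/2 * (z - z0_w)^2))`,
#' by inverse-CDF sampling on a fine grid — the statistical model of a
#' perfectly equilibrated, uncorrelated umbrella window, with no molecular
#' dynamics involved.
#'
#' @param pmf A [true_pmf_spec()] object.
#' @param centers Bias centers (nm), strictly increasing, within the
#'   profile's `z_range`.
#' @param force_constant Bias stiffness (kcal/mol/nm^2); 400 matches the
#'   reference umbrella protocol.
#' @param temperature Kelvin.
#' @param n_per_window Samples per window.
#' @param seed RNG seed; window `w` uses a substream derived from
#'   `(seed, w)`.
#' @param n_grid Grid points for the inverse-CDF construction (>= 10^4).
#' @return An [umbrella_windows()] object.
#' @export
sample_umbrella_windows <- function(pmf, centers, force_constant = 400,
                                    temperature = 298.15,
                                    n_per_window = 10000L, seed = 1L,
                                    n_grid = 20000L) {
  stopifnot(inherits(pmf, "true_pmf"),
            all(centers >= pmf$z_range[1]), all(centers <= pmf$z_range[2]),
            n_per_window >= 1, n_grid >= 10000L)
  beta <- 1 / kBT(temperature)
  z <- seq(pmf$z_range[1], pmf$z_range[2], length.out = n_grid)
  F_z <- pmf$fn(z)
  samples <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    e <- F_z + 0.5 * force_constant * (z - centers[w])^2
    dens <- exp(-beta * (e - min(e)))
    cdf <- cumsum((dens[-1] + dens[-n_grid]) / 2) * diff(z[1:2])
    if (!is.finite(cdf[length(cdf)]) || cdf[length(cdf)] <= 0) {
      stop(sprintf("biased density is numerically zero everywhere in window %d (center %.4g nm)",
                   w, centers[w]))
    }
    cdf <- c(0, cdf / cdf[length(cdf)])
    set.seed(substream_seed(seed, w))
    u <- stats::runif(n_per_window)
    samples[[w]] <- stats::approx(cdf, z, xout = u, ties = "ordered")$y
  }
  umbrella_windows(centers, force_constant, temperature, samples = samples)
}
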