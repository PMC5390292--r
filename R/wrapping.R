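#' Parameters of the continuum tip-wrapping model
#'
#' Continuum energetics of a membrane partially wrapping a spherical
#' nanoparticle tip of radius `R` to wrapping angle `theta`, on an infinite
#' tension-free membrane:
#' \deqn{G_{tot}(\theta) = G_{bend} + G_{ad}
#'   = 4\pi k_b (1 - \cos\theta) + 2\pi R^2 k_{ad} (1 - \cos\theta)}
#' with bending modulus `k_b` and (signed) unit adhesion strength `k_ad`;
#' `k_ad < 0` means favorable adhesion.
#'
#' @param k_b Bending modulus, in the units named by `k_b_units`
#'   (typically ~20 k_BT for lipid bilayers).
#' @param k_ad Signed unit adhesion strength (kcal/mol/nm^2); use
#'   [kad_signed()] to convert a reported magnitude.
#' @param tip_radius Tip radius R (nm).
#' @param temperature Kelvin; used to convert k_BT to kcal/mol.
#' @param k_b_units `"kBT"` or `"kcal/mol"`.
#' @return A `wrapping_params` object carrying `k_b_kcal`, the bending
#'   modulus in kcal/mol.
#' @examples
#' wrapping_params(k_b = 20, k_ad = -2, tip_radius = 2)
#' @export
wrapping_params <- function(k_b, k_ad, tip_radius, temperature = 298.15,
                            k_b_units = c("kBT", "kcal/mol")) {
  k_b_units <- match.arg(k_b_units)
  stopifnot(length(k_b) == 1L, k_b > 0,
            length(k_ad) == 1L, is.finite(k_ad),
            length(tip_radius) == 1L, tip_radius > 0,
            length(temperature) == 1L, temperature > 0)
  k_b_kcal <- if (k_b_units == "kBT") k_b * kBT(temperature) else k_b
  structure(
    list(k_b = k_b, k_b_units = k_b_units, k_b_kcal = k_b_kcal,
         k_ad = k_ad, tip_radius = tip_radius, temperature = temperature),
    class = "wrapping_params"
  )
}

#' @export
print.wrapping_params <- function(x, ...) {
  cat(sprintf(
    "Wrapping model: k_b = %g %s (%.4g kcal/mol), k_ad = %g kcal/mol/nm^2, R = %g nm, T = %g K -> %s\n",
    x$k_b, x$k_b_units, x$k_b_kcal, x$k_ad, x$tip_radius, x$temperature,
    if (is_wrapped(x)) "wrapping" else "no wrapping"
  ))
  invisible(x)
}

#' Convert a reported adhesion-strength magnitude to the signed convention
#'
#' Adhesion strengths are often reported as positive magnitudes; the
#' continuum wrapping model needs `k_ad < 0` for favorable adhesion.
#'
#' @param magnitude Non-negative adhesion strength magnitude(s).
#' @return `-abs(magnitude)`.
#' @export
kad_signed <- function(magnitude) -abs(magnitude)

#' Total wrapping energy at a wrapping angle
#'
#' @param theta Wrapping angle(s) in radians, in `[0, pi]`.
#' @param params A [wrapping_params()] object.
#' @return `(4*pi*k_b + 2*pi*R^2*k_ad) * (1 - cos(theta))` in kcal/mol.
#' @export
g_tot <- function(theta, params) {
  stopifnot(inherits(params, "wrapping_params"), is.numeric(theta))
  if (any(theta < 0 | theta > pi)) {
    stop("wrapping angle theta must lie in [0, pi]")
  }
  prefactor(params) * (1 - cos(theta))
}

prefactor <- function(params) {
  4 * pi * params$k_b_kcal + 2 * pi * params$tip_radius^2 * params$k_ad
}

# strict G_tot < 0 with a relative guard so exact balance (G_tot = 0 up to
# floating-point roundoff) is classified no-wrap
wrap_test <- function(pre, k_b_kcal) pre < -1e-9 * 4 * pi * k_b_kcal

#' Does the membrane wrap the tip?
#'
#' Wrapping is energetically favorable when `G_tot < 0` for `theta > 0`,
#' i.e. when `4*pi*k_b + 2*pi*R^2*k_ad < 0`; points exactly on the balance
#' (`G_tot = 0`) are classified as no-wrap (strict inequality).
#'
#' @param params A [wrapping_params()] object.
#' @return Logical.
#' @export
is_wrapped <- function(params) {
  stopifnot(inherits(params, "wrapping_params"))
  wrap_test(prefactor(params), params$k_b_kcal)
}

#' Critical tip radius for wrapping
#'
#' Setting the wrapping energy to zero gives `R_c = sqrt(2*k_b/|k_ad|)`:
#' tips sharper than `R_c` are not wrapped, blunter tips are.
#'
#' @param k_b Bending modulus in the units of `k_b_units`.
#' @param k_ad Signed unit adhesion strength (kcal/mol/nm^2); must be
#'   negative (favorable adhesion), otherwise no finite critical radius
#'   exists.
#' @param temperature Kelvin (for `k_b_units = "kBT"`).
#' @param k_b_units `"kcal/mol"` (default) or `"kBT"`.
#' @return Critical radius in nm.
#' @examples
#' critical_radius(20, -2, k_b_units = "kBT") # sqrt(11.85) ~ 3.44 nm
#' @export
critical_radius <- function(k_b, k_ad, temperature = 298.15,
                            k_b_units = c("kcal/mol", "kBT")) {
  k_b_units <- match.arg(k_b_units)
  stopifnot(length(k_b) == 1L, k_b > 0, length(k_ad) == 1L, is.finite(k_ad))
  if (k_ad >= 0) {
    stop("k_ad must be negative (favorable adhesion); no finite critical radius otherwise")
  }
  k_b_kcal <- if (k_b_units == "kBT") k_b * kBT(temperature) else k_b
  sqrt(2 * k_b_kcal / abs(k_ad))
}

#' Wrapping/no-wrapping phase diagram over (k_b, k_ad)
#'
#' Classifies every grid point at fixed tip radius by the sign of the
#' wrapping-energy prefactor, and attaches the analytic phase boundary
#' `k_ad = -2 * k_b / R^2`.
#'
#' @param k_b_grid Bending-modulus grid, in `k_b_units`.
#' @param k_ad_grid Signed adhesion-strength grid (kcal/mol/nm^2).
#' @param tip_radius Tip radius R (nm).
#' @param temperature Kelvin.
#' @param k_b_units `"kBT"` (default) or `"kcal/mol"`.
#' @return A `phase_diagram`: logical matrix `wrapped` (rows follow
#'   `k_b_grid`, columns `k_ad_grid`) plus a `boundary` data frame;
#'   `as.data.frame()` returns the long form.
#' @examples
#' pd <- phase_diagram(seq(5, 40, by = 5), seq(-4, 0, by = 0.5), tip_radius = 2)
#' head(as.data.frame(pd))
#' @export
phase_diagram <- function(k_b_grid, k_ad_grid, tip_radius,
                          temperature = 298.15,
                          k_b_units = c("kBT", "kcal/mol")) {
  k_b_units <- match.arg(k_b_units)
  stopifnot(length(k_b_grid) >= 1L, all(k_b_grid > 0),
            length(k_ad_grid) >= 1L, all(is.finite(k_ad_grid)),
            length(tip_radius) == 1L, tip_radius > 0)
  conv <- if (k_b_units == "kBT") kBT(temperature) else 1
  kb_kcal <- k_b_grid * conv
  wrapped <- outer(kb_kcal, k_ad_grid,
                   function(kb, kad) wrap_test(4 * pi * kb + 2 * pi * tip_radius^2 * kad, kb))
  dimnames(wrapped) <- list(k_b = signif(k_b_grid, 8), k_ad = signif(k_ad_grid, 8))
  boundary <- data.frame(
    k_b = k_b_grid,
    k_ad_boundary = -2 * kb_kcal / tip_radius^2
  )
  structure(
    list(k_b_grid = k_b_grid, k_ad_grid = k_ad_grid, wrapped = wrapped,
         boundary = boundary, tip_radius = tip_radius,
         temperature = temperature, k_b_units = k_b_units),
    class = "phase_diagram"
  )
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  data.frame(
    k_b = rep(x$k_b_grid, times = length(x$k_ad_grid)),
    k_ad = rep(x$k_ad_grid, each = length(x$k_b_grid)),
    wrapped = as.vector(x$wrapped)
  )
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf(
    "Wrapping phase diagram: %d x %d grid, R = %g nm, k_b in %s; %.1f%% of points wrap\n",
    length(x$k_b_grid), length(x$k_ad_grid), x$tip_radius, x$k_b_units,
    100 * mean(x$wrapped)
  ))
  invisible(x)
}
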