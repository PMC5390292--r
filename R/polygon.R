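#' Specification of a random irregular-polygon ensemble
#'
#' Describes the Monte-Carlo ensemble used to model the nanoparticle surface
#' patch in contact with the membrane as a random star-shaped polygon.
#' Vertex `i` sits at angle `phi_i = (2*pi/n) * (i + u_i * dalpha)` with
#' `u_i ~ U(-1, 1)` (angles then sorted ascending, which guarantees a simple,
#' counter-clockwise polygon) and radius `rho_i = base_radius * (1 + v_i * dr)`
#' with `v_i ~ U(-1, 1)`. `dr` and `dalpha` are the two dimensionless
#' irregularity amplitudes (0.3 each by default).
#'
#' @param n_vertices Number of vertices (>= 3); 4, 6, 8 and 10 are the
#'   standard choices.
#' @param dr Radial irregularity amplitude, in `[0, 1)`.
#' @param dalpha Angular irregularity amplitude, in `[0, 1)`.
#' @param base_radius Mean circumradius (arbitrary length units; relative
#'   areas do not depend on it).
#' @param n_samples Monte-Carlo ensemble size.
#' @param seed Integer RNG seed; each polygon draw uses a substream derived
#'   from `(seed, draw_index)` so the ensemble is order-independent.
#' @return An object of class `polygon_ensemble_spec`.
#' @seealso [generate_polygon()], [area_curve()]
#' @export
polygon_ensemble_spec <- function(n_vertices, dr = 0.3, dalpha = 0.3,
                                  base_radius = 1, n_samples = 100000L,
                                  seed = 1L) {
  stopifnot(
    length(n_vertices) == 1L, n_vertices >= 3,
    length(dr) == 1L, dr >= 0, dr < 1,
    length(dalpha) == 1L, dalpha >= 0, dalpha < 1,
    length(base_radius) == 1L, base_radius > 0,
    length(n_samples) == 1L, n_samples >= 1,
    length(seed) == 1L, is.finite(seed)
  )
  structure(
    list(
      n_vertices = as.integer(n_vertices), dr = dr, dalpha = dalpha,
      base_radius = base_radius, n_samples = as.integer(n_samples),
      seed = as.integer(seed)
    ),
    class = "polygon_ensemble_spec"
  )
}

#' @export
print.polygon_ensemble_spec <- function(x, ...) {
  cat(sprintf(
    "Polygon ensemble: n = %d vertices, dr = %g, dalpha = %g, base radius %g, %d draws (seed %d)\n",
    x$n_vertices, x$dr, x$dalpha, x$base_radius, x$n_samples, x$seed
  ))
  invisible(x)
}

#' Draw one random irregular polygon from an ensemble
#'
#' Reproducible given `(spec$seed, draw_index)`: the same pair always yields
#' the same polygon, independently of any other draws.
#'
#' @param spec A [polygon_ensemble_spec()].
#' @param draw_index 1-based index of the draw within the ensemble.
#' @return An `irregular_polygon`: an n x 2 matrix of vertices in
#'   counter-clockwise order (columns `x`, `y`).
#' @examples
#' spec <- polygon_ensemble_spec(6, dr = 0.3, dalpha = 0.3, seed = 42)
#' p <- generate_polygon(spec, 1)
#' polygon_area(p)
#' @export
generate_polygon <- function(spec, draw_index = 1L) {
  stopifnot(inherits(spec, "polygon_ensemble_spec"), draw_index >= 1)
  set.seed(substream_seed(spec$seed, draw_index))
  n <- spec$n_vertices
  u <- stats::runif(n, -1, 1)
  v <- stats::runif(n, -1, 1)
  phi <- sort((2 * pi / n) * (seq_len(n) - 1 + u * spec$dalpha))
  rho <- spec$base_radius * (1 + v * spec$dr)
  vertices <- cbind(x = rho * cos(phi), y = rho * sin(phi))
  structure(vertices, class = c("irregular_polygon", "matrix", "array"))
}

#' Construct an irregular polygon from vertex coordinates
#'
#' @param x,y Vertex coordinates in boundary order, or `x` an n x 2 matrix.
#' @param validate Check simplicity and counter-clockwise orientation.
#' @return An `irregular_polygon`.
#' @export
irregular_polygon <- function(x, y = NULL, validate = TRUE) {
  v <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  stopifnot(ncol(v) == 2L, nrow(v) >= 3L, all(is.finite(v)))
  colnames(v) <- c("x", "y")
  p <- structure(v, class = c("irregular_polygon", "matrix", "array"))
  if (validate) assert_valid_polygon(p)
  p
}

shoelace <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

# Proper segment-intersection test between all non-adjacent edge pairs.
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (shared endpoint) incl. the wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
      c <- v[j, ]; d <- v[if (j == n) 1L else j + 1L, ]
      if (segments_intersect(a, b, c, d)) return(FALSE)
    }
  }
  TRUE
}

assert_valid_polygon <- function(poly) {
  v <- unclass(poly)
  if (!is_simple_polygon(v)) {
    stop_geometry("polygon is not simple (edges self-intersect)")
  }
  if (shoelace(v) <= 0) {
    stop_geometry("polygon vertices must be in counter-clockwise order (signed area > 0)")
  }
  invisible(poly)
}

#' Area of a simple polygon (shoelace formula)
#'
#' @param poly An `irregular_polygon` or an n x 2 vertex matrix in
#'   counter-clockwise order.
#' @param validate Check simplicity and orientation first (disable inside
#'   tight ensemble loops where the generator already guarantees both).
#' @return The positive area (length squared).
#' @examples
#' sq <- irregular_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' polygon_area(sq) # 1
#' @export
polygon_area <- function(poly, validate = TRUE) {
  v <- if (inherits(poly, "irregular_polygon")) unclass(poly) else as.matrix(poly)
  stopifnot(ncol(v) == 2L, nrow(v) >= 3L)
  if (validate) {
    if (!is_simple_polygon(v)) {
      stop_geometry("polygon is not simple (edges self-intersect)")
    }
    if (shoelace(v) <= 0) {
      stop_geometry("polygon vertices must be in counter-clockwise order (signed area > 0)")
    }
  }
  shoelace(v)
}
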