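# Corner-fillet geometry shared by round_corners() and the ensemble sweep.
#
# For each vertex with wedge angle beta (the interior angle for convex
# corners, 2*pi minus it for reflex corners) the fillet of radius rr is
# tangent to both adjacent edges at offset t = rr / tan(beta/2) from the
# vertex.  The signed area removed (convex) or added (reflex) by the fillet
# is s * rr^2 * (cot(beta/2) - (pi - beta)/2) with s = +1 / -1, so for a
# fixed polygon the rounded area is exactly A - C * rr^2 up to the
# feasibility cutoff rr_max = min over corners/edges of the offset bound.
fillet_geometry <- function(poly) {
  v <- unclass(poly)
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  e_out <- v[nxt, , drop = FALSE] - v            # edge leaving vertex i
  e_in <- v - v[prv, , drop = FALSE]             # edge arriving at vertex i
  L_out <- sqrt(rowSums(e_out^2))
  L_in <- sqrt(rowSums(e_in^2))
  cross <- e_in[, 1] * e_out[, 2] - e_in[, 2] * e_out[, 1]
  dot <- e_in[, 1] * e_out[, 1] + e_in[, 2] * e_out[, 2]
  turn <- atan2(cross, dot)                      # signed turning angle
  s <- ifelse(turn >= 0, 1, -1)                  # +1 convex (CCW), -1 reflex
  beta <- pi - abs(turn)                         # wedge angle in (0, pi)
  tanb2 <- tan(beta / 2)
  # offset per unit rounding radius; beta -> pi (collinear) gives 0
  t_unit <- 1 / tanb2
  # per-vertex area coefficient (signed)
  coef <- s * (1 / tanb2 - (pi - beta) / 2)
  # feasibility: offset at each vertex must not exceed half of either
  # adjacent edge; expressed as the largest admissible rounding radius
  rr_max_vertex <- (0.5 * pmin(L_in, L_out)) * tanb2
  list(
    vertices = v, n = n, e_in = e_in, e_out = e_out,
    L_in = L_in, L_out = L_out, beta = beta, sign = s,
    t_unit = t_unit, coef_sum = sum(coef),
    rr_max = min(rr_max_vertex)
  )
}

#' Replace polygon corners by tangent circular fillets
#'
#' Each vertex is replaced by a circular arc of radius `rr` tangent to both
#' adjacent edges, at offset `t = rr / tan(beta/2)` from the vertex, where
#' `beta` is the wedge angle (interior angle for convex corners, its
#' explement for reflex corners).  Reflex corners are filleted with the same
#' tangent construction, the arc bulging outward, so rounding them adds area.
#'
#' @param poly An `irregular_polygon` (counter-clockwise).
#' @param rr Rounding radius (same length units as the vertices), `>= 0`.
#' @return A `rounded_outline`: a closed boundary of alternating line
#'   segments and arcs, with the source polygon and `rr` attached.
#' @section Infeasibility:
#' When the tangent offset at any vertex exceeds half of an adjacent edge
#' length the fillets would overlap; an error of condition class
#' `ndwrap_infeasible_fillet` is raised so ensemble code can count the
#' rejection.
#' @examples
#' sq <- irregular_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' out <- round_corners(sq, 0.2)
#' rounded_area(out) # 1 - (4 - pi) * 0.04
#' @export
round_corners <- function(poly, rr) {
  stopifnot(length(rr) == 1L, is.finite(rr), rr >= 0)
  if (inherits(poly, "irregular_polygon")) assert_valid_polygon(poly)
  else poly <- irregular_polygon(poly)
  v <- unclass(poly)
  n <- nrow(v)
  if (rr == 0) {
    elements <- lapply(seq_len(n), function(i) {
      list(type = "segment", from = v[i, ], to = v[if (i == n) 1L else i + 1L, ])
    })
    return(structure(
      list(elements = elements, source = poly, rounding_radius = 0),
      class = "rounded_outline"
    ))
  }
  geom <- fillet_geometry(poly)
  if (rr > geom$rr_max) {
    stop_infeasible(sprintf(
      "rounding radius %g infeasible: tangent offset exceeds half an adjacent edge (max feasible radius %g)",
      rr, geom$rr_max
    ))
  }
  t_off <- rr * geom$t_unit
  u_in <- geom$e_in / geom$L_in
  u_out <- geom$e_out / geom$L_out
  T_in <- v - t_off * u_in       # tangent point on the incoming edge
  T_out <- v + t_off * u_out     # tangent point on the outgoing edge
  # fillet center: offset rr from the incoming edge, on the interior side
  # for convex corners and the exterior side for reflex corners
  left_n <- cbind(-u_in[, 2], u_in[, 1])
  centers <- T_in + geom$sign * rr * left_n
  elements <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    th1 <- atan2(T_in[i, 2] - centers[i, 2], T_in[i, 1] - centers[i, 1])
    th2 <- atan2(T_out[i, 2] - centers[i, 2], T_out[i, 1] - centers[i, 1])
    sweep <- ((th2 - th1 + pi) %% (2 * pi)) - pi  # |sweep| = pi - beta < pi
    elements[[2L * i - 1L]] <- list(
      type = "arc", center = centers[i, ], radius = rr,
      theta_start = th1, sweep = sweep
    )
    j <- if (i == n) 1L else i + 1L
    elements[[2L * i]] <- list(type = "segment", from = T_out[i, ], to = T_in[j, ])
  }
  structure(
    list(elements = elements, source = poly, rounding_radius = rr),
    class = "rounded_outline"
  )
}

#' @export
print.rounded_outline <- function(x, ...) {
  n_arc <- sum(vapply(x$elements, function(e) e$type == "arc", logical(1)))
  cat(sprintf(
    "Rounded outline: %d elements (%d arcs), rounding radius %g, area %.6g\n",
    length(x$elements), n_arc, x$rounding_radius, rounded_area(x)
  ))
  invisible(x)
}

#' Exact area enclosed by a rounded outline
#'
#' Evaluates the boundary line integral `A = 1/2 * integral(x dy - y dx)`
#' (Green's theorem) exactly over every segment and circular arc, so convex
#' and reflex fillets are handled uniformly by the signed sweep.
#'
#' @param outline A `rounded_outline` from [round_corners()].
#' @return The enclosed area.
#' @export
rounded_area <- function(outline) {
  stopifnot(inherits(outline, "rounded_outline"))
  a <- 0
  for (e in outline$elements) {
    if (e$type == "segment") {
      a <- a + 0.5 * (e$from[1] * e$to[2] - e$to[1] * e$from[2])
    } else {
      th1 <- e$theta_start
      th2 <- th1 + e$sweep
      r <- e$radius
      a <- a + 0.5 * (e$center[1] * r * (sin(th2) - sin(th1)) -
                        e$center[2] * r * (cos(th2) - cos(th1)) +
                        r^2 * e$sweep)
    }
  }
  unname(a)
}

#' Mean relative contact area versus rounding radius
#'
#' Monte-Carlo sweep behind the relative-area curves: for each rounding
#' radius in `rr_grid`, draws `spec$n_samples` random polygons and averages
#' `area(rr) / area(0)` over the polygons for which the fillet construction
#' is feasible at that radius.  Infeasible polygons are excluded from the
#' mean (not clamped) and counted in `rejection_fraction`.
#'
#' @param spec A [polygon_ensemble_spec()].
#' @param rr_grid Non-negative, ascending rounding radii (units of
#'   `base_radius`).
#' @return An `area_curve` object; `as.data.frame()` gives columns
#'   `n_vertices`, `rr`, `mean_relative_area`, `sd_relative_area`,
#'   `rejection_fraction`, `n_effective`.
#' @examples
#' spec <- polygon_ensemble_spec(4, n_samples = 500, seed = 7)
#' ac <- area_curve(spec, seq(0, 0.2, by = 0.1))
#' as.data.frame(ac)
#' @export
area_curve <- function(spec, rr_grid) {
  stopifnot(inherits(spec, "polygon_ensemble_spec"),
            is.numeric(rr_grid), length(rr_grid) >= 1L,
            all(is.finite(rr_grid)), all(rr_grid >= 0),
            !is.unsorted(rr_grid, strictly = FALSE))
  n_samp <- spec$n_samples
  base_area <- numeric(n_samp)
  coef_sum <- numeric(n_samp)
  rr_max <- numeric(n_samp)
  for (i in seq_len(n_samp)) {
    p <- generate_polygon(spec, i)
    g <- fillet_geometry(p)
    base_area[i] <- shoelace(g$vertices)
    coef_sum[i] <- g$coef_sum
    rr_max[i] <- g$rr_max
  }
  k <- length(rr_grid)
  mean_rel <- sd_rel <- rej <- numeric(k)
  n_eff <- integer(k)
  for (j in seq_len(k)) {
    rr <- rr_grid[j]
    ok <- rr <= rr_max
    if (!any(ok)) {
      stop_infeasible(sprintf(
        "every polygon in the ensemble is infeasible at rounding radius %g", rr
      ))
    }
    rel <- (base_area[ok] - coef_sum[ok] * rr^2) / base_area[ok]
    mean_rel[j] <- mean(rel)
    sd_rel[j] <- if (sum(ok) > 1L) stats::sd(rel) else 0
    rej[j] <- 1 - sum(ok) / n_samp
    n_eff[j] <- sum(ok)
  }
  structure(
    list(
      rr_grid = rr_grid, mean_relative_area = mean_rel,
      sd_relative_area = sd_rel, rejection_fraction = rej,
      n_effective = n_eff, spec = spec
    ),
    class = "area_curve"
  )
}

#' @export
as.data.frame.area_curve <- function(x, ...) {
  data.frame(
    n_vertices = x$spec$n_vertices,
    rr = x$rr_grid,
    mean_relative_area = x$mean_relative_area,
    sd_relative_area = x$sd_relative_area,
    rejection_fraction = x$rejection_fraction,
    n_effective = x$n_effective
  )
}

#' @export
print.area_curve <- function(x, ...) {
  cat(sprintf("Relative contact-area curve (n = %d vertices, %d draws):\n",
              x$spec$n_vertices, x$spec$n_samples))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
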