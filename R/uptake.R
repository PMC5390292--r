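assert_assay <- function(assay) {
  need <- c("nd_type", "condition", "time_hr", "replicate", "intensity")
  missing <- setdiff(need, names(assay))
  if (length(missing) > 0) {
    stop("assay is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(assay$condition), c("4C", "37C"))
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected '4C'/'37C')")
  }
  if (any(assay$intensity < 0)) stop("intensities must be non-negative")
  invisible(assay)
}

#' Photoluminescence calibration slope
#'
#' Ordinary least-squares slope of fluorescence intensity (emission peak)
#' versus particle concentration, used to put different particle types on a
#' common per-mass intensity scale.  The 0 ug/mL point, when present,
#' serves as the blank of the calibration series; its mean intensity is
#' subtracted before fitting (the slope itself is unaffected; the stored
#' `blank` documents the series background).
#'
#' @param series Data frame with columns `concentration` (ug/mL) and
#'   `intensity` (one particle type), needing at least two distinct
#'   concentrations.
#' @return A `calibration_fit` with `slope` (intensity per ug/mL), its
#'   standard error `se_slope`, `intercept` and `blank`.
#' @examples
#' s <- data.frame(concentration = c(0, 5, 10, 15, 20),
#'                 intensity = 2 * c(0, 5, 10, 15, 20))
#' calibration_slope(s)$slope # 2
#' @export
calibration_slope <- function(series) {
  stopifnot(all(c("concentration", "intensity") %in% names(series)))
  if (length(unique(series$concentration)) < 2L) {
    stop("calibration needs at least two distinct concentrations")
  }
  blank <- if (any(series$concentration == 0)) {
    mean(series$intensity[series$concentration == 0])
  } else 0
  fit <- stats::lm(I(intensity - blank) ~ concentration, data = series)
  cf <- summary(fit)$coefficients
  structure(
    list(slope = unname(cf["concentration", "Estimate"]),
         se_slope = unname(cf["concentration", "Std. Error"]),
         intercept = unname(cf["(Intercept)", "Estimate"]),
         blank = blank),
    class = "calibration_fit"
  )
}

#' Fit calibration slopes for every particle type
#'
#' @param calibration Data frame with columns `nd_type`, `concentration`,
#'   `intensity`.
#' @return Named list of [calibration_slope()] fits.
#' @export
calibration_slopes <- function(calibration) {
  stopifnot(all(c("nd_type", "concentration", "intensity") %in% names(calibration)))
  fits <- lapply(split(calibration, calibration$nd_type), calibration_slope)
  fits
}

#' Normalize assay intensities by calibration slope
#'
#' Converts raw well fluorescence into per-mass units: `intensity /
#' slope(nd_type)`.  The calibration blank corrects the calibration series
#' itself (see [calibration_slope()]) but is not subtracted from cell
#' wells: the water-based calibration blank is not a cell-plate background,
#' and the assay design has no cell-only wells to supply one.  Applying the
#' normalization to an already-normalized assay is a no-op (with a
#' warning), so the operation is idempotent.
#'
#' @param assay Long-format assay data frame (`nd_type`, `condition`,
#'   `time_hr`, `replicate`, `intensity`).
#' @param slopes Named list of `calibration_fit` objects (from
#'   [calibration_slopes()]) or a named numeric vector of slopes; every
#'   `nd_type` present in the assay must be covered and every slope must be
#'   positive.
#' @return The assay with `intensity` replaced by its normalized value and
#'   attribute `normalized = TRUE`.
#' @export
normalize_assay <- function(assay, slopes) {
  assert_assay(assay)
  if (isTRUE(attr(assay, "normalized"))) {
    warning("assay is already normalized; returning it unchanged")
    return(assay)
  }
  get_slope <- function(ty) {
    if (!ty %in% names(slopes)) {
      stop(sprintf("no calibration slope for nd_type '%s'", ty))
    }
    s <- slopes[[ty]]
    if (inherits(s, "calibration_fit")) s$slope else as.numeric(s)
  }
  for (ty in unique(assay$nd_type)) {
    slope <- get_slope(ty)
    if (!is.finite(slope) || slope <= 0) {
      stop(sprintf("calibration slope for '%s' must be positive", ty))
    }
    sel <- assay$nd_type == ty
    assay$intensity[sel] <- assay$intensity[sel] / slope
  }
  attr(assay, "normalized") <- TRUE
  assay
}

#' Two-sample t-test p-value (pooled or Welch), raw or summary input
#'
#' @param a,b Replicate values per group (numeric vectors with `n >= 2`),
#'   or each a list/named vector with elements `mean`, `sd`, `n` for
#'   summary input.
#' @param variant `"pooled"` (Student, df = n_a + n_b - 2) or `"welch"`.
#' @return Two-sided p-value.  Two groups with zero variance and equal
#'   means give `p = 1`; zero variance with unequal means is undefined and
#'   returns `NA` with a warning.
#' @examples
#' two_sample_p(list(mean = -41.9033, sd = 1.6671, n = 3),
#'              list(mean = -41.5567, sd = 6.93695, n = 3)) # ~0.937
#' @export
two_sample_p <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  as_summary <- function(x) {
    if (is.list(x) || !is.null(names(x))) {
      x <- as.list(x)
      stopifnot(all(c("mean", "sd", "n") %in% names(x)))
      list(mean = as.numeric(x$mean), sd = as.numeric(x$sd), n = as.numeric(x$n))
    } else {
      stopifnot(is.numeric(x), length(x) >= 2L)
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    }
  }
  sa <- as_summary(a)
  sb <- as_summary(b)
  stopifnot(sa$n >= 2, sb$n >= 2, sa$sd >= 0, sb$sd >= 0)
  if (sa$sd == 0 && sb$sd == 0) {
    if (sa$mean == sb$mean) return(1)
    warning("both groups have zero variance but different means; p-value undefined")
    return(NA_real_)
  }
  if (variant == "pooled") {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    se <- sqrt(sa$sd^2 / sa$n + sb$sd^2 / sb$n)
    df <- se^4 / ((sa$sd^2 / sa$n)^2 / (sa$n - 1) + (sb$sd^2 / sb$n)^2 / (sb$n - 1))
  }
  tstat <- (sa$mean - sb$mean) / se
  2 * stats::pt(-abs(tstat), df)
}

#' Quantify anchored and internalized particle amounts
#'
#' Implements the temperature-split subtraction: 4 C wells measure
#' anchoring only, 37 C wells measure anchoring plus internalization, so
#' per (type, time point)
#' `internalized = mean(37C) - mean(4C)`, with uncertainty by quadrature
#' over the two unpaired well groups.  Negative internalized estimates are
#' reported as-is with a QC flag, never clipped.  Cross-type comparisons
#' (ratios of means with delta-method standard errors, and two-sample
#' p-values on the anchored and total well intensities) are attached for
#' every pair of types.
#'
#' @param assay Long-format (ideally normalized) assay with both conditions
#'   at every (type, time point) and `n >= 2` wells per cell.
#' @param test t-test variant for the comparisons, `"pooled"` or
#'   `"welch"`.
#' @return An `uptake_result`: list with data frames `summary` (per type
#'   and time: anchored/total/internalized means, sds, standard errors,
#'   `qc_negative_internalized`) and `comparisons` (per type pair and time:
#'   metric ratios with standard errors and p-values).
#' @seealso [uptake_ratio()] to pull a single ratio in a chosen direction.
#' @export
quantify_uptake <- function(assay, test = c("pooled", "welch")) {
  test <- match.arg(test)
  assert_assay(assay)
  cells <- unique(assay[, c("nd_type", "time_hr")])
  cells <- cells[order(cells$nd_type, cells$time_hr), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ty <- cells$nd_type[i]; t <- cells$time_hr[i]
    x4 <- assay$intensity[assay$nd_type == ty & assay$time_hr == t &
                            assay$condition == "4C"]
    x37 <- assay$intensity[assay$nd_type == ty & assay$time_hr == t &
                             assay$condition == "37C"]
    if (length(x4) == 0L || length(x37) == 0L) {
      stop(sprintf("nd_type '%s' at %g hr is missing the %s condition",
                   ty, t, if (length(x4) == 0L) "4C" else "37C"))
    }
    if (length(x4) < 2L || length(x37) < 2L) {
      stop(sprintf("nd_type '%s' at %g hr needs >= 2 replicate wells per condition", ty, t))
    }
    data.frame(
      nd_type = ty, time_hr = t,
      n_4C = length(x4), n_37C = length(x37),
      anchored_mean = mean(x4), anchored_sd = stats::sd(x4),
      anchored_se = stats::sd(x4) / sqrt(length(x4)),
      total_mean = mean(x37), total_sd = stats::sd(x37),
      total_se = stats::sd(x37) / sqrt(length(x37)),
      internalized_mean = mean(x37) - mean(x4),
      internalized_sd = sqrt(stats::sd(x37)^2 + stats::sd(x4)^2),
      internalized_se = sqrt(stats::sd(x37)^2 / length(x37) +
                               stats::sd(x4)^2 / length(x4))
    )
  })
  summary_df <- do.call(rbind, rows)
  summary_df$qc_negative_internalized <- summary_df$internalized_mean < 0
  if (any(summary_df$qc_negative_internalized)) {
    warning("negative internalized estimate(s) reported (flagged, not clipped)")
  }
  types <- sort(unique(summary_df$nd_type))
  comparisons <- NULL
  if (length(types) >= 2L) {
    pairs <- utils::combn(types, 2L, simplify = FALSE)
    comp_rows <- list()
    for (pr in pairs) {
      for (t in sort(unique(summary_df$time_hr))) {
        sa <- summary_df[summary_df$nd_type == pr[1] & summary_df$time_hr == t, ]
        sb <- summary_df[summary_df$nd_type == pr[2] & summary_df$time_hr == t, ]
        if (nrow(sa) == 0L || nrow(sb) == 0L) next
        a4 <- assay$intensity[assay$nd_type == pr[1] & assay$time_hr == t &
                                assay$condition == "4C"]
        b4 <- assay$intensity[assay$nd_type == pr[2] & assay$time_hr == t &
                                assay$condition == "4C"]
        a37 <- assay$intensity[assay$nd_type == pr[1] & assay$time_hr == t &
                                 assay$condition == "37C"]
        b37 <- assay$intensity[assay$nd_type == pr[2] & assay$time_hr == t &
                                 assay$condition == "37C"]
        ratio_se <- function(ma, sea, mb, seb) {
          if (ma == 0 || mb == 0) return(NA_real_)
          abs(ma / mb) * sqrt((sea / ma)^2 + (seb / mb)^2)
        }
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          type_a = pr[1], type_b = pr[2], time_hr = t,
          anchored_ratio = sa$anchored_mean / sb$anchored_mean,
          anchored_ratio_se = ratio_se(sa$anchored_mean, sa$anchored_se,
                                       sb$anchored_mean, sb$anchored_se),
          total_ratio = sa$total_mean / sb$total_mean,
          total_ratio_se = ratio_se(sa$total_mean, sa$total_se,
                                    sb$total_mean, sb$total_se),
          internalized_ratio = sa$internalized_mean / sb$internalized_mean,
          internalized_ratio_se = ratio_se(sa$internalized_mean, sa$internalized_se,
                                           sb$internalized_mean, sb$internalized_se),
          p_anchored = two_sample_p(a4, b4, variant = test),
          p_total = two_sample_p(a37, b37, variant = test)
        )
      }
    }
    comparisons <- do.call(rbind, comp_rows)
  }
  structure(list(summary = summary_df, comparisons = comparisons, test = test),
            class = "uptake_result")
}

#' @export
print.uptake_result <- function(x, ...) {
  cat("Anchored / internalized quantification (37C minus 4C subtraction):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$comparisons)) {
    cat(sprintf("\nCross-type comparisons (%s t-test):\n", x$test))
    print(x$comparisons, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Extract a cross-type ratio from an uptake result
#'
#' @param result An `uptake_result` from [quantify_uptake()].
#' @param metric `"anchored"`, `"internalized"` or `"total"`.
#' @param numerator,denominator Particle type names.
#' @param time_hr Time point (hours).
#' @return List with `ratio` (mean numerator / mean denominator) and its
#'   delta-method `se`.
#' @export
uptake_ratio <- function(result, metric = c("anchored", "internalized", "total"),
                         numerator, denominator, time_hr) {
  metric <- match.arg(metric)
  stopifnot(inherits(result, "uptake_result"))
  s <- result$summary
  pick <- function(ty) {
    r <- s[s$nd_type == ty & s$time_hr == time_hr, ]
    if (nrow(r) != 1L) {
      stop(sprintf("no unique summary row for nd_type '%s' at %g hr", ty, time_hr))
    }
    r
  }
  a <- pick(numerator)
  b <- pick(denominator)
  m <- function(r) r[[paste0(metric, "_mean")]]
  se <- function(r) r[[paste0(metric, "_se")]]
  ratio <- m(a) / m(b)
  list(ratio = ratio,
       se = abs(ratio) * sqrt((se(a) / m(a))^2 + (se(b) / m(b))^2))
}
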