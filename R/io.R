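#' Read a free-energy profile in the two-column xvg dialect
#'
#' Parses whitespace-delimited text with comment lines prefixed `#` or `@`
#' (the dialect emitted by common free-energy tools): column 1 is the
#' reaction coordinate (nm), column 2 the free energy (kcal/mol), and an
#' optional column 3 a per-bin error.
#'
#' @param path File path.
#' @return A [pmf_profile()].
#' @export
read_xvg <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data lines in ", path)
  d <- utils::read.table(text = lines[keep], header = FALSE)
  if (ncol(d) < 2L) stop("expected at least two columns (z, free energy) in ", path)
  pmf_profile(d[[1L]], d[[2L]],
              error = if (ncol(d) >= 3L) d[[3L]] else NULL,
              reference = "as-read")
}

#' Write a free-energy profile as xvg-compatible text (and optionally CSV)
#'
#' @param profile A [pmf_profile()].
#' @param path Output file path.
#' @param format `"xvg"` (two/three whitespace-separated columns with
#'   `@`-prefixed headers) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(profile, path, format = c("xvg", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(profile, "pmf_profile"))
  d <- as.data.frame(profile)
  if (format == "csv") {
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    header <- c(
      "@    title \"Potential of mean force\"",
      "@    xaxis  label \"z (nm)\"",
      "@    yaxis  label \"F (kcal/mol)\"",
      sprintf("# reference: %s", profile$reference)
    )
    body <- do.call(sprintf, c(
      list(fmt = paste(rep("%.10g", ncol(d)), collapse = " ")),
      unname(as.list(d))
    ))
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Write umbrella windows as per-window sample files plus a manifest
#'
#' Emits `window_<i>.dat` (one sampled z value per line) for each window
#' and `manifest.csv` with columns `window`, `file`, `center`,
#' `force_constant`, `temperature`.
#'
#' @param windows An [umbrella_windows()] object with samples.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir) {
  stopifnot(inherits(windows, "umbrella_windows"), !is.null(windows$samples))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("window_%02d.dat", seq_along(windows$centers))
  for (w in seq_along(files)) {
    writeLines(sprintf("%.10g", windows$samples[[w]]), file.path(dir, files[w]))
  }
  manifest <- data.frame(
    window = seq_along(files), file = files, center = windows$centers,
    force_constant = windows$force_constant, temperature = windows$temperature
  )
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read umbrella windows from a manifest
#'
#' @param manifest Path to a `manifest.csv` written by
#'   [write_umbrella_windows()] (or a directory containing one).
#' @return An [umbrella_windows()] object.
#' @export
read_umbrella_windows <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  m <- utils::read.csv(manifest)
  need <- c("file", "center", "force_constant", "temperature")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (length(unique(m$force_constant)) != 1L || length(unique(m$temperature)) != 1L) {
    stop("all windows must share one force constant and temperature")
  }
  ord <- order(m$center)
  m <- m[ord, , drop = FALSE]
  samples <- lapply(file.path(dirname(manifest), m$file),
                    function(f) scan(f, quiet = TRUE))
  umbrella_windows(m$center, m$force_constant[1L], m$temperature[1L],
                   samples = samples)
}

#' Read a long-format plate assay CSV
#'
#' Expects columns `nd_type`, `condition` (`4C`/`37C`), `time_hr`,
#' `replicate`, `intensity`.
#'
#' @param path CSV file path.
#' @return A validated assay data frame.
#' @export
read_plate_assay <- function(path) {
  assert_assay(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a calibration-series CSV
#'
#' Expects columns `nd_type`, `concentration` (ug/mL), `intensity`.
#'
#' @param path CSV file path.
#' @return A data frame usable by [calibration_slopes()].
#' @export
read_calibration <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nd_type", "concentration", "intensity")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("calibration is missing column(s): ", paste(missing, collapse = ", "))
  }
  d
}
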