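#' Construct a 1D SAXS scattering curve
#'
#' A `scattering_curve` holds a measured or simulated one-dimensional SAXS
#' profile: a strictly increasing momentum-transfer grid `s` (nm^-1,
#' s = 4 pi sin(theta) / lambda), intensities `I(s)` and per-point
#' uncertainties `sigma`, plus free-form metadata (sample label, detergent
#' and fatty-acid concentrations, ...).
#'
#' @param s Momentum transfer grid, nm^-1; strictly increasing, all > 0.
#' @param intensity Intensities, same length as `s`.
#' @param sigma Per-point uncertainties, same length, all > 0 where the
#'   intensity is finite.
#' @param meta Named list of metadata (e.g. `sample`, `conc_mg_ml`,
#'   `ma_ug_ml`). Stored verbatim; written to `.dat` headers.
#' @return An object of class `scattering_curve`.
#' @seealso [read_dat()], [write_dat()]
#' @export
scattering_curve <- function(s, intensity, sigma, meta = list()) {
  s <- as.numeric(s); intensity <- as.numeric(intensity)
  sigma <- as.numeric(sigma)
  if (length(s) == 0L)
    stop("empty curve: no data points")
  if (length(s) != length(intensity) || length(s) != length(sigma))
    stop("s, intensity and sigma must have the same length")
  if (any(!is.finite(s)) || any(s <= 0))
    stop("s must be finite and positive")
  if (any(diff(s) <= 0))
    stop("s must be strictly increasing (non-monotone grid)")
  if (any(sigma[is.finite(intensity)] <= 0))
    stop("non-positive sigma")
  structure(list(s = s, intensity = intensity, sigma = sigma,
                 meta = as.list(meta)),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("SAXS curve: %d points, s = %.4g..%.4g nm^-1\n",
              length(x$s), min(x$s), max(x$s)))
  if (length(x$meta)) {
    kv <- vapply(names(x$meta),
                 function(k) sprintf("%s=%s", k, format(x$meta[[k]])), "")
    cat("  meta:", paste(kv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$s)

#' Restrict a curve to an s-range
#'
#' @param curve A [scattering_curve()].
#' @param s_min,s_max Inclusive bounds, nm^-1.
#' @return The truncated `scattering_curve`.
#' @export
crop_curve <- function(curve, s_min = -Inf, s_max = Inf) {
  keep <- curve$s >= s_min & curve$s <= s_max
  if (!any(keep)) stop("cropping removed every point")
  scattering_curve(curve$s[keep], curve$intensity[keep],
                   curve$sigma[keep], curve$meta)
}

#' Read a SAXS curve from an ATSAS/SASBDB-style .dat file
#'
#' Whitespace-separated columns s, I and (optionally) sigma; header lines
#' (comments, '#'-prefixed or free text) are skipped tolerantly.  Units are
#' normalized to nm^-1 internally: when `units_hint` is missing the grid is
#' auto-detected, and a grid whose maximum is below 0.6 is taken to be in
#' inverse Angstrom and multiplied by 10.  Two-column files get synthetic
#' 1% uncertainties with a loud warning.
#'
#' Header lines of the form `# key = value` written by [write_dat()] are
#' restored into `meta`.
#'
#' @param path File path.
#' @param units_hint Optional, `"nm"` or `"angstrom"`; overrides
#'   auto-detection.
#' @return A [scattering_curve()] with `s` in nm^-1.
#' @export
read_dat <- function(path, units_hint = c("auto", "nm", "angstrom")) {
  units_hint <- match.arg(units_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  rows <- list()
  for (ln in lines) {
    txt <- trimws(ln)
    if (!nzchar(txt)) next
    m <- regmatches(txt, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.+)$", txt))[[1]]
    if (length(m) == 3L) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
      next
    }
    toks <- strsplit(gsub(",", " ", txt), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) %in% c(2L, 3L) && !anyNA(vals)) rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("no numeric data rows in ", path)
  ncols <- vapply(rows, length, 1L)
  rows <- rows[ncols == max(ncols)]
  if (length(rows) < 10L)
    stop("fewer than 10 numeric rows in ", path)
  m <- do.call(rbind, rows)
  s <- m[, 1]; intensity <- m[, 2]
  # crop leading non-positive s (some deposited files carry s = 0 rows)
  keep <- s > 0
  s <- s[keep]; intensity <- intensity[keep]
  if (ncol(m) >= 3L) {
    sigma <- m[keep, 3]
    if (any(sigma[is.finite(intensity)] <= 0)) stop("non-positive sigma in ", path)
  } else {
    sigma <- pmax(0.01 * abs(intensity), 1e-12)
    warning("2-column file: synthesized sigma = 1% of |I| for ", path)
  }
  if (any(diff(s) <= 0)) stop("non-monotone s grid in ", path)
  in_angstrom <- switch(units_hint,
                        nm = FALSE,
                        angstrom = TRUE,
                        auto = max(s) < 0.6)
  if (in_angstrom) {
    s <- s * 10
    meta$units_in <- "angstrom^-1"
  }
  scattering_curve(s, intensity, sigma, meta)
}

#' Write a SAXS curve to a 3-column .dat file
#'
#' Metadata are written as `# key = value` header lines so that
#' `read_dat(write_dat(curve))` round-trips both the numbers (to 6+
#' significant digits) and the metadata.
#'
#' @param curve A [scattering_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dat <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (length(curve$s) == 0L) stop("refusing to write empty curve")
  hdr <- character(0)
  if (length(curve$meta))
    hdr <- vapply(names(curve$meta), function(k)
      sprintf("# %s = %s", k, format(curve$meta[[k]], digits = 12)), "")
  body <- sprintf("%.9e %.9e %.9e", curve$s, curve$intensity, curve$sigma)
  writeLines(c("# s[1/nm] I sigma", hdr, body), path)
  invisible(path)
}
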