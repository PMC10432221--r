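#' Guinier analysis of a SAXS curve
#'
#' Weighted linear fit of ln I vs s^2 over the lowest angles, iterating
#' the upper limit so that s_max * Rg <= `srg_limit` (default 1.3, the
#' community standard for globular particles).  Rg = sqrt(-3 * slope),
#' I0 = exp(intercept).
#'
#' @param curve A [scattering_curve()].
#' @param srg_limit Dimensionless upper limit on s * Rg.
#' @param min_points Minimum number of points in the fit window.
#' @return An object of class `guinier_result`: `rg` (nm), `i0`,
#'   `fit_range`, `n_points`, `quality` (in [0, 1], residual-based).
#' @export
guinier_fit <- function(curve, srg_limit = 1.3, min_points = 5) {
  stopifnot(inherits(curve, "scattering_curve"))
  ok <- is.finite(curve$intensity) & curve$intensity > 0
  s <- curve$s[ok]; i <- curve$intensity[ok]; sig <- curve$sigma[ok]
  if (length(s) < min_points) stop("too few positive-intensity points")
  fit_window <- function(n_use) {
    idx <- seq_len(n_use)
    x <- s[idx]^2; y <- log(i[idx]); w <- (i[idx] / sig[idx])^2
    # with enough points include the s^4 curvature term: it removes the
    # ~2% Rg bias a pure linear Guinier fit has at s*Rg ~ 1.3
    xm <- if (n_use >= 10) cbind(1, x, x^2) else cbind(1, x)
    fit <- stats::lm.wfit(xm, y, w)
    list(slope = fit$coefficients[2], intercept = fit$coefficients[1],
         resid = fit$residuals, w = w, n = n_use)
  }
  n_use <- length(s)
  for (iter in 1:30) {
    f <- fit_window(n_use)
    if (f$slope >= 0)
      stop("non-globular or noise-dominated: no Guinier decay")
    rg <- sqrt(-3 * f$slope)
    n_new <- max(min_points, sum(s * rg <= srg_limit))
    if (n_new >= n_use || n_new == f$n) break
    n_use <- n_new
  }
  f <- fit_window(n_use)
  if (f$slope >= 0) stop("non-globular or noise-dominated: no Guinier decay")
  rg <- sqrt(-3 * f$slope)
  # residual-based quality: 1 for chi2_red <= 1, decaying above
  chi2_red <- sum(f$w * f$resid^2) / max(f$n - 2, 1)
  quality <- 1 / (1 + max(0, chi2_red - 1))
  structure(list(rg = unname(rg), i0 = unname(exp(f$intercept)),
                 fit_range = c(s[1], s[f$n]), n_points = f$n,
                 quality = quality),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.3f nm, I0 = %.4g (%d pts, s = %.3g..%.3g, q = %.2f)\n",
              x$rg, x$i0, x$n_points, x$fit_range[1], x$fit_range[2],
              x$quality))
  invisible(x)
}

# kernel matrix: I_model(s) = 4 pi * integral P(r) sin(sr)/(sr) dr,
# P represented by its values on a uniform r grid (trapezoid weights)
.ift_kernel <- function(s, r) {
  dr <- r[2] - r[1]
  w <- rep(dr, length(r)); w[1] <- w[length(r)] <- dr / 2
  x <- outer(s, r)
  k <- sin(x) / x
  k[x == 0] <- 1
  4 * pi * sweep(k, 2, w, `*`)
}

.ift_solve <- function(a_w, y_w, d2, alpha) {
  m <- crossprod(a_w) + alpha * crossprod(d2)
  as.numeric(solve(m, crossprod(a_w, y_w)))
}

#' Regularized indirect Fourier transform for P(r)
#'
#' Computes the pair-distance distribution P(r) on a uniform grid
#' 0..dmax (101 points) with boundary conditions P(0) = P(dmax) = 0, by
#' Tikhonov-regularized weighted least squares:
#' min ||(I_model - I)/sigma||^2 + alpha ||P''||^2 with
#' I_model(s) = 4 pi * integral P(r) sin(sr)/(sr) dr.  With
#' `alpha = "auto"` the weight is chosen by the discrepancy principle:
#' the largest alpha on a scale-aware grid whose reduced chi-square is
#' still noise-limited (within 10% of the best achievable, or <= 1),
#' i.e. the smoothest P(r) consistent with the data.  Non-negativity is
#' NOT imposed: mixed-sign contrast (core-shell particles) legitimately
#' produces oscillating P(r); the negativity magnitude is reported.
#'
#' @param curve A [scattering_curve()].
#' @param dmax Maximum particle dimension, nm.
#' @param alpha Regularization weight, or `"auto"`.
#' @param n_r Number of r-grid points (default 101).
#' @return A `distance_distribution`: `r`, `pr`, `dmax`, `rg_pr`,
#'   `i0_pr`, `alpha`, `chi2_reduced`, `negativity` (|min P| / max P).
#' @export
ift_pr <- function(curve, dmax, alpha = "auto", n_r = 101) {
  stopifnot(inherits(curve, "scattering_curve"), dmax > 0)
  if (dmax < pi / max(curve$s))
    warning("dmax below the resolution limit pi/s_max")
  r <- seq(0, dmax, length.out = n_r)
  a <- .ift_kernel(curve$s, r)
  # impose P(0) = P(dmax) = 0 by dropping the boundary columns
  free <- 2:(n_r - 1)
  a_w <- a[, free] / curve$sigma
  y_w <- curve$intensity / curve$sigma
  nf <- length(free)
  d2 <- diff(diag(nf), differences = 2)
  # include boundary curvature so the solution bends smoothly to zero
  edge <- matrix(0, 2, nf)
  edge[1, 1:2] <- c(-2, 1); edge[2, (nf - 1):nf] <- c(1, -2)
  d2 <- rbind(edge[1, ], d2, edge[2, ])
  solve_alpha <- function(al, hard = TRUE) {
    p <- tryCatch(.ift_solve(a_w, y_w, d2, al),
                  error = function(e)
                    if (hard) stop("singular IFT system: ",
                                   conditionMessage(e)) else NULL)
    if (is.null(p)) return(NULL)
    resid <- a_w %*% p - y_w
    list(p = p, rn = sum(resid^2), sn = sum((d2 %*% p)^2))
  }
  if (identical(alpha, "auto")) {
    # discrepancy principle: the LARGEST alpha whose weighted residual is
    # still noise-limited (chi2_red within 10% of the best achievable, or
    # <= 1); gives the smoothest P(r) consistent with the data.  Alphas
    # too small to stabilize the system are skipped.
    al_grid <- 10^seq(-8, 4, length.out = 25) * stats::median(abs(a_w))^2
    sols <- lapply(al_grid, solve_alpha, hard = FALSE)
    keep <- !vapply(sols, is.null, TRUE)
    if (!any(keep)) stop("singular IFT system at every regularization weight")
    al_grid <- al_grid[keep]; sols <- sols[keep]
    dof <- max(length(curve$s) - nf, 1)
    chi2 <- vapply(sols, `[[`, 0, "rn") / dof
    thr <- max(1.1 * min(chi2), 1)
    best <- max(which(chi2 <= thr))
    alpha <- al_grid[best]
    sol <- sols[[best]]
  } else {
    sol <- solve_alpha(alpha)
  }
  pr <- numeric(n_r)
  pr[free] <- sol$p
  dr <- r[2] - r[1]
  ipr <- sum(pr) * dr - (pr[1] + pr[n_r]) * dr / 2
  i0 <- 4 * pi * ipr
  rg2 <- sum(pr * r^2) * dr / (2 * ipr)
  structure(list(r = r, pr = pr, dmax = dmax,
                 rg_pr = if (rg2 > 0) sqrt(rg2) else NA_real_,
                 i0_pr = i0, alpha = alpha,
                 chi2_reduced = sol$rn / max(length(curve$s) - nf, 1),
                 negativity = if (max(pr) > 0) max(0, -min(pr)) / max(pr) else NA_real_),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("P(r): dmax = %.3f nm, Rg = %.3f nm, I0 = %.4g\n",
              x$dmax, x$rg_pr, x$i0_pr))
  invisible(x)
}

#' Scan candidate Dmax values and select the smallest adequate one
#'
#' Runs [ift_pr()] over a grid of dmax values and returns the smallest
#' dmax for which the fit quality has plateaued (chi2 within 10% of the
#' minimum over the grid, or already at the noise floor chi2 <= 1) and
#' P(r) is non-negative within a ringing tolerance of -0.5% of max(P).  If no grid point qualifies, the grid
#' maximum is returned with a warning.
#'
#' @param curve A [scattering_curve()].
#' @param dmax_grid Candidate dmax values, nm (should span ~2*Rg..4*Rg).
#' @param alpha Regularization weight forwarded to [ift_pr()].
#' @param neg_tol Allowed negativity fraction (default 0.005).
#' @param chi2_slack Plateau slack on chi2 (default 1.05).
#' @return Selected dmax, nm.
#' @export
estimate_dmax <- function(curve, dmax_grid, alpha = "auto",
                          neg_tol = 0.005, chi2_slack = 1.05) {
  stopifnot(length(dmax_grid) >= 2)
  dmax_grid <- sort(dmax_grid)
  fits <- lapply(dmax_grid, function(d)
    tryCatch(ift_pr(curve, d, alpha), error = function(e) NULL,
             warning = function(w) suppressWarnings(ift_pr(curve, d, alpha))))
  chi2 <- vapply(fits, function(f) if (is.null(f)) Inf else f$chi2_reduced, 0)
  neg <- vapply(fits, function(f) if (is.null(f)) Inf else f$negativity, 0)
  # plateau: within slack of the best chi2, or already noise-limited
  thr <- max(chi2_slack * min(chi2, na.rm = TRUE), 1)
  ok <- is.finite(chi2) & chi2 <= thr & neg <= neg_tol
  if (!any(ok)) {
    warning("no plateau found: returning grid maximum")
    return(max(dmax_grid))
  }
  dmax_grid[which(ok)[1]]
}

#' Number of Shannon channels in a scattering curve
#'
#' floor(s_max * dmax / pi): the number of independent information
#' channels carried by a curve measured to s_max for a particle of
#' maximum dimension dmax.
#'
#' @param s_max Maximum momentum transfer, nm^-1.
#' @param dmax Maximum particle dimension, nm.
#' @return Integer >= 0.
#' @export
shannon_channels <- function(s_max, dmax) {
  stopifnot(s_max > 0, dmax > 0)
  as.integer(floor(s_max * dmax / pi))
}

#' Micelle aggregation number from forward scattering
#'
#' The ratio I0(micelle) / I0(single monomer equivalent).  Both values
#' must be on the same concentration basis; the normalization of the
#' monomer forward scattering (per what concentration it is quoted) is
#' the caller's responsibility and is exposed, not assumed.
#'
#' @param i0_micelle Forward scattering of the micelle solution, cm^-1.
#' @param i0_monomer_equivalent Computed forward scattering of a single
#'   monomer on the same basis, cm^-1.
#' @return The ratio (dimensionless).
#' @export
aggregation_number <- function(i0_micelle, i0_monomer_equivalent) {
  if (i0_micelle <= 0 || i0_monomer_equivalent <= 0)
    stop("forward intensities must be positive")
  i0_micelle / i0_monomer_equivalent
}

#' Model-free primary analysis of a SAXS curve
#'
#' Convenience wrapper running [guinier_fit()], [estimate_dmax()] (grid
#' spanning 2..4 Guinier Rg), [ift_pr()] at the selected dmax, and
#' [shannon_channels()]; optionally an aggregation number when the
#' monomer-equivalent forward scattering is supplied.
#'
#' @param curve A [scattering_curve()].
#' @param i0_monomer Optional monomer-equivalent forward scattering for
#'   [aggregation_number()].
#' @param dmax Either `"auto"` or a numeric dmax, nm.
#' @return A list of class `primary_params`: `rg`, `i0`, `dmax`,
#'   `rg_pr`, `i0_pr`, `n_shannon`, `n_mol` (NA when `i0_monomer`
#'   missing), plus the underlying `guinier` and `pr` objects.
#' @export
primary_analysis <- function(curve, i0_monomer = NULL, dmax = "auto") {
  g <- guinier_fit(curve)
  if (identical(dmax, "auto")) {
    grid <- seq(2 * g$rg, 4 * g$rg, length.out = 9)
    dmax <- estimate_dmax(curve, grid)
  }
  pr <- ift_pr(curve, dmax)
  structure(list(rg = g$rg, i0 = g$i0, dmax = dmax,
                 rg_pr = pr$rg_pr, i0_pr = pr$i0_pr,
                 n_shannon = shannon_channels(max(curve$s), dmax),
                 n_mol = if (is.null(i0_monomer)) NA_real_
                         else aggregation_number(g$i0, i0_monomer),
                 guinier = g, pr = pr),
            class = "primary_params")
}

#' @export
print.primary_params <- function(x, ...) {
  cat(sprintf("primary analysis: Rg %.3f nm, Dmax %.2f nm, I0 %.4g, N_shannon %d\n",
              x$rg, x$dmax, x$i0, x$n_shannon))
  if (is.finite(x$n_mol)) cat(sprintf("  N_mol = %.1f\n", x$n_mol))
  invisible(x)
}
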