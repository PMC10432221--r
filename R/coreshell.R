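#' Core-shell ellipsoid model parameters
#'
#' Parameter vector of the polydisperse core-shell ellipsoid-of-revolution
#' micelle model.  The ellipsoid has OUTER semiaxes (a_out, a_out, b_out);
#' the hydrophobic core is the inner ellipsoid (a_out - t, a_out - t,
#' b_out - t), i.e. the shell of polar headgroups has constant axis-wise
#' thickness t.  The core carries contrast `rho_in` (negative for aliphatic
#' tails in water), the shell `rho_out` (positive for POE/sorbitan heads),
#' both in e/nm^3 relative to solvent.  Because I is proportional to
#' scale * rho^2, absolute contrasts are only determined on a relative
#' scale; the physically meaningful observables are the ratio
#' rho_in/rho_out and scale * rho_out^2.
#'
#' @param a_out Equatorial outer semiaxis, nm.
#' @param b_out Polar outer semiaxis, nm.
#' @param t Shell thickness, nm (0 <= t < min(a_out, b_out)).
#' @param d_rell Gaussian size dispersion applied additively to both outer
#'   semiaxes, nm (standard deviation; 0 = monodisperse).
#' @param rho_in,rho_out Core and shell electron-density contrasts, e/nm^3.
#' @param scale Overall intensity scale (instrument units).
#' @return An object of class `coreshell_params`.
#' @export
coreshell_params <- function(a_out, b_out, t = 0, d_rell = 0,
                             rho_in = -35, rho_out = 60, scale = 1) {
  stopifnot(a_out > 0, b_out > 0, t >= 0, d_rell >= 0, scale > 0)
  if (t >= min(a_out, b_out))
    stop("shell consumes core: t must be < min(a_out, b_out)")
  structure(list(a_out = a_out, b_out = b_out, t = t, d_rell = d_rell,
                 rho_in = rho_in, rho_out = rho_out, scale = scale),
            class = "coreshell_params")
}

#' @export
print.coreshell_params <- function(x, ...) {
  cat(sprintf(paste0("core-shell ellipsoid: a = %.3f nm, b = %.3f nm, ",
                     "t = %.3f nm, dR = %.3f nm\n"),
              x$a_out, x$b_out, x$t, x$d_rell))
  cat(sprintf("  contrasts: core %.4g, shell %.4g e/nm^3 (ratio %.3f); scale %.4g\n",
              x$rho_in, x$rho_out, x$rho_in / x$rho_out, x$scale))
  invisible(x)
}

#' Normalized sphere scattering amplitude
#'
#' Phi(x) = 3 (sin x - x cos x) / x^3, the form-factor amplitude of a
#' uniform sphere; Phi(0) = 1.  A Taylor series is used below x = 1e-3 to
#' avoid cancellation.
#'
#' @param x Non-negative numeric vector (x = s * r).
#' @return Values in [-1, 1].
#' @export
sphere_amp <- function(x) {
  stopifnot(all(x >= 0))
  out <- x                             # preserves dim for matrix input
  small <- x < 1e-3
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

# volume of ellipsoid of revolution (a, a, b)
.ell_volume <- function(a, b) 4 * pi / 3 * a^2 * b

# Effective radius seen along direction cosine mu for semiaxes (a, a, b):
# r(mu) = sqrt(a^2 (1 - mu^2) + b^2 mu^2)
.ell_radius <- function(a, b, mu) sqrt(a^2 * (1 - mu^2) + b^2 * mu^2)

#' Scattering intensity of a monodisperse core-shell ellipsoid of revolution
#'
#' Orientation-averaged intensity
#' I(s) = scale * integral_0^1 A(s, mu)^2 dmu with
#' A(s, mu) = rho_out V_o Phi(s r_o(mu)) + (rho_in - rho_out) V_i
#' Phi(s r_i(mu)), outer semiaxes (a_out, a_out, b_out) and core semiaxes
#' (a_out - t, a_out - t, b_out - t).  `d_rell` is ignored here; see
#' [polydisperse_intensity()].
#'
#' @param p A [coreshell_params()].
#' @param s Momentum transfer grid, nm^-1, all > 0.
#' @param n_quad Gauss-Legendre quadrature order on mu in [0, 1].
#' @return Intensities at `s`.
#' @export
coreshell_intensity <- function(p, s, n_quad = 64) {
  stopifnot(inherits(p, "coreshell_params"), all(s > 0))
  gl <- pracma::gaussLegendre(n_quad, 0, 1)
  a_i <- p$a_out - p$t
  b_i <- p$b_out - p$t
  v_o <- .ell_volume(p$a_out, p$b_out)
  v_i <- .ell_volume(a_i, b_i)
  r_o <- .ell_radius(p$a_out, p$b_out, gl$x)   # length n_quad
  r_i <- .ell_radius(a_i, b_i, gl$x)
  # amplitude matrix: rows = s, cols = quadrature nodes
  amp <- p$rho_out * v_o * sphere_amp(outer(s, r_o)) +
    (p$rho_in - p$rho_out) * v_i * sphere_amp(outer(s, r_i))
  p$scale * as.numeric(amp^2 %*% gl$w)
}

# Gaussian size-distribution nodes for the polydispersity average:
# offsets delta on the outer semiaxes, truncated at +/- 3 sigma and, if
# needed, above so that core semiaxes stay positive.  Number-weighted.
.size_nodes <- function(p, n_nodes = 15) {
  if (p$d_rell <= 0) return(list(delta = 0, w = 1))
  lo <- -3 * p$d_rell
  hi <- 3 * p$d_rell
  min_core <- min(p$a_out, p$b_out) - p$t
  if (lo <= -min_core) {
    lo <- -0.999 * min_core
    warning("size distribution truncated to keep core semiaxes positive")
  }
  delta <- seq(lo, hi, length.out = n_nodes)
  w <- stats::dnorm(delta, sd = p$d_rell)
  list(delta = delta, w = w / sum(w))
}

#' Polydisperse core-shell ellipsoid intensity
#'
#' Gaussian size-dispersion average of [coreshell_intensity()]: the size
#' offset delta ~ N(0, d_rell^2), truncated at +/- 3 sigma, is applied
#' additively to both outer semiaxes with the shell thickness t held
#' fixed.  The average is taken over the forward-normalized form factors,
#' I(s) = I_mono(0) * sum_k w_k I_k(s) / I_k(0): the dispersion smears
#' the curve SHAPE while the forward value stays that of the mean-size
#' micelle.  (A raw number-weighted intensity average would up-weight the
#' large-size tail as V^2 and broaden the apparent Rg by several tenths
#' of a nm, which is inconsistent with the measured Guinier radii of
#' these micelles; see the package vignette.)  Reduces exactly to the
#' monodisperse intensity when `d_rell = 0`.
#'
#' @inheritParams coreshell_intensity
#' @param n_nodes Number of quadrature nodes over the size distribution.
#' @return Intensities at `s`.
#' @export
polydisperse_intensity <- function(p, s, n_quad = 64, n_nodes = 15) {
  stopifnot(inherits(p, "coreshell_params"))
  if (p$d_rell <= 0) return(coreshell_intensity(p, s, n_quad))
  nd <- .size_nodes(p, n_nodes)
  i0_base <- .forward_amp(p$a_out, p$b_out, p$t, p$rho_in, p$rho_out)^2
  acc <- numeric(length(s))
  for (k in seq_along(nd$delta)) {
    pk <- p
    pk$a_out <- p$a_out + nd$delta[k]
    pk$b_out <- p$b_out + nd$delta[k]
    i0_k <- .forward_amp(pk$a_out, pk$b_out, p$t, p$rho_in, p$rho_out)^2
    acc <- acc + nd$w[k] * coreshell_intensity(pk, s, n_quad) / i0_k
  }
  i0_base * acc
}

# forward amplitude A(0) = rho_out (V_o - V_i) + rho_in V_i, electrons
.forward_amp <- function(a, b, t, rho_in, rho_out) {
  v_o <- .ell_volume(a, b)
  v_i <- .ell_volume(a - t, b - t)
  rho_out * (v_o - v_i) + rho_in * v_i
}

#' Contrast-weighted radius of gyration of the core-shell ellipsoid
#'
#' Closed form from ellipsoid second moments: for a uniform ellipsoid
#' (a, a, b), integral r^2 dV = V (2 a^2 + b^2) / 5.  Core and shell are
#' combined with their contrasts:
#' Rg^2 = sum_k rho_k M2_k / sum_k rho_k V_k over {core, shell}.
#' With `polydisperse = TRUE` the monodisperse Rg is broadened over the
#' size distribution consistently with [polydisperse_intensity()] (the
#' Guinier limit of the forward-normalized dispersion average):
#' Rg_eff^2 = E[Rg(delta)^2].
#'
#' @param p A [coreshell_params()].
#' @param polydisperse Include the d_rell size-distribution broadening.
#' @return Radius of gyration, nm.
#' @export
model_rg <- function(p, polydisperse = FALSE) {
  stopifnot(inherits(p, "coreshell_params"))
  mono <- function(a, b, t) {
    a_i <- a - t; b_i <- b - t
    v_o <- .ell_volume(a, b); v_i <- .ell_volume(a_i, b_i)
    m2_o <- v_o * (2 * a^2 + b^2) / 5
    m2_i <- v_i * (2 * a_i^2 + b_i^2) / 5
    num <- p$rho_out * (m2_o - m2_i) + p$rho_in * m2_i
    den <- p$rho_out * (v_o - v_i) + p$rho_in * v_i
    if (abs(den) < 1e-9 * abs(p$rho_out) * v_o)
      stop("contrast-match point: net contrast-weighted volume ~ 0")
    list(rg2 = num / den, i0 = den^2)
  }
  if (!polydisperse || p$d_rell <= 0) {
    res <- mono(p$a_out, p$b_out, p$t)
    if (res$rg2 <= 0) stop("negative Rg^2: unphysical contrast combination")
    return(sqrt(res$rg2))
  }
  nd <- .size_nodes(p)
  rg2 <- numeric(length(nd$delta))
  for (k in seq_along(nd$delta)) {
    res <- mono(p$a_out + nd$delta[k], p$b_out + nd$delta[k], p$t)
    rg2[k] <- res$rg2
  }
  sqrt(sum(nd$w * rg2))
}

#' Fit the polydisperse core-shell ellipsoid model to a SAXS curve
#'
#' Weighted least squares with a bounded Levenberg-Marquardt trust-region
#' optimizer ([minpack.lm::nls.lm()]), multi-started from a bound-scaled
#' Latin hypercube (fixed seed) to mitigate local minima.  Because SAXS
#' intensities span several decades, the optimizer works on
#' sigma-weighted LOG-intensity residuals, (ln I_model - ln I) * (I /
#' sigma) -- the delta-method equivalent of the linear chi-square near
#' the optimum but far better conditioned from distant starts -- and the
#' overall amplitude is profiled out analytically at every step
#' (variable projection).  The reported `chi2_reduced` is the ordinary
#' linear-space reduced chi-square at the solution.
#'
#' Because the overall scale and the absolute contrasts are degenerate
#' (I ~ scale * rho_out^2), the fit parameterizes shape (a_out, b_out, t,
#' d_rell) and the contrast ratio rho_in/rho_out; the returned params
#' carry rho_out = 1 on the relative scale.
#'
#' @param curve A [scattering_curve()].
#' @param init A [coreshell_params()] giving the starting point (its
#'   rho_in/rho_out ratio is used; absolute contrasts are not fitted).
#' @param bounds Named list of `c(lower, upper)` for any of `a_out`,
#'   `b_out`, `t`, `d_rell`, `ratio`; unset parameters get defaults.
#' @param fit_range Optional `c(s_min, s_max)` restriction, nm^-1.
#' @param n_starts Number of multi-start points (>= 1; start 1 is `init`).
#' @param seed RNG seed for the Latin hypercube starts.
#' @param n_quad,n_nodes Forwarded to [polydisperse_intensity()].
#' @return An object of class `coreshell_fit`: `params`, `chi2_reduced`,
#'   `fitted_curve`, `fit_range`, `uncertainties` (NA until
#'   [fit_uncertainty_sweep()] is run), `n_starts_converged`.
#' @export
fit_coreshell <- function(curve, init, bounds = list(), fit_range = NULL,
                          n_starts = 8, seed = 20230619,
                          n_quad = 48, n_nodes = 11) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(init, "coreshell_params"), n_starts >= 1)
  if (!is.null(fit_range))
    curve <- crop_curve(curve, fit_range[1], fit_range[2])
  s <- curve$s; iobs <- curve$intensity; sig <- curve$sigma

  def_bounds <- list(a_out = c(1.5, 8), b_out = c(1, 6), t = c(0.2, 2),
                     d_rell = c(0, 1.2), ratio = c(-1.5, -0.1))
  for (nm in names(bounds)) def_bounds[[nm]] <- bounds[[nm]]
  b <- def_bounds
  pnames <- c("a_out", "b_out", "t", "d_rell", "ratio")
  lower <- vapply(pnames, function(k) b[[k]][1], 0)
  upper <- vapply(pnames, function(k) b[[k]][2], 0)

  shape_intensity <- function(th) {
    pk <- coreshell_params(th[1], th[2], th[3], th[4],
                           rho_in = th[5], rho_out = 1, scale = 1)
    # optimizer excursions to large d_rell trigger the truncation
    # warning legitimately; silence it inside the fit loop
    suppressWarnings(polydisperse_intensity(pk, s, n_quad, n_nodes))
  }
  pos <- iobs > 0
  wlog <- (iobs / sig)[pos]
  log_iobs <- log(iobs[pos])
  resid_fun <- function(th) {
    im <- tryCatch(shape_intensity(th), error = function(e) NULL)
    if (is.null(im) || any(!is.finite(im)) || any(im <= 0))
      return(rep(1e6, sum(pos)))
    lr <- log(im[pos]) - log_iobs
    la <- -sum(wlog^2 * lr) / sum(wlog^2)   # profiled log amplitude
    (lr + la) * wlog
  }

  th0 <- c(init$a_out, init$b_out, init$t, init$d_rell,
           init$rho_in / init$rho_out)
  th0 <- pmin(pmax(th0, lower + 1e-9), upper - 1e-9)
  starts <- list(th0)
  if (n_starts > 1) {
    set.seed(seed)
    n_extra <- n_starts - 1
    # bound-scaled Latin hypercube on the 5 shape/ratio parameters
    u <- matrix(vapply(1:5, function(j)
      (sample(n_extra) - stats::runif(n_extra)) / n_extra,
      numeric(n_extra)), nrow = n_extra)
    for (i in seq_len(n_extra)) {
      thi <- lower + u[i, ] * (upper - lower)
      if (thi[3] >= min(thi[1], thi[2])) thi[3] <- 0.4 * min(thi[1], thi[2])
      starts[[i + 1]] <- thi
    }
  }

  best <- NULL; diag_msgs <- character(0); n_ok <- 0L
  for (st in starts) {
    fitk <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) e)
    if (inherits(fitk, "error")) {
      diag_msgs <- c(diag_msgs, conditionMessage(fitk)); next
    }
    ssr <- sum(fitk$fvec^2)
    if (!is.finite(ssr)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || ssr < best$ssr)
      best <- list(par = fitk$par, ssr = ssr)
  }
  if (is.null(best))
    stop("no start converged; diagnostics: ",
         paste(unique(diag_msgs), collapse = "; "))

  th <- best$par
  im <- shape_intensity(th)
  amp <- sum(im * iobs / sig^2) / sum(im^2 / sig^2)   # linear-space scale
  params <- coreshell_params(th[1], th[2], th[3], th[4],
                             rho_in = th[5], rho_out = 1,
                             scale = max(amp, .Machine$double.xmin))
  dof <- max(length(s) - 6L, 1L)
  fitted <- scattering_curve(s, amp * im, sig,
                             meta = list(sample = "coreshell fit"))
  structure(list(params = params,
                 uncertainties = stats::setNames(rep(NA_real_, 5), pnames),
                 chi2_reduced = sum(((amp * im - iobs) / sig)^2) / dof,
                 fitted_curve = fitted,
                 fit_range = range(s),
                 n_starts_converged = n_ok),
            class = "coreshell_fit")
}

#' @export
print.coreshell_fit <- function(x, ...) {
  cat("core-shell fit (relative contrast scale)\n")
  print(x$params)
  cat(sprintf("  chi2_red = %.4g over s = %.3g..%.3g nm^-1; %d start(s) converged\n",
              x$chi2_reduced, x$fit_range[1], x$fit_range[2],
              x$n_starts_converged))
  if (any(is.finite(x$uncertainties)))
    cat("  sweep SD:", paste(sprintf("%s %.3g", names(x$uncertainties),
                                     x$uncertainties), collapse = ", "), "\n")
  invisible(x)
}

#' Parameter uncertainties from a fitting-interval sweep
#'
#' Re-fits the model over a set of upper fit limits s_max spanning the
#' data range carrying `n_shannon_window` to `n_shannon_window + 2`
#' Shannon channels (s_max = N pi / Dmax with Dmax taken as
#' 2 (a_out + d_rell)), and reports the per-parameter standard deviation
#' across the refits -- error assessment by varying the fitting interval
#' around the range carrying N_shannon channels.  Below ~N-1 channels the
#' shell thickness / contrast-ratio degeneracy is unresolved and refits
#' are not informative, so the sweep stays at or above the central
#' channel count.
#'
#' @param curve The measured [scattering_curve()].
#' @param fit A `coreshell_fit` from [fit_coreshell()].
#' @param n_shannon_window Number of Shannon channels defining the central
#'   s_max (default 6).
#' @param n_sweep Number of sweep points (default 5, spanning +/- 20%).
#' @param ... Forwarded to [fit_coreshell()] (e.g. `n_starts`).
#' @return The `coreshell_fit` with `uncertainties` filled in and fields
#'   `sweep_smax`, `sweep_values`, `n_failed` attached.
#' @export
fit_uncertainty_sweep <- function(curve, fit, n_shannon_window = 6,
                                  n_sweep = 5, ...) {
  stopifnot(inherits(fit, "coreshell_fit"))
  p <- fit$params
  dmax <- 2 * (p$a_out + p$d_rell)
  s_lo <- n_shannon_window * pi / dmax
  s_hi <- (n_shannon_window + 2) * pi / dmax
  s_lo <- min(max(s_lo, min(curve$s) * 3), max(curve$s) * 0.9)
  s_hi <- min(s_hi, max(curve$s))
  smax_set <- seq(s_lo, s_hi, length.out = n_sweep)
  pnames <- c("a_out", "b_out", "t", "d_rell", "ratio")
  vals <- matrix(NA_real_, n_sweep, 5, dimnames = list(NULL, pnames))
  n_failed <- 0L
  for (i in seq_along(smax_set)) {
    fi <- tryCatch(
      fit_coreshell(curve, init = p, fit_range = c(min(curve$s), smax_set[i]),
                    n_starts = 1, ...),
      error = function(e) NULL)
    if (is.null(fi)) { n_failed <- n_failed + 1L; next }
    q <- fi$params
    vals[i, ] <- c(q$a_out, q$b_out, q$t, q$d_rell, q$rho_in / q$rho_out)
  }
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  fit$uncertainties <- sds
  fit$sweep_smax <- smax_set
  fit$sweep_values <- vals
  fit$n_failed <- n_failed
  fit
}
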