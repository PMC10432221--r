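#' Candidate curve set for mixture decomposition
#'
#' Theoretical intensities of candidate micelle models on a common s-grid,
#' used as the basis for the non-negative mixture fit.
#'
#' @param ids Unique model labels.
#' @param curves Matrix (length(grid) x length(ids)) of non-negative
#'   candidate intensities, or a list of intensity vectors.
#' @param grid Common s grid, nm^-1.
#' @param volumes Optional per-candidate particle volumes used to convert
#'   NNLS amplitude weights into volume fractions (default 1: fractions
#'   are normalized amplitude weights).
#' @return An object of class `candidate_set`.
#' @export
candidate_set <- function(ids, curves, grid, volumes = 1) {
  if (is.list(curves)) curves <- do.call(cbind, curves)
  curves <- as.matrix(curves)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("candidate ids must be unique")
  if (ncol(curves) != length(ids)) stop("one curve per id required")
  if (nrow(curves) != length(grid)) stop("curves must match the grid length")
  if (any(curves < 0)) stop("candidate intensities must be non-negative")
  volumes <- rep_len(volumes, length(ids))
  colnames(curves) <- ids
  structure(list(ids = ids, curves = curves, grid = as.numeric(grid),
                 volumes = volumes),
            class = "candidate_set")
}

#' Build a candidate set from micelle models
#'
#' Computes Debye curves for a list of models on a common grid; particle
#' volumes are taken as the summed displaced bead volumes.
#'
#' @param models Named list of `micelle_model` objects (e.g. from
#'   [generate_ensemble()]).
#' @param s Common s grid, nm^-1.
#' @param ... Forwarded to [as_bead_scatterer()].
#' @return A [candidate_set()].
#' @export
candidate_set_from_models <- function(models, s, ...) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  curves <- vapply(models, function(m)
    debye_intensity(as_bead_scatterer(m, ...), s), numeric(length(s)))
  vols <- vapply(models, function(m) sum(m$beads$volume), 0)
  candidate_set(names(models), pmax(curves, 0), s, vols)
}

#' Reduced chi-square discrepancy between two curves
#'
#' sum(((I_model - I) / sigma)^2) / (N - p).
#'
#' @param model_curve Model intensities on the data grid.
#' @param data A [scattering_curve()].
#' @param p Number of fitted parameters (default 0).
#' @return Reduced chi-square.
#' @export
chi2_reduced <- function(model_curve, data, p = 0) {
  stopifnot(inherits(data, "scattering_curve"),
            length(model_curve) == length(data$s))
  n <- length(data$s)
  if (n <= p) stop("N must exceed the number of parameters")
  sum(((model_curve - data$intensity) / data$sigma)^2) / (n - p)
}

# interpolate candidates onto the data grid (never the reverse: the
# measured sigma must be preserved)
.align_candidates <- function(cands, data) {
  s <- data$s
  if (length(s) == length(cands$grid) &&
      max(abs(s - cands$grid)) < 1e-9 * max(s))
    return(cands$curves)
  if (min(s) < min(cands$grid) - 1e-9 || max(s) > max(cands$grid) + 1e-9)
    stop("data grid extends beyond the candidate grid")
  apply(cands$curves, 2, function(y)
    stats::approx(cands$grid, y, xout = s)$y)
}

#' Non-negative least squares (FNNLS active-set algorithm)
#'
#' Solves min ||A x - y||^2 subject to x >= 0 working on the normal
#' equations (Bro-de Jong "fast NNLS").  Robust on large, strongly
#' collinear candidate bases where plain Lawson-Hanson implementations
#' can cycle.
#'
#' @param a Design matrix (m x n).
#' @param y Response vector (length m).
#' @return List with `x` (solution, length n) and `resnorm`
#'   (||A x - y||^2).
#' @export
nnls_solve <- function(a, y) {
  a <- as.matrix(a)
  ata <- crossprod(a)
  aty <- as.numeric(crossprod(a, y))
  n <- ncol(a)
  x <- numeric(n)
  passive <- logical(n)
  # gradient tolerance on the scale of A'y; solution positivity is tested
  # on the scale of the candidate solution itself
  tol_w <- 10 * .Machine$double.eps * max(abs(aty), 1) * n
  w <- aty - as.numeric(ata %*% x)
  outer_max <- 3L * n
  for (it in seq_len(outer_max)) {
    free <- which(!passive)
    if (length(free) == 0 || max(w[free]) <= tol_w) break
    passive[free[which.max(w[free])]] <- TRUE
    repeat {
      p <- which(passive)
      sp <- tryCatch(solve(ata[p, p, drop = FALSE], aty[p]),
                     error = function(e)
                       qr.solve(ata[p, p, drop = FALSE] +
                                  diag(1e-12 * mean(diag(ata)[p]),
                                       length(p)), aty[p]))
      tol_x <- 1e-12 * max(abs(sp))
      if (all(sp > tol_x)) { x[p] <- sp; x[!passive] <- 0; break }
      neg <- sp <= tol_x
      alpha <- suppressWarnings(min(x[p][neg] / (x[p][neg] - sp[neg]),
                                    na.rm = TRUE))
      if (!is.finite(alpha)) alpha <- 0
      x[p] <- x[p] + alpha * (sp - x[p])
      drop_idx <- x[p] <= tol_x
      passive[p[drop_idx]] <- FALSE
      x[p[drop_idx]] <- 0
      if (!any(passive)) break
    }
    w <- aty - as.numeric(ata %*% x)
  }
  list(x = x, resnorm = sum((a %*% x - y)^2))
}

#' Non-negative least-squares mixture decomposition
#'
#' Solves min || (sum_k w_k I_k - I) / sigma ||^2 subject to w >= 0 over
#' the candidate curves, then converts the amplitude weights into volume
#' fractions f_k = w_k V_k / sum_j w_j V_j using the candidate volumes.
#'
#' @param cands A [candidate_set()].
#' @param data A [scattering_curve()]; interpolated onto the candidate
#'   grid range if the grids differ.
#' @return An object of class `mixture_result`: `fractions` (named, sum
#'   1), `weights` (raw NNLS amplitudes), `chi2_reduced`, `selected`
#'   (ids with nonzero fractions), `scale`, `fitted`.
#' @export
nnls_fractions <- function(cands, data) {
  stopifnot(inherits(cands, "candidate_set"),
            inherits(data, "scattering_curve"))
  a <- .align_candidates(cands, data)
  aw <- a / data$sigma
  yw <- data$intensity / data$sigma
  sol <- nnls_solve(aw, yw)
  w <- sol$x
  if (all(w <= 0)) stop("no candidate explains data: all-zero NNLS solution")
  wv <- w * cands$volumes
  fractions <- stats::setNames(wv / sum(wv), cands$ids)
  fitted <- as.numeric(a %*% w)
  k <- sum(w > 0)
  structure(list(fractions = fractions, weights = stats::setNames(w, cands$ids),
                 sds = stats::setNames(rep(NA_real_, length(w)), cands$ids),
                 chi2_reduced = chi2_reduced(fitted, data, p = k),
                 selected = cands$ids[fractions > 0],
                 scale = sum(w), fitted = fitted),
            class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("mixture fit: chi2_red = %.4g, %d nonzero component(s)\n",
              x$chi2_reduced, length(x$selected)))
  fr <- x$fractions[x$selected]
  sd <- x$sds[x$selected]
  for (k in seq_along(fr))
    cat(sprintf("  %-20s %5.1f%%%s\n", names(fr)[k], 100 * fr[k],
                if (is.finite(sd[k])) sprintf(" +/- %.1f", 100 * sd[k]) else ""))
  invisible(x)
}

#' Select systematically nonzero mixture components via an s_max sweep
#'
#' Runs [nnls_fractions()] with the data truncated at each of several
#' upper limits s_max (default 2.5..3.0 nm^-1 in 5 steps).  A candidate is
#' selected iff its volume fraction exceeds `threshold` at EVERY sweep
#' point ("systematically nonzero").  Final fractions are the sweep means
#' renormalized over the selected set; their SDs over the sweep provide
#' the uncertainty estimates.
#'
#' @param cands A [candidate_set()].
#' @param data A [scattering_curve()].
#' @param smax_values Sweep of upper s limits, nm^-1 (>= 3 values).
#' @param threshold Selection threshold on the fraction (default 0.02).
#' @return A `mixture_result` restricted to the selected components, with
#'   `sds` filled, plus `sweep` (fraction matrix, sweep x candidate).
#' @export
select_models <- function(cands, data,
                          smax_values = seq(2.5, 3.0, length.out = 5),
                          threshold = 0.02) {
  stopifnot(length(smax_values) >= 3)
  frac <- matrix(0, length(smax_values), length(cands$ids),
                 dimnames = list(NULL, cands$ids))
  chi2 <- numeric(length(smax_values))
  for (i in seq_along(smax_values)) {
    di <- crop_curve(data, s_max = smax_values[i])
    fi <- nnls_fractions(cands, di)
    frac[i, ] <- fi$fractions
    chi2[i] <- fi$chi2_reduced
  }
  sel <- cands$ids[apply(frac > threshold, 2, all)]
  if (length(sel) == 0) stop("empty selection: no systematically nonzero component")
  mean_fr <- colMeans(frac[, sel, drop = FALSE])
  sds <- apply(frac[, sel, drop = FALSE], 2, stats::sd)
  mean_fr <- mean_fr / sum(mean_fr)
  structure(list(fractions = mean_fr, sds = sds,
                 chi2_reduced = mean(chi2), selected = sel,
                 scale = NA_real_, sweep = frac,
                 smax_values = smax_values),
            class = "mixture_result")
}
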