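# Independent oracles used across the suite.  These deliberately avoid the
# package's analytic form-factor path so that agreement is evidence, not
# circularity.

# noiseless uniform-sphere curve with proportional "errors" for weighting
sphere_curve <- function(R = 3, rho = 1, s = seq(0.1, 3, length.out = 291),
                         sig_frac = 0.01) {
  V <- 4 * pi / 3 * R^3
  I <- (rho * V)^2 * (3 * (sin(s * R) - s * R * cos(s * R)) / (s * R)^3)^2
  scattering_curve(s, I, pmax(I * sig_frac, 1e-12))
}

# closed-form distance distribution of a uniform sphere, p(r) ~ r^2 (...)
sphere_pr_analytic <- function(r, R) {
  p <- r^2 * (1 - 3 * r / (4 * R) + r^3 / (16 * R^3))
  p[r > 2 * R] <- 0
  p
}

# Monte-Carlo sample of points uniformly filling the outer ellipsoid of a
# core-shell body, weighted by the local contrast: a brute-force Debye
# oracle for coreshell_intensity (monodisperse)
mc_coreshell_scatterer <- function(p, n = 4000, seed = 7) {
  set.seed(seed)
  pts <- matrix(nrow = 0, ncol = 3)
  while (nrow(pts) < n) {
    cand <- cbind(runif(n, -1, 1), runif(n, -1, 1), runif(n, -1, 1))
    pts <- rbind(pts, cand[rowSums(cand^2) <= 1, , drop = FALSE])
  }
  pts <- pts[seq_len(n), ]
  xyz <- cbind(pts[, 1] * p$a_out, pts[, 2] * p$a_out, pts[, 3] * p$b_out)
  ai <- p$a_out - p$t; bi <- p$b_out - p$t
  inside <- (xyz[, 1] / ai)^2 + (xyz[, 2] / ai)^2 + (xyz[, 3] / bi)^2 <= 1
  v_o <- 4 * pi / 3 * p$a_out^2 * p$b_out
  f <- ifelse(inside, p$rho_in, p$rho_out) * v_o / n
  bead_scatterer(xyz, f, smear_width = 0)
}

# replicate-averaged Monte-Carlo Debye intensity with a standard error:
# "agreement within sampling error" can then be asserted rigorously
mc_coreshell_intensity <- function(p, s, n = 3000, n_rep = 5, seed0 = 100) {
  runs <- vapply(seq_len(n_rep), function(k) {
    b <- mc_coreshell_scatterer(p, n = n, seed = seed0 + k)
    debye_intensity(b, s)
  }, numeric(length(s)))
  list(mean = rowMeans(runs),
       se = apply(runs, 1, stats::sd) / sqrt(n_rep))
}

# reduced 12-candidate dictionary: one conformer per geometry x size --
# the "well-separated" basis for mixture-recovery property tests
well_separated_candidates <- function(s = seq(0.1, 3, length.out = 146)) {
  ids <- as.vector(outer(1:6, c(22, 35),
                         function(m, n) sprintf("m%d_n%d_1-c18", m, n)))
  models <- list()
  for (m in 1:6) for (n in c(22, 35))
    models[[sprintf("m%d_n%d_1-c18", m, n)]] <-
      build_micelle(ellipsoid_geometry(m), "1-c18", n)
  candidate_set_from_models(models[ids], s)
}
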