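test_that("Debye sum reproduces closed two-bead and forward values", {
  b <- bead_scatterer(rbind(c(0, 0, 0), c(0, 0, 1)), f_eff = 1,
                      smear_width = 0)
  expect_equal(debye_intensity(b, pi, method = "direct"), 2, tolerance = 1e-12)
  expect_equal(debye_intensity(b, 1e-6, method = "direct"), 4,
               tolerance = 1e-9)
  # bead-order symmetry
  b2 <- bead_scatterer(rbind(c(0, 0, 1), c(0, 0, 0)), f_eff = 1,
                       smear_width = 0)
  s <- seq(0.2, 3, length.out = 20)
  expect_equal(debye_intensity(b, s), debye_intensity(b2, s))
})

test_that("histogram-accelerated path matches the O(N^2) reference", {
  m <- build_micelle(ellipsoid_geometry(6), "1-c18", 35)
  b <- as_bead_scatterer(m)
  s <- seq(0.1, 3, length.out = 60)
  i_hist <- debye_intensity(b, s, method = "histogram", bin_width = 0.05)
  i_dir <- debye_intensity(b, s, method = "direct")
  expect_lt(max(abs(i_hist - i_dir) / abs(i_dir)), 0.005)
})

test_that("bead-filled ellipsoid matches the analytic form factor", {
  fill <- ellipsoid_bead_fill(4, 3, 3, 0.25)
  b <- bead_scatterer(fill, 1, smear_width = 0)
  # compare at the lattice's own effective semiaxes (a point lattice sits
  # half a cell short of the continuum boundary)
  a_eff <- sqrt(5 * mean(fill[, 1]^2))
  c_eff <- sqrt(5 * mean(fill[, 3]^2))
  p <- coreshell_params(c_eff, a_eff, t = 0, d_rell = 0,
                        rho_in = 1, rho_out = 1)
  s <- seq(0.1, 2, length.out = 30)
  i_bead <- debye_intensity(b, s) / nrow(fill)^2
  i_an <- coreshell_intensity(p, s) / (4 * pi / 3 * c_eff^2 * a_eff)^2
  expect_lt(max(abs(i_bead - i_an) / i_an), 0.02)
})

test_that("coordinate Rg handles point, shell and filled bodies", {
  expect_equal(coords_rg(bead_scatterer(matrix(c(1, 2, 3), 1, 3), 5)), 0)
  u <- fibonacci_directions(100) * 2.5
  expect_equal(coords_rg(bead_scatterer(u, 1)), 2.5, tolerance = 1e-6)
  fill <- ellipsoid_bead_fill(4, 3, 3, 0.25)
  expect_equal(coords_rg(bead_scatterer(fill, 1)), sqrt(34 / 5),
               tolerance = 0.03)
  expect_error(coords_rg(bead_scatterer(u, rep(c(1, -1), 50))),
               "contrast-matched")
})

test_that("pair-distance histogram has the counting identities", {
  b <- bead_scatterer(rbind(c(0, 0, 0), c(0, 0, 2)), f_eff = c(2, 2),
                      smear_width = 0)
  pr <- coords_pr(b, n_bins = 50)
  expect_equal(pr$dmax, 2)
  expect_identical(which.max(pr$pr), 50L)   # single spike at r = 2
  m <- build_micelle(ellipsoid_geometry(6), "1-c18", 35)
  bm <- as_bead_scatterer(m)
  prm <- coords_pr(bm)
  f <- bm$f_eff
  dr <- prm$r[2] - prm$r[1]
  expect_equal(sum(prm$pr) * dr, sum(f)^2 - sum(f^2), tolerance = 1e-9)
  expect_equal(prm$rg_pr, coords_rg(bm), tolerance = 0.01)
  # overall micelle size: 2a plus tail allowance
  expect_gte(prm$dmax, 8); expect_lte(prm$dmax, 11)
})

test_that("forward intensity is additive for far-separated bodies", {
  set.seed(4)
  a <- matrix(rnorm(60), 20, 3)
  b <- matrix(rnorm(60), 20, 3) + 500
  f1 <- runif(20); f2 <- runif(20)
  joint <- bead_scatterer(rbind(a, b), c(f1, f2), smear_width = 0)
  expect_equal(debye_intensity(joint, 1e-7, method = "direct"),
               (sum(f1) + sum(f2))^2, tolerance = 1e-4)
})

test_that("the DDM reference micelle reproduces the measured radius", {
  m <- ddm_micelle()
  expect_identical(m$n_mol, 174L)
  expect_equal(174 * 510.6 / 1000, 89, tolerance = 0.005)
  b <- as_bead_scatterer(m)
  s <- seq(0.1, 3, length.out = 146)
  I <- debye_intensity(b, s)
  g <- guinier_fit(scattering_curve(s, I, pmax(abs(I) * 0.01, 1e-9)))
  expect_gte(g$rg, 2.9); expect_lte(g$rg, 3.3)
})

test_that("optional hydration layer raises head contrast only", {
  m <- build_micelle(ellipsoid_geometry(5), "1-c12", 22)
  b0 <- as_bead_scatterer(m)
  bh <- as_bead_scatterer(m, hydration_contrast = 30)
  head <- m$beads$role == "head"
  expect_true(all(bh$f_eff[head] > b0$f_eff[head]))
  expect_equal(bh$f_eff[!head], b0$f_eff[!head])
})
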