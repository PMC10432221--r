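test_that("sphere amplitude kernel matches its closed form and limits", {
  expect_identical(sphere_amp(0), 1)
  expect_equal(sphere_amp(pi), 3 / pi^2, tolerance = 1e-12)
  x <- c(0.01, 0.1, 1, 5)
  expect_equal(sphere_amp(x), 3 * (sin(x) - x * cos(x)) / x^3,
               tolerance = 1e-12)
  # continuity across the series switch at x = 1e-3: the series value
  # just below the switch equals the series evaluated just above it
  series <- function(x) 1 - x^2 / 10 + x^4 / 280
  expect_equal(sphere_amp(0.999e-3), series(0.999e-3), tolerance = 1e-15)
  expect_equal(sphere_amp(1.001e-3), series(1.001e-3), tolerance = 1e-9)
  expect_true(all(abs(sphere_amp(seq(0, 50, by = 0.1))) <= 1))
})

test_that("core-shell intensity collapses to the uniform sphere", {
  R <- 3; rho <- 2
  p <- coreshell_params(R, R, t = 0, d_rell = 0, rho_in = rho, rho_out = rho)
  s <- seq(0.1, 3, length.out = 100)
  V <- 4 * pi / 3 * R^3
  expect_equal(coreshell_intensity(p, s), (rho * V)^2 * sphere_amp(s * R)^2,
               tolerance = 1e-10)
})

test_that("forward amplitude matches hand-computed ellipsoid volumes", {
  p <- micelle_fixture("table2_ps20")
  # independent arithmetic: V = (4 pi / 3) a^2 b for outer and core bodies
  v_o <- 4 * pi / 3 * 3.68^2 * 2.46
  v_i <- 4 * pi / 3 * (3.68 - 0.88)^2 * (2.46 - 0.88)
  a0 <- 60 * (v_o - v_i) + (-35) * v_i
  expect_equal(coreshell_intensity(p, 1e-4) / p$scale, a0^2,
               tolerance = 1e-6)
  expect_equal(v_o, 139.6, tolerance = 1e-3)
  expect_equal(v_i, 51.9, tolerance = 1e-2)
})

test_that("quadrature is converged at the default order", {
  p <- micelle_fixture("table2_f4")
  s <- seq(0.1, 3, length.out = 50)
  i64 <- coreshell_intensity(p, s, n_quad = 64)
  i128 <- coreshell_intensity(p, s, n_quad = 128)
  expect_lt(max(abs(i64 - i128) / abs(i128)), 1e-6)
})

test_that("analytic intensity agrees with a Monte-Carlo Debye oracle", {
  p <- micelle_fixture("table2_ps20")
  pm <- p; pm$d_rell <- 0; pm$scale <- 1
  s <- seq(0.1, 2, length.out = 25)
  mc <- mc_coreshell_intensity(pm, s, n = 3000, n_rep = 5, seed0 = 7)
  i_an <- coreshell_intensity(pm, s)
  # agreement within the oracle's own sampling error, everywhere
  expect_true(all(abs(mc$mean - i_an) <= 5 * mc$se))
  # and to a few percent where the curve carries real weight
  rel <- abs(mc$mean - i_an) / i_an
  expect_lt(stats::median(rel[i_an / i_an[1] > 0.05]), 0.03)
})

test_that("shell consuming the core is rejected", {
  expect_error(coreshell_params(3, 2, t = 2.5), "shell consumes core")
})

test_that("size dispersion smears the shape and broadens Rg monotonically", {
  s <- seq(0.05, 3, length.out = 200)
  base <- micelle_fixture("table2_ps20")
  p0 <- base; p0$d_rell <- 0
  expect_equal(polydisperse_intensity(p0, s), coreshell_intensity(p0, s))
  rgs <- vapply(c(0, 0.2, 0.37, 0.5), function(d) {
    pk <- base; pk$d_rell <- d
    I <- polydisperse_intensity(pk, s)
    guinier_fit(scattering_curve(s, I, pmax(0.01 * I, 1e-15)))$rg
  }, 0)
  expect_true(all(diff(rgs) > 0))
  # forward-normalized average keeps I(0) at the mean-size value
  expect_equal(polydisperse_intensity(base, 1e-4),
               coreshell_intensity(p0, 1e-4), tolerance = 1e-6)
})

test_that("Guinier radius of the dispersed PS20 model matches measurement", {
  p <- micelle_fixture("table2_ps20")
  s <- seq(0.05, 3, length.out = 300)
  I <- polydisperse_intensity(p, s)
  g <- guinier_fit(scattering_curve(s, I, pmax(0.01 * I, 1e-15)))
  expect_equal(g$rg, 3.4, tolerance = 0.1 / 3.4)
})

test_that("contrast-weighted model Rg matches a Monte-Carlo second moment", {
  # sphere limit
  ps <- coreshell_params(3, 3, t = 0, d_rell = 0, rho_in = 5, rho_out = 5)
  expect_equal(model_rg(ps), sqrt(3 / 5) * 3, tolerance = 1e-12)
  for (nm in c("table2_ps20", "table2_f2")) {
    p <- micelle_fixture(nm)
    b <- mc_coreshell_scatterer(p, n = 20000, seed = 13)
    rg_mc <- sqrt(sum(b$f_eff * rowSums(b$coords^2)) / sum(b$f_eff))
    expect_equal(model_rg(p), rg_mc, tolerance = 0.01)
  }
  expect_equal(model_rg(micelle_fixture("table2_ps20")), 3.30,
               tolerance = 0.01 / 3.3)
  expect_equal(model_rg(micelle_fixture("table2_f2")), 2.88,
               tolerance = 0.01 / 2.9)
  # contrast-match point errors out
  pc <- coreshell_params(3, 2, t = 0.5, rho_in = -100, rho_out = 1)
  pc$rho_in <- local({ # solve for exact match
    v_o <- 4 * pi / 3 * 9 * 2; v_i <- 4 * pi / 3 * 2.5^2 * 1.5
    -1 * (v_o - v_i) / v_i
  })
  expect_error(model_rg(pc), "contrast-match")
})

test_that("noiseless parameter recovery from a perturbed start is exact", {
  p <- micelle_fixture("table2_ps20")
  cv <- simulate_curve(p, noise = noise_model(0, 0))
  init <- p
  init$a_out <- p$a_out * 1.2; init$b_out <- p$b_out * 0.8
  init$t <- p$t * 1.15; init$d_rell <- p$d_rell * 0.8
  init$rho_in <- -0.45; init$rho_out <- 1
  f <- fit_coreshell(cv, init, n_starts = 1)
  q <- f$params
  expect_equal(q$a_out, p$a_out, tolerance = 0.01)
  expect_equal(q$b_out, p$b_out, tolerance = 0.01)
  expect_equal(q$t, p$t, tolerance = 0.01)
  expect_equal(q$rho_in / q$rho_out, p$rho_in / p$rho_out, tolerance = 0.02)
})

test_that("an oblate truth fits worse under prolate-constrained bounds", {
  p <- micelle_fixture("table2_ps20")   # oblate: a > b
  cv <- simulate_curve(p, noise = noise_model(), seed = 3)
  init_ob <- p
  f_oblate <- fit_coreshell(cv, init_ob, n_starts = 1)
  # prolate constraint: equatorial semiaxis smaller than polar
  init_pr <- coreshell_params(2.4, 3.7, t = 0.8, d_rell = 0.3,
                              rho_in = -0.55, rho_out = 1)
  f_prolate <- fit_coreshell(cv, init_pr, n_starts = 2,
                             bounds = list(a_out = c(1.5, 2.8),
                                           b_out = c(3.0, 6)))
  expect_gt(f_prolate$chi2_reduced, f_oblate$chi2_reduced)
})

test_that("interval-sweep uncertainties are tiny on noiseless data", {
  p <- micelle_fixture("table2_ps20")
  cv <- simulate_curve(p, noise = noise_model(0, 0))
  f <- fit_coreshell(cv, p, n_starts = 1)
  fs <- fit_uncertainty_sweep(cv, f)
  expect_true(all(fs$uncertainties[c("a_out", "b_out", "t")] <
                    0.01 * c(p$a_out, p$b_out, p$t)))
  expect_identical(fs$n_failed, 0L)
})

test_that("interval-sweep uncertainties on noisy data match table magnitudes", {
  p <- micelle_fixture("table2_ps20")
  cv <- simulate_curve(p, noise = noise_model(), seed = 7)
  f <- fit_coreshell(cv, p, n_starts = 1)
  fs <- fit_uncertainty_sweep(cv, f)
  # semiaxis SDs of order 0.01-0.1 nm, as in the published +/- entries
  expect_lt(fs$uncertainties["a_out"], 0.1)
  expect_lt(fs$uncertainties["b_out"], 0.1)
  expect_gt(sum(fs$uncertainties[c("a_out", "b_out")]), 0)
})
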