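# a small set of synthetic candidate curves with distinct shapes
toy_candidates <- function(s = seq(0.1, 3, length.out = 120)) {
  shapes <- cbind(exp(-3 * s^2), exp(-1.2 * s^2),
                  1 / (1 + (2 * s)^2)^2, exp(-6 * s))
  candidate_set(c("A", "B", "C", "D"), shapes, s)
}

test_that("the in-package NNLS matches an independent solver", {
  set.seed(1)
  for (k in 1:20) {
    a <- matrix(runif(80), 20, 4); y <- runif(20)
    expect_equal(nnls_solve(a, y)$x, pracma::lsqnonneg(a, y)$x,
                 tolerance = 1e-10)
  }
  # non-trivial active set: target outside the cone
  a <- cbind(c(1, 0), c(-1, 1))
  expect_equal(nnls_solve(a, c(-2, 1))$x, pracma::lsqnonneg(a, c(-2, 1))$x)
})

test_that("exact data recover a single candidate and exact mixtures", {
  cands <- toy_candidates()
  s <- cands$grid
  d1 <- scattering_curve(s, cands$curves[, "B"],
                         pmax(0.01 * cands$curves[, "B"], 1e-12))
  r1 <- nnls_fractions(cands, d1)
  expect_equal(unname(r1$fractions["B"]), 1, tolerance = 1e-9)
  expect_lt(r1$chi2_reduced, 1e-12)

  mix <- 0.3 * cands$curves[, "A"] + 0.7 * cands$curves[, "C"]
  d2 <- scattering_curve(s, mix, pmax(0.01 * mix, 1e-12))
  r2 <- nnls_fractions(cands, d2)
  expect_equal(unname(r2$fractions[c("A", "C")]), c(0.3, 0.7),
               tolerance = 1e-6)
  expect_equal(unname(r2$fractions["D"]), 0)
  expect_equal(sum(r2$fractions), 1, tolerance = 1e-9)
})

test_that("NNLS is invariant under candidate reordering", {
  cands <- toy_candidates()
  s <- cands$grid
  mix <- 0.4 * cands$curves[, "A"] + 0.6 * cands$curves[, "D"]
  d <- scattering_curve(s, mix, pmax(0.01 * mix, 1e-12))
  perm <- c(3, 1, 4, 2)
  cands_p <- candidate_set(cands$ids[perm], cands$curves[, perm], s)
  r <- nnls_fractions(cands, d)
  rp <- nnls_fractions(cands_p, d)
  expect_equal(r$fractions[sort(names(r$fractions))],
               rp$fractions[sort(names(rp$fractions))], tolerance = 1e-9)
})

test_that("volume weighting converts amplitudes into volume fractions", {
  cands <- toy_candidates()
  cands$volumes <- c(1, 2, 4, 8)
  s <- cands$grid
  mix <- 0.5 * cands$curves[, "A"] + 0.5 * cands$curves[, "C"]
  d <- scattering_curve(s, mix, pmax(0.01 * mix, 1e-12))
  r <- nnls_fractions(cands, d)
  expect_equal(unname(r$fractions["C"] / r$fractions["A"]), 4,
               tolerance = 1e-6)
})

test_that("reduced chi-square behaves like a chi-square statistic", {
  s <- seq(0.1, 2, length.out = 200)
  d <- scattering_curve(s, rep(10, 200), rep(1, 200))
  expect_equal(chi2_reduced(rep(10, 200), d), 0)
  expect_equal(chi2_reduced(rep(11, 200), d), 1)
  expect_error(chi2_reduced(rep(10, 200), d, p = 200), "exceed")
  set.seed(5)
  sims <- replicate(100, {
    y <- 10 + rnorm(200)
    chi2_reduced(rep(10, 200), scattering_curve(s, y, rep(1, 200)))
  })
  expect_equal(mean(sims), 1, tolerance = 0.05)
})

test_that("sweep selection keeps systematically nonzero components", {
  cands <- toy_candidates()
  s <- cands$grid
  mix <- 0.45 * cands$curves[, "A"] + 0.55 * cands$curves[, "C"]
  d <- scattering_curve(s, mix, pmax(1e-8 * mix, 1e-15))
  r <- select_models(cands, d)
  expect_setequal(r$selected, c("A", "C"))
  expect_true(all(r$sds < 1e-6))
  expect_equal(sum(r$fractions), 1, tolerance = 1e-9)
})

test_that("chi2 decreases as true components enter the candidate set", {
  cands <- toy_candidates()
  s <- cands$grid
  mix <- 0.5 * cands$curves[, "A"] + 0.3 * cands$curves[, "B"] +
    0.2 * cands$curves[, "D"]
  set.seed(9)
  iobs <- mix * (1 + 0.02 * rnorm(length(s)))
  d <- scattering_curve(s, iobs, 0.02 * mix)
  chi <- vapply(list("A", c("A", "B"), c("A", "B", "D")), function(ids) {
    nnls_fractions(candidate_set(ids, cands$curves[, ids, drop = FALSE], s),
                   d)$chi2_reduced
  }, 0)
  expect_true(all(diff(chi) < 0))
})

test_that("well-separated micelle mixtures are recovered under noise", {
  cands <- well_separated_candidates()
  s <- cands$grid
  true_ids <- c("m1_n35_1-c18", "m5_n22_1-c18", "m6_n35_1-c18")
  curves_n <- sweep(cands$curves[, true_ids], 2,
                    colSums(cands$curves[, true_ids]), "/")
  i_true <- as.numeric(curves_n %*% c(0.3, 0.3, 0.4))
  hits <- 0L
  n_seeds <- 25L
  sds_seen <- c()
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    sig <- 0.02 * i_true
    cv <- scattering_curve(s, i_true + rnorm(length(s), 0, sig), sig)
    r <- tryCatch(select_models(cands, cv), error = function(e) NULL)
    if (is.null(r)) next
    if (all(true_ids %in% r$selected)) hits <- hits + 1L
    sds_seen <- c(sds_seen, r$sds[intersect(true_ids, r$selected)])
  }
  expect_gte(hits / n_seeds, 0.9)
  # sweep SDs of the order of a few percentage points
  expect_lt(stats::median(sds_seen), 0.05)
})
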