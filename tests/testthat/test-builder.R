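test_that("Fibonacci directions are unit, deterministic and quasi-uniform", {
  expect_equal(fibonacci_directions(1), matrix(c(0, 0, 1), 1, 3))
  for (n in c(2, 8, 21, 34, 50)) {
    u <- fibonacci_directions(n)
    expect_equal(sqrt(rowSums(u^2)), rep(1, n), tolerance = 1e-12)
  }
  expect_identical(fibonacci_directions(34), fibonacci_directions(34))
  expect_error(fibonacci_directions(0), ">= 1")
  # brute force over all pairs at n = 34: minimal separation stays above
  # 0.7 x the asymptotic uniform spacing sqrt(8 pi / (sqrt(5) n))
  u <- fibonacci_directions(34)
  cosang <- tcrossprod(u); diag(cosang) <- -1
  min_angle <- acos(max(pmin(cosang, 1)))
  expect_gte(min_angle, 0.7 * sqrt(8 * pi / (sqrt(5) * 34)))
})

test_that("geometry presets and validation behave", {
  g1 <- ellipsoid_geometry(1)
  expect_equal(c(g1$a, g1$b, g1$c), c(4.5, 3.4, 3.3))
  g6 <- ellipsoid_geometry(6)
  expect_equal(c(g6$a, g6$b, g6$c), c(5.0, 4.0, 4.0))
  expect_error(ellipsoid_geometry(7), "model_id")
  expect_error(ellipsoid_geometry(a = 3, b = 4, c = 3), "semiaxes")
})

test_that("monomer templates carry the head-positive/tail-negative contrast", {
  tpl <- monomer_templates()
  expect_length(tpl, 15)
  expect_true(all(c("1-c18", "2-c12") %in% names(tpl)))
  for (t in tpl) {
    f <- t$beads$electrons - 334 * t$beads$volume
    expect_true(all(f[t$beads$role == "tail"] < 0))
    expect_true(all(f[t$beads$role == "head"] > 0))
    expect_gt(t$extent, 0)
  }
  expect_error(monomer_templates("9-c99"), "unknown conformer")
})

test_that("built micelles satisfy their geometric contract", {
  m <- build_micelle(ellipsoid_geometry(6), "1-c18", 35)
  expect_identical(m$n_mol, 35L)
  expect_identical(nrow(m$placements), 35L)
  g <- m$geometry; bd <- m$beads
  # tails inward: each monomer's innermost tail bead closer to the centre
  # than its outermost head bead
  rad <- sqrt(bd$x^2 + bd$y^2 + bd$z^2)
  for (i in unique(bd$monomer)) {
    sel <- bd$monomer == i
    expect_lt(min(rad[sel & bd$role == "tail"]),
              max(rad[sel & bd$role == "head"]))
  }
  # clash threshold honored between different monomers
  d <- as.matrix(dist(cbind(bd$x, bd$y, bd$z)))
  same <- outer(bd$monomer, bd$monomer, "==")
  expect_gte(min(d[!same]), 0.30)
  # envelope: heads hug the surface, tail ends reach the core
  mcoord <- sqrt((bd$x / g$a)^2 + (bd$y / g$b)^2 + (bd$z / g$c)^2)
  head_m <- mcoord[bd$role == "head"]
  expect_gte(mean(head_m >= 0.85 & head_m <= 1.15), 0.95)
  tail_end <- vapply(split(seq_len(nrow(bd)), bd$monomer), function(i) {
    ii <- i[bd$role[i] == "tail"]
    max((mcoord[ii])[which.max(-mcoord[ii])])
  }, 0)
  expect_true(all(tail_end <= 0.6))
})

test_that("single monomer and small builds are clash-free and deterministic", {
  m1 <- build_micelle(ellipsoid_geometry(5), "2-c12", 1)
  expect_identical(m1$n_mol, 1L)
  m22a <- build_micelle(ellipsoid_geometry(5), "1-c18", 22)
  m22b <- build_micelle(ellipsoid_geometry(5), "1-c18", 22)
  expect_identical(m22a$beads, m22b$beads)
  # overall size: max pair distance ~ 2a within one monomer extent
  dmax <- coords_pr(as_bead_scatterer(m22a))$dmax
  ext <- monomer_templates("1-c18")[["1-c18"]]$extent
  expect_gte(dmax, 2 * 4.0 - ext)
  expect_lte(dmax, 2 * 4.0 + ext)
})

test_that("restricted ensembles have the right cardinality and unique ids", {
  ens <- generate_ensemble(model_ids = c(1, 5), sizes = 22,
                           conformers = c("1-c18", "2-c12", "1-c12b"))
  expect_length(ens, 6)
  expect_false(anyDuplicated(names(ens)) > 0)
  expect_true(all(vapply(ens, function(m) m$n_mol == 22L, TRUE)))
})

test_that("uniform fill of an ellipsoid has the analytic radius of gyration", {
  fill <- ellipsoid_bead_fill(4, 3, 3, 0.3)
  b <- bead_scatterer(fill, 1)
  expect_equal(coords_rg(b), sqrt((16 + 9 + 9) / 5), tolerance = 0.03)
})

test_that("PDB export round-trips beads as pseudo-atoms", {
  m <- build_micelle(ellipsoid_geometry(5), "1-c12", 22)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  pdb <- bio3d::read.pdb(path)
  expect_identical(length(unique(pdb$atom$chain)), 22L)
  expect_identical(nrow(pdb$atom), nrow(m$beads))
  xyz_back <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  expect_equal(xyz_back, as.matrix(m$beads[, c("x", "y", "z")]) * 10,
               tolerance = 1e-3, ignore_attr = TRUE)
  # B-factor column carries the per-bead contrast
  f <- m$beads$electrons - 334 * m$beads$volume
  expect_equal(pdb$atom$b, round(f, 2), tolerance = 1e-6)
  empty <- m; empty$beads <- m$beads[0, ]
  expect_error(write_pdb(empty, path), "empty")
})
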