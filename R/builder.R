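#' Quasi-uniform directions from the spherical Fibonacci lattice
#'
#' Generates `n` quasi-homogeneously distributed unit vectors using the
#' golden-angle (Fibonacci) spiral on the sphere.  Any `n >= 1` is
#' accepted; Fibonacci numbers (1, 2, 3, 5, 8, 13, 21, 34, ...) give the
#' most even coverage.  Deterministic.
#'
#' @param n Number of directions, >= 1.
#' @return An `n x 3` matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  k <- seq_len(n) - 1L
  z <- 1 - (2 * k + 1) / n
  golden <- (1 + sqrt(5)) / 2
  phi <- 2 * pi * k / golden
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Ellipsoid geometry presets for the candidate micelles
#'
#' The six preset ellipsoids used to span the plausible micelle shapes:
#' model 1 (4.5/3.4/3.3 nm), 2 (4.5/4.5/3.5), 3 (5.0/3.5/3.5),
#' 4 (5.0/4.5/4.0), 5 (4.0/3.0/3.0) and 6 (5.0/4.0/4.0).
#'
#' @param model_id Integer 1..6, or omit `a`,`b`,`c` to use a preset.
#' @param a,b,c Optional explicit semiaxes, nm (a >= b >= c > 0).
#' @return An object of class `ellipsoid_geometry`.
#' @export
ellipsoid_geometry <- function(model_id = NULL, a = NULL, b = NULL, c = NULL) {
  presets <- list(`1` = c(4.5, 3.4, 3.3), `2` = c(4.5, 4.5, 3.5),
                  `3` = c(5.0, 3.5, 3.5), `4` = c(5.0, 4.5, 4.0),
                  `5` = c(4.0, 3.0, 3.0), `6` = c(5.0, 4.0, 4.0))
  if (is.null(a)) {
    if (is.null(model_id) || !as.character(model_id) %in% names(presets))
      stop("model_id must be 1..6 when semiaxes are not given")
    ax <- presets[[as.character(model_id)]]
  } else {
    ax <- c(a, b, c)
  }
  if (any(ax <= 0) || is.unsorted(rev(ax)))
    stop("semiaxes must satisfy a >= b >= c > 0")
  structure(list(a = ax[1], b = ax[2], c = ax[3],
                 model_id = if (is.null(model_id)) NA_integer_ else model_id),
            class = "ellipsoid_geometry")
}

# ---- monomer bead templates ------------------------------------------------
#
# Bead-level chemistry (contrasts vs water at 334 e/nm^3):
#   POE bead   = 2 ethylene-oxide units: 48 e, 0.123 nm^3  (+7 e net)
#   sorbitan   = ring + linkages:        77 e, 0.200 nm^3  (+10 e net)
#   CH2 pair   = 2 methylenes:           16 e, 0.0538 nm^3 (-2 e net)
#   CH2-CH3    = terminal pair:          17 e, 0.0815 nm^3 (-10 e net)
# Head beads positive, tail beads negative, as required for POE-sorbitan
# esters in water.

.BEADS <- list(
  poe      = c(electrons = 48, volume = 0.1228),
  sorbitan = c(electrons = 77, volume = 0.2000),
  ch2pair  = c(electrons = 16, volume = 0.0538),
  ch2ch3   = c(electrons = 17, volume = 0.0815),
  glucose  = c(electrons = 86, volume = 0.1620)
)

.bead_f <- function(name, solvent = WATER_ELECTRON_DENSITY) {
  b <- .BEADS[[name]]
  unname(b["electrons"] - solvent * b["volume"])
}

# Build one monomer template in its local frame: z axis radial, z = 0 is
# the head end (placed at the ellipsoid surface), tails run to negative z.
# Tails zigzag with tilt angle beta so their axial span never exceeds
# `max_depth` (bent conformers use a smaller max_depth).
.make_template <- function(id, n_tails, carbons, max_depth) {
  deg <- pi / 180
  head <- rbind(
    data.frame(z = 0.00, lat = 0.30, psi = c(0, 120, 240) * deg, bead = "poe"),
    data.frame(z = -0.14, lat = 0.42, psi = c(45, 135, 225, 315) * deg, bead = "poe"),
    data.frame(z = -0.28, lat = 0.30, psi = c(60, 180, 300) * deg, bead = "poe"),
    data.frame(z = -0.40, lat = 0.00, psi = 0, bead = "sorbitan"))
  head$role <- "head"
  nb <- ceiling(carbons / 2)
  span <- 0.25 * (nb - 1)
  cosb <- if (span > 0) min(1, max_depth / span) else 1
  sinb <- sqrt(max(0, 1 - cosb^2))
  tails <- list()
  tail_psi <- if (n_tails == 2) c(0, pi) else 0
  tail_lat0 <- if (n_tails == 2) 0.25 else 0
  for (tj in seq_len(n_tails)) {
    k <- seq_len(nb) - 1L
    z <- -0.60 - 0.25 * k * cosb
    # twin tails taper toward the monomer axis with depth; zigzag keeps
    # the bent-tail lateral footprint small
    lat <- tail_lat0 * pmax(0.2, 1 - k / 4) + (k %% 2) * 0.18 * sinb
    bead <- c(rep("ch2pair", nb - 1L), "ch2ch3")
    tails[[tj]] <- data.frame(z = z, lat = lat, psi = tail_psi[tj],
                              bead = bead, role = "tail")
  }
  beads <- rbind(head, do.call(rbind, tails))
  beads$electrons <- vapply(beads$bead, function(b) unname(.BEADS[[b]]["electrons"]), 0)
  beads$volume <- vapply(beads$bead, function(b) unname(.BEADS[[b]]["volume"]), 0)
  structure(list(conformer_id = id, n_tails = n_tails, tail_carbons = carbons,
                 poe_counts = c(w = 5, x = 5, y = 5, z = 5),
                 beads = beads, extent = max(beads$z) - min(beads$z)),
            class = "monomer_template")
}

#' Monomer conformer templates
#'
#' The 15 shipped surfactant conformers: POE-sorbitan esters with one or
#' two acyl tails of 10-18 carbons, in extended ("1-c18") and bent
#' ("1-c18b") tail arrangements.  Labels follow the
#' `(tail count)-c(carbons per tail)` convention.  Each template is a
#' bead-level model: one bead per 2 CH2 along the tail (0.25 nm spacing),
#' a sorbitan bead and POE beads splayed near the head end, with electron
#' counts and displaced solvent volumes per bead.
#'
#' @param ids Optional character vector to select a subset by label.
#' @return Named list of `monomer_template` objects (15 by default).
#' @export
monomer_templates <- function(ids = NULL) {
  spec <- list(
    c("1-c10", 1, 10, 1.45), c("1-c12", 1, 12, 1.45),
    c("1-c14", 1, 14, 1.45), c("1-c16", 1, 16, 1.45),
    c("1-c18", 1, 18, 1.45),
    c("1-c12b", 1, 12, 1.10), c("1-c14b", 1, 14, 1.10),
    c("1-c16b", 1, 16, 1.10), c("1-c18b", 1, 18, 1.10),
    c("2-c10", 2, 10, 1.45), c("2-c12", 2, 12, 1.45),
    c("2-c14", 2, 14, 1.45), c("2-c18", 2, 18, 1.45),
    c("2-c12b", 2, 12, 1.10), c("2-c18b", 2, 18, 1.10))
  out <- lapply(spec, function(x)
    .make_template(x[[1]], as.integer(x[[2]]), as.integer(x[[3]]),
                   as.numeric(x[[4]])))
  names(out) <- vapply(out, `[[`, "", "conformer_id")
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(out))
    if (length(missing)) stop("unknown conformer(s): ",
                              paste(missing, collapse = ", "))
    out <- out[ids]
  }
  out
}

# deterministic orthonormal frame with e3 = u
.local_frame <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2, e3 = u)
}

# place one template at unit direction u on geometry g; returns bead df
.place_monomer <- function(tpl, u, g, monomer_index) {
  v <- c(g$a * u[1], g$b * u[2], g$c * u[3])   # point on the surface
  r_surf <- sqrt(sum(v^2))
  er <- v / r_surf
  fr <- .local_frame(er)
  bd <- tpl$beads
  # stretch the tail so its end reaches the core even along long semiaxes
  depth <- -min(bd$z)
  gfac <- max(1, 0.42 * r_surf / depth)
  z <- ifelse(bd$role == "tail", bd$z * gfac, bd$z)
  lat <- bd$lat
  xyz <- t(vapply(seq_len(nrow(bd)), function(i) {
    v + z[i] * fr$e3 +
      lat[i] * (cos(bd$psi[i]) * fr$e1 + sin(bd$psi[i]) * fr$e2)
  }, numeric(3)))
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             electrons = bd$electrons, volume = bd$volume,
             role = bd$role, monomer = monomer_index,
             conformer = tpl$conformer_id)
}

.clash_pairs <- function(beads, min_dist) {
  co <- as.matrix(beads[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(co))
  same <- outer(beads$monomer, beads$monomer, "==")
  bad <- which(d < min_dist & !same & upper.tri(d), arr.ind = TRUE)
  bad
}

#' Build a quasiatomistic bead-level micelle
#'
#' Places `n` monomer templates along the spherical Fibonacci directions,
#' mapped to the ellipsoid surface by anisotropic scaling
#' v = (a u_x, b u_y, c u_z).  Each monomer's axis is aligned with the
#' local radial direction, tail pointing inward and head end at the
#' surface.  Bead clashes between different monomers (< `clash_min` nm)
#' are resolved by up to 20 deterministic passes of small angular jitter
#' (golden-ratio sequence, no RNG).
#'
#' @param geom An [ellipsoid_geometry()].
#' @param conformer Conformer label (see [monomer_templates()]) or a
#'   `monomer_template` object; a vector of labels of length `n` assigns
#'   conformers per monomer.
#' @param n Number of monomers, >= 1.
#' @param clash_min Minimum allowed distance between beads of different
#'   monomers, nm.
#' @return An object of class `micelle_model` with fields `beads`
#'   (data.frame with coordinates nm, electrons, volume, role, monomer,
#'   conformer), `n_mol`, `geometry`, `placements`, `provenance`.
#' @export
build_micelle <- function(geom, conformer = "1-c18", n = 35,
                          clash_min = 0.30) {
  stopifnot(inherits(geom, "ellipsoid_geometry"), n >= 1)
  n <- as.integer(n)
  if (inherits(conformer, "monomer_template")) {
    tpls <- rep(list(conformer), n)
    labels <- rep(conformer$conformer_id, n)
  } else {
    labels <- rep(as.character(conformer), length.out = n)
    reg <- monomer_templates(unique(labels))
    tpls <- reg[labels]
  }
  dirs <- fibonacci_directions(n)
  golden <- (1 + sqrt(5)) / 2
  build_all <- function(jit, jphase) {
    pieces <- vector("list", n)
    for (i in seq_len(n)) {
      u <- dirs[i, ]
      if (jit[i] > 0) {
        # deterministic small rotation in a golden-ratio direction whose
        # phase advances with the resolution pass
        ang <- 2 * pi * (((i + jphase[i]) * golden) %% 1)
        fr <- .local_frame(u)
        u <- u + jit[i] * (cos(ang) * fr$e1 + sin(ang) * fr$e2)
        u <- u / sqrt(sum(u^2))
      }
      pieces[[i]] <- .place_monomer(tpls[[i]], u, geom, i)
    }
    do.call(rbind, pieces)
  }
  jit <- numeric(n)
  jphase <- numeric(n)
  beads <- build_all(jit, jphase)
  for (pass in seq_len(20)) {
    bad <- .clash_pairs(beads, clash_min)
    if (nrow(bad) == 0) break
    offenders <- unique(beads$monomer[c(bad[, 1], bad[, 2])])
    jit[offenders] <- jit[offenders] + 0.02
    jphase[offenders] <- jphase[offenders] + pass
    beads <- build_all(jit, jphase)
  }
  bad <- .clash_pairs(beads, clash_min)
  if (nrow(bad) > 0) {
    pr <- unique(t(apply(cbind(beads$monomer[bad[, 1]],
                               beads$monomer[bad[, 2]]), 1, sort)))
    stop("unresolvable clashes between monomers: ",
         paste(apply(pr, 1, paste, collapse = "-"), collapse = ", "))
  }
  rownames(beads) <- NULL
  structure(list(beads = beads, n_mol = n, geometry = geom,
                 placements = data.frame(monomer = seq_len(n),
                                         conformer = labels,
                                         jitter = jit),
                 provenance = list(clash_min = clash_min)),
            class = "micelle_model")
}

#' @export
print.micelle_model <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("micelle: %d monomers (%s), %d beads on ellipsoid %.1f/%.1f/%.1f nm\n",
              x$n_mol, paste(unique(x$placements$conformer), collapse = ","),
              nrow(x$beads), g$a, g$b, g$c))
  invisible(x)
}

#' Generate the full candidate micelle ensemble
#'
#' One model per (geometry, aggregation number, conformer) combination:
#' with the 6 preset geometries, sizes 22 and 35 and the 15 shipped
#' conformers this yields 180 uniquely labelled candidate micelles.
#' Build failures are never silently dropped: an irrecoverable clash
#' aborts naming the failing combination.
#'
#' @param model_ids Geometry preset ids (default 1:6).
#' @param sizes Aggregation numbers (default c(22, 35)).
#' @param conformers Conformer labels (default all 15).
#' @return Named list of `micelle_model` objects; names are
#'   `m<model>_n<size>_<conformer>`.
#' @export
generate_ensemble <- function(model_ids = 1:6, sizes = c(22, 35),
                              conformers = names(monomer_templates())) {
  out <- list()
  for (m in model_ids) {
    g <- ellipsoid_geometry(m)
    for (nn in sizes) for (cf in conformers) {
      id <- sprintf("m%d_n%d_%s", m, nn, cf)
      out[[id]] <- tryCatch(build_micelle(g, cf, nn),
                            error = function(e)
                              stop("ensemble build failed for ", id, ": ",
                                   conditionMessage(e)))
    }
  }
  out
}

#' Write a bead model as a pseudo-atom PDB file
#'
#' One HETATM per bead, one chain per monomer, coordinates in Angstrom
#' (nm x 10).  The per-bead effective contrast (electrons minus displaced
#' solvent) is stored in the B-factor column -- a documented convention so
#' models round-trip through standard PDB readers.  Files with more than
#' 99,999 atoms fall back to wrapped serial numbers with a warning.
#'
#' @param model A `micelle_model`.
#' @param path Output path.
#' @param solvent_density Solvent electron density for the B-factor
#'   contrast, e/nm^3.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path, solvent_density = WATER_ELECTRON_DENSITY) {
  stopifnot(inherits(model, "micelle_model"))
  bd <- model$beads
  if (nrow(bd) == 0) stop("empty model")
  natoms <- nrow(bd)
  if (natoms > 99999) warning("more than 99,999 beads: serial numbers wrap")
  chains <- c(LETTERS, letters, 0:9)
  f_eff <- bd$electrons - solvent_density * bd$volume
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(bd[, c("x", "y", "z")]) * 10)),
                   type = rep("HETATM", natoms),
                   resno = bd$monomer,
                   resid = ifelse(bd$role == "head", "HED", "TAL"),
                   eleno = ((seq_len(natoms) - 1L) %% 99999L) + 1L,
                   elety = ifelse(bd$role == "head", "O", "C"),
                   chain = chains[((bd$monomer - 1L) %% length(chains)) + 1L],
                   o = rep(1, natoms),
                   b = round(f_eff, 2))
  invisible(path)
}

#' Fill an ellipsoid with a uniform bead lattice
#'
#' Control body for scattering cross-checks: beads on a cubic lattice
#' inside the ellipsoid (x/a)^2 + (y/b)^2 + (z/c)^2 <= 1, all with equal
#' weight.
#'
#' @param a,b,c Semiaxes, nm.
#' @param spacing Lattice spacing, nm.
#' @return Matrix of bead coordinates (nm).
#' @export
ellipsoid_bead_fill <- function(a, b, c, spacing = 0.3) {
  gx <- seq(-a, a, by = spacing)
  gy <- seq(-b, b, by = spacing)
  gz <- seq(-c, c, by = spacing)
  gr <- expand.grid(x = gx, y = gy, z = gz)
  inside <- (gr$x / a)^2 + (gr$y / b)^2 + (gr$z / c)^2 <= 1
  as.matrix(gr[inside, ])
}

#' Reference DDM micelle bead model
#'
#' n-dodecyl-beta-maltoside micelle: 174 monomers on an ellipsoid with
#' semiaxes 4.0/3.0/3.0 nm (MW = 174 x 510.6 Da ~ 89 kDa).  Each monomer
#' is a two-bead maltoside head (glucose rings, strongly positive
#' contrast) over a C12 tail.  Tail beads of neighbouring monomers
#' interdigitate in the crowded core, so the clash threshold is relaxed
#' to 0.15 nm.
#'
#' @param n Number of monomers (default 174).
#' @return A `micelle_model`.
#' @export
ddm_micelle <- function(n = 174) {
  deg <- pi / 180
  # semiaxes describe the full micelle envelope incl. the hydration
  # fringe; the maltoside ring centres sit ~0.4-0.8 nm below it and the
  # C12 tail is slightly coiled (0.21 nm effective spacing)
  head <- data.frame(z = c(-0.45, -0.80), lat = c(0.15, 0.15),
                     psi = c(0, 180) * deg, bead = "glucose", role = "head")
  nb <- 6L
  k <- seq_len(nb) - 1L
  tail <- data.frame(z = -1.05 - 0.21 * k, lat = (k %% 2) * 0.08, psi = 0,
                     bead = c(rep("ch2pair", nb - 1L), "ch2ch3"),
                     role = "tail")
  beads <- rbind(head, tail)
  beads$electrons <- vapply(beads$bead, function(b) unname(.BEADS[[b]]["electrons"]), 0)
  beads$volume <- vapply(beads$bead, function(b) unname(.BEADS[[b]]["volume"]), 0)
  tpl <- structure(list(conformer_id = "ddm-c12", n_tails = 1L,
                        tail_carbons = 12L, poe_counts = c(w = 0, x = 0, y = 0, z = 0),
                        beads = beads, extent = max(beads$z) - min(beads$z)),
                   class = "monomer_template")
  build_micelle(ellipsoid_geometry(a = 4, b = 3, c = 3), tpl, n,
                clash_min = 0.15)
}
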