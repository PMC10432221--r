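# micellesaxs

Analysis of small-angle X-ray scattering (SAXS) from surfactant
micelles — polysorbate 20 (PS20), its monolaurate (F2) and higher-order
ester (F4) fractions, and reference detergents such as DDM — including
the response of micelle size to incorporated fatty acids.

The package implements two complementary modeling routes plus the
model-free groundwork, all validated against synthetic data with known
truth:

* **Model-free analysis** — Guinier fits (`I(s) ≈ I0 exp(−s²Rg²/3)`),
  a Tikhonov-regularized indirect Fourier transform for the pair
  distance distribution `P(r)` with `Dmax` selection, Shannon channel
  counts `⌊s_max·Dmax/π⌋`, and aggregation numbers from forward
  scattering.
* **Core-shell ellipsoid modeling** — the micelle as a polydisperse
  core-shell ellipsoid of revolution with outer semiaxes `(a, a, b)`,
  shell thickness `t`, Gaussian size dispersion `dR_ell`, and core/shell
  contrasts `ρ_in < 0 < ρ_out` (e/nm³ vs water, 334 e/nm³):

      A(s, µ) = ρ_out·V_o·Φ(s·r_o(µ)) + (ρ_in − ρ_out)·V_i·Φ(s·r_i(µ)),
      I(s)    = scale · ∫₀¹ A² dµ,   Φ(x) = 3(sin x − x cos x)/x³

  with bounded multi-start least-squares fitting and fitting-interval
  sweep uncertainties.
* **Quasiatomistic modeling** — bead-level micelles built by placing
  monomer conformers along spherical-Fibonacci directions on preset
  ellipsoids (6 geometries × sizes {22, 35} × 15 conformers = a
  180-model candidate ensemble), Debye-equation scattering
  `I(s) = Σᵢⱼ fᵢfⱼ sin(s·rᵢⱼ)/(s·rᵢⱼ)`, and non-negative least-squares
  decomposition of a measured curve into candidate volume fractions
  with sweep-based selection of systematically nonzero components.
* **Synthetic data** — curves with counting-like heteroscedastic noise
  generated from any model (including the published best-fit parameter
  sets, shipped as `micelle_fixture()` entries, and a fatty-acid
  titration scenario), each carrying its ground truth.

See `vignettes/micelle-saxs-methods.Rmd` for the model assumptions,
parameter conventions, numerical choices and known limitations.

## Worked example

```r
library(micellesaxs)

p   <- micelle_fixture("table2_ps20")   # published PS20 best-fit geometry
cv  <- simulate_curve(p, seed = 1)      # 291-point curve, ~2% noise at s = 1
pa  <- primary_analysis(cv)
fit <- fit_coreshell(cv, init = p, n_starts = 2)
fit <- fit_uncertainty_sweep(cv, fit)
print(pa); print(fit)
```

```
primary analysis: Rg 3.337 nm, Dmax 8.34 nm, I0 0.05394, N_shannon 7
core-shell fit (relative contrast scale)
core-shell ellipsoid: a = 3.683 nm, b = 2.450 nm, t = 0.875 nm, dR = 0.369 nm
  contrasts: core -0.5799, shell 1 e/nm^3 (ratio -0.580); scale 1.662e-05
  chi2_red = 0.9446 over s = 0.1..3 nm^-1; 2 start(s) converged
  sweep SD: a_out 0.0178, b_out 0.000831, t 0.0336, d_rell 0.00361, ratio 0.0367
```

Reading the numbers: the model-free stage recovers the Guinier radius
(3.34 nm) and maximum dimension (8.3 nm) of the simulated PS20 micelle;
the blind refit lands on the generating geometry (truth: a 3.68, b 2.46,
t 0.88, dR 0.37 nm) within the sweep uncertainties, and the recovered
contrast ratio −0.58 is the physical tail/head contrast ratio (≈ −0.55)
— absolute contrasts are only defined on a relative scale, so the shell
contrast is reported as 1.

Bead-level candidates and mixture decomposition:

```r
ens   <- generate_ensemble()                      # 180 models
cands <- candidate_set_from_models(ens, seq(0.1, 3, length.out = 146))
mix   <- select_models(cands, cv)                 # sweep-based NNLS
write_pdb(ens[["m6_n35_1-c18"]], "micelle.pdb")   # pseudo-atom export
```

A thin command-line wrapper over these functions is installed at
`inst/scripts/micellesaxs` (subcommands `primary`, `fit-coreshell`,
`build`, `scatter`, `simulate`, `run`).

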