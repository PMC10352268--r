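---
title: "Quantifying T1 contrast agents at 64 mT: models, simulation and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying T1 contrast agents at 64 mT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfrelax)
```

## The problem

Point-of-care MRI scanners operating at 64 mT have renewed interest in
contrast agents optimized for low field. Superparamagnetic iron oxide
nanoparticles (SPIONs), which act as negative (T2) agents at clinical
fields, become strong positive (T1) agents at 64 mT: their longitudinal
relaxivity r1 can exceed that of a clinical Gd chelate by nearly an order of
magnitude while the figure of merit r2/r1 stays near 1. `lfrelax`
implements the full quantitative chain used to establish such claims —
phantom imaging, voxelwise relaxometry, relaxivity regression, SQUID-style
magnetometry, and fast-field-cycling dispersion (NMRD) analysis — together
with a synthetic-data generator that stands in for the physical phantom,
magnetometer and relaxometer. Every fitting module can therefore be
validated by round-trip against known ground truth.

## The agent panel

`build_default_agents()` returns seven agents: four monodisperse carboxylic
acid-coated SPIONs with core diameters 4.9, 8.5, 12.9 and 15.7 nm, two
clustered therapeutic formulations (ferumoxytol, ferumoxides) and the Gd
chelate Gd-BOPTA. Their stored mass saturation magnetizations (40.3-95.7
A m²/kg) and relaxivities at 0.064 T and 3 T are the measured study values
and serve as simulation ground truth; e.g. the 15.7 nm sample carries
r1 = 67.0 L mmol⁻¹ s⁻¹ at 64 mT against 7.7 for the chelate.

Two generator parameters are *not* measured quantities and were chosen
once:

* **Per-particle magnetic moments.** The supplementary magnetic diameters
  were not available, so moments are calibrated so that every SPION sits at
  40-50% of its saturation magnetization at 64 mT and 294.65 K — the
  qualitative magnetometry observation that underlies the low-field r1
  enhancement. This puts all moments near 1e-19 J/T (magnetic diameters
  7-8 nm at magnetite volumetric magnetization).
* **Effective cluster diameters for ferumoxytol/ferumoxides.** TEM cannot
  resolve individual cores in these multi-core agents, so no measured core
  diameter exists; synthetic effective values of 6.0 and 5.5 nm are used
  where a diameter is required (dispersion modelling, moment bookkeeping).

Neel correlation times grow with core size over 1-20 ns, the range typical
of magnetite cores below 20 nm.

## Signal models and voxelwise mapping

Inversion recovery: `S = S0 |1 − (1+d) e^(−TI/T1) + e^(−TR/T1)|`, with `d`
the inversion scale factor; echo decay: `S = S0 e^(−TE/T2)`. The magnitude
(absolute-value) model is fitted directly rather than after polarity
restoration, because magnitude images are what the scanner exports. The
64 mT protocols use the fifteen inversion times 100-2500 ms (TR 3000 ms)
and ten echo times 37-702 ms; the 3 T protocols use eleven inversion times
50-6000 ms (TR 10 s) and five echo times 14-224 ms.

Numerical choices for `fit_t1_voxel()`/`fit_t2_voxel()`:

* bounded Levenberg-Marquardt (`minpack.lm`), T1 ∈ [1 ms, 20 s],
  T2 ∈ [1 ms, 5 s], d ∈ [0, 1.2];
* the magnitude IR model has a null-point local minimum, so the optimizer
  is started from a coarse T1 grid {50, 200, 800, 2000} ms and the lowest
  residual wins; when the per-series noise level is known, the start loop
  exits early once the residual reaches the noise floor;
* T2 fits start from the log-linear regression of log S on TE, which is
  already exact on noiseless data;
* degenerate voxels (constant signal) are flagged `converged = FALSE` with
  `T = NA`, never silently assigned a value; all-zero voxels are an error
  at the single-voxel level and are skipped (flagged) during map
  construction;
* `map_volume()` masks voxels whose maximum signal is below 5× the noise
  floor; with zero recorded noise everything with signal is fitted.

Whether the study fixed d = 1 or fitted it per voxel is not documented;
both are supported and fitting d is the default (`fit_d = FALSE` fixes
it).

## Phantom simulation

Tubes are circles on an axial slice replicated across slices, each holding
one agent at one nominal concentration of the dilution series 0, 0.03,
0.06, 0.12, 0.25, 0.5, 1 mmol/L metal; the 3 T series omits the blank
(its holder has one fewer slot). Per-voxel rates come from the linear
model `1/T = 1/T′ + r·[CM]`, with the agarose background rates defaulting
to R1′ = 0.35 s⁻¹ and R2′ = 1.5 s⁻¹ — placeholders in the absence of
published blank-gel values, configurable throughout. Nominal
concentrations are rescaled by each agent's assayed/nominal stock ratio
(0.91-1.02 by default) before rates are computed, emulating the
ICP-OES-based concentration correction.

Noise is Rician — two independent Gaussian channels combined in magnitude
— with SD expressed as a fraction of S0 (0.02 = SNR 50). This is the
standard magnitude-MRI noise model; it is not a k-space simulation and
carries no echo-train, coil-sensitivity or distortion effects, so passing
round-trip tests demonstrates estimator correctness, not robustness to
scanner artifacts.

The default geometry (32×32×1 grid, tube radius 4 voxels, ~49-voxel ROIs)
is a desk-scale stand-in for 50 mL tubes, which would span ~18 voxels
across at the 1.6 mm in-plane resolution; the tube median over the
converged voxels is the per-concentration summary statistic (robust to
stray non-converged voxels at ROI edges).

## Relaxivity estimation and the exclusion rule

Relaxivities are ordinary least-squares slopes of rate versus assayed
concentration (`fit_relaxivity()`); the intercept estimates the background
rate. No weighting is applied by default (a weighted option using rate SEs
exists). An inversion-recovery protocol cannot measure T1 below its first
inversion time, so concentrations whose fitted T1 falls below it (100 ms
at 64 mT, 50 ms at 3 T — read from the protocol, not hard-coded) are
excluded, and the exclusion propagates to all four (field × channel) fits
of that agent so every regression uses identical concentrations.
Non-converged tube fits are likewise excluded, with their own reason
string. Under the default panel and background rates this rule removes 11
of the 42 agent-concentration datasets, all at high concentration for the
strongly relaxing agents.

Reported tables round half-up to 1 decimal; derived ratios
(`relaxivity_ratio()`, `fold_enhancement()`) are always computed from
unrounded fits and rounded only for display.

## Langevin magnetometry

`M(B) = Ms·L(μB/k_BT)` with `L(x) = coth x − 1/x` (Taylor series below
|x| = 1e-5 for stability). `fit_langevin()` estimates (Ms, μ) by least
squares, starting from the curve maximum and the low-field slope
`Ms·μ/3k_BT`; the effective magnetic diameter is
`d = (6μ/π M_vol)^(1/3)` using magnetite density 5180 kg/m³ to convert
mass to volumetric magnetization (configurable — the conversion density is
not a measured quantity). Only a single-population Langevin is fitted; no
moment-distribution (log-normal) model, and no hysteresis/ZFC-FC analysis
since superparamagnetic particles show zero remanence. Ms uncertainty from
a measured moment and metal content combines both relative errors in
quadrature (`propagate_ms_error()`).

## Dispersion (NMRD) models

The superparamagnetic forward model `spm_r1()` sums three outer-sphere
contributions weighted by the Langevin alignment `L(x)`,
`x = μB0/k_BT`:

* a **Curie term** `3 L² J_A(ω, τ_D)` from the static thermally averaged
  moment, dispersed only by translational diffusion (Ayant spectral
  density). Its rise with field followed by the diffusion cutoff at
  `ω τ_D ≈ 1` produces the characteristic peak at a few MHz;
* a transverse fluctuating-moment term
  `c_f (1 − L² − 2L/x) J_F(ω, τ_D, τ_N)` (Freed spectral density with
  finite Neel time);
* a longitudinal fluctuation term `c_t (2L/x) J_F(ω, τ_D, τ_N)`.

Default weights are `c_f = 3`, `c_t = 7/2`; the exact stoichiometric
constants of the heuristic model vary across the literature, so they are
exposed as parameters and all validation of this module is structural
(zero-frequency limits to 1e-12 against independent complex-arithmetic
oracles, peak locations, monotone peak shifts, round-trip parameter
recovery) rather than literature-constant-exact. The `x → 0` limits
(`L² → 0`, `2L/x → 2/3`) are evaluated analytically, so the model is
smooth through zero field. The amplitude is proportional to `1/(d·D)` —
the outer-sphere encounter-rate scaling — normalized at d = 10 nm,
D = 2.3e-9 m²/s, with all remaining prefactors absorbed into the fitted
`K_scale`. `τ_D = d²/D` is always derived, never stored.

With the default panel (D = 2.3e-9 m²/s, water at room temperature) the
model peaks fall at 6.7, 4.1 and 2.3 MHz for the 8.5, 12.9 and 15.7 nm
cores — inside the observed 2-10 MHz band and decreasing with diameter.
A caveat worth stating: the peak frequency does *not* scale exactly as
1/τ_D ∝ 1/d², because the Langevin-alignment rise (a pure function of
frequency through `x`) pins the low-frequency side of the peak; strict
1/d² scaling would hold only if that weight were frequency-flat. The peak
shift with size is therefore monotone but sub-quadratic.

Gd chelates are fitted with Solomon-Bloembergen-Morgan theory (`sbm_r1()`):
inner-sphere `r1 = (q/55500)/(T_1M + τ_M)` with the standard dipolar
`1/T_1M` (correlation rates combining rotation, exchange and electron
relaxation from a transient zero-field splitting `(Δ², τ_V)`),
`ω_S = 658.2 ω_I`, S = 7/2, plus a Freed outer-sphere term. Defaults
(q = 1, r = 3.1 Å, τ_R = 90 ps, τ_M = 150 ns, τ_V = 25 ps,
Δ² = 4e19 s⁻²) give a low-field plateau near 8 L mmol⁻¹ s⁻¹ with the
usual dispersion steps, appropriate for a small Gd chelate at room
temperature.

`fit_nmrd()` performs weighted least squares with the instrument error
model (±1% relative, the stated rate accuracy of fast-field-cycling
relaxometry) on log-scale free parameters (d, τ_N, K for the SPM model;
τ_R, τ_V, Δ² for SBM), holding everything else frozen — in particular D,
which the analysis freezes at the bulk-water value for the measurement
temperature since fitting it against d is degenerate through τ_D.
Frequency grids are log-spaced over the instrument range 0.01-40 MHz.
Each temperature is fitted independently (no Arrhenius coupling).
`r1_at_field(fit, 0.064)` interpolates the fitted curve at the 64 mT
proton Larmor frequency, 2.72 MHz. `predict_diffusion_dependence()`
recomputes profiles across media (CSF to grey matter, roughly 3e-9 down
to 0.7e-9 m²/s): slower diffusion raises low-frequency r1 (the 1/D
amplitude) and shifts the peak down (growing τ_D).

## Pipeline, reproducibility and problem sizes

`run_pipeline()` executes magnetometry → phantom relaxivity →
NMRD → report from a single YAML config (see
`inst/extdata/default_config.yaml`), writes CSV tables shaped like the
study's summary tables, a markdown report and a `manifest.json` with the
config hash and per-file checksums; identical config and seed reproduce
identical checksums. All randomness is seeded: protocol seeds are derived
deterministically from the config seed.

Default problem sizes were chosen so the full study runs in well under a
minute on one CPU: 32×32 single-slice phantoms (≈1000 voxel fits per
series), 71-point magnetization curves over 0-7 T, 32-point dispersion
profiles, 25-50 Monte-Carlo repeats where a sampling distribution is
needed. At these sizes the end-to-end SNR-50 study recovers all fourteen
generator r1 values (7 agents × 2 fields) within a few percent.

```{r example, eval = FALSE}
cfg <- system.file("extdata", "default_config.yaml", package = "lfrelax")
res <- run_pipeline(cfg, output = tempfile("lfrelax"))
res$relaxivity$tables[["0.064"]]
```

## Known limitations

* The agarose background rates and the Gd magnetometry slope are
  placeholders, not measurements; all results that depend on them
  (notably the exclusion-rule count) are conditional on those defaults.
* The Rician generator reproduces magnitude-noise statistics only; no
  FSE echo-train blurring, B1/B0 inhomogeneity, registration error or
  partial-volume effects, so recovery tests bound estimator error, not
  total experimental error.
* The SPM weight constants are a documented transcription choice; fitted
  `K_scale` absorbs any global constant mismatch, so amplitudes are
  comparable only within a fixed weight convention.
* Multi-core agents (ferumoxytol) violate the isolated-particle assumption
  of both the Langevin and dispersion models; the single-population fits
  are effective-parameter descriptions.
* No r2/T2 dispersion modelling (transverse relaxivity is measured only by
  imaging) and no interacting-particle corrections.
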