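# lfrelax

Quantitative characterization of MRI contrast agents for low-field
(64 mT) imaging: phantom relaxometry, relaxivity estimation, Langevin
magnetometry and NMRD dispersion modelling, with a seeded synthetic-data
generator standing in for the scanner, magnetometer and fast-field-cycling
relaxometer.

## Who this is for

Physicists and imaging scientists evaluating positive T1 contrast agents
for point-of-care low-field MRI. Superparamagnetic iron oxide nanoparticles
(SPIONs) — negative agents at 1.5-3 T — develop longitudinal relaxivities
up to 67 L mmol⁻¹ s⁻¹ at 64 mT, roughly 9× a clinical Gd chelate, while
keeping r2/r1 ≈ 1. The package implements the analysis chain that
quantifies these properties and validates every estimator by round-trip
against known ground truth.

## The models at the core

* **Relaxivity** (per field, per channel): `1/T_{1,2} = 1/T'_{1,2} +
  r_{1,2}·[CM]`; `r` is the OLS slope of rate versus assayed metal
  concentration. Concentrations whose fitted T1 falls below the first
  inversion time of the protocol are excluded and the exclusion propagates
  to all four field × channel fits of that agent.
* **Voxelwise mapping**: magnitude inversion recovery
  `S = S0|1 − (1+d)e^(−TI/T1) + e^(−TR/T1)|` and echo decay
  `S = S0 e^(−TE/T2)`, fitted by bounded Levenberg-Marquardt with
  grid-started T1 to avoid the null-point local minimum.
* **Magnetometry**: single Langevin `M(B) = Ms·L(μB/k_BT)`,
  `L(x) = coth x − 1/x`; magnetic diameter `d = (6μ/π M_vol)^{1/3}`.
* **NMRD**: heuristic superparamagnetic model — Curie term
  `3L²·J_Ayant(ω τ_D)` plus Neel-modulated Freed terms, `τ_D = d²/D` —
  and Solomon-Bloembergen-Morgan theory for Gd chelates; r1 at 64 mT is
  read off the fitted curve at 2.72 MHz.

## Worked example

Simulate a 15.7 nm SPION dilution phantom at 64 mT with SNR 50, map T1
voxel by voxel, and summarize the tube ROIs:

```r
library(lfrelax)
agents   <- build_default_agents()
layout   <- default_phantom_layout("D", concs = c(0, 0.06, 0.25))
protocol <- default_protocol(0.064, "inversion_recovery",
                             noise_sigma = 0.02, seed = 42)
series   <- simulate_phantom_series(layout, protocol, agents)
t1_map   <- map_volume(series)
tube_relaxation_table(t1_map, layout)
#>   agent conc    T_ms mean_ms   sd_ms  n
#> 1     D 0.00 2875.67 2551.95 798.466 49
#> 2     D 0.06  233.86  234.86   8.211 49
#> 3     D 0.25   58.62   61.69   7.336 49
```

The blank tube recovers the agarose background (true T1 = 1/0.35 s⁻¹ =
2857 ms); at 0.06 mmol/L the true T1 is 234 ms — the tube median lands
within 1%. Derived metrics come straight from the fitted slopes:

```r
round_half_up(fold_enhancement(67.0, 7.7), 1)   # r1 vs Gd-BOPTA at 64 mT
#> [1] 8.7
p <- spm_params_for_agent(agents$D)
spm_peak_frequency(p)                            # dispersion peak, MHz
#> [1] 2.29
spm_r1(larmor_frequency(0.064), p)               # r1 at 64 mT from the model
#> [1] 61.5
```

The full seven-agent study (both fields, both channels, magnetometry and
dispersion fits, CSV/markdown report, checksummed manifest) runs from one
config file:

```r
cfg <- system.file("extdata", "default_config.yaml", package = "lfrelax")
res <- run_pipeline(cfg, output = "lfrelax_out")
```

A thin CLI wrapper with `run-all`, `simulate-*` and `map` subcommands is
installed at `inst/cli/lfrelax.R`.

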