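Package: lfrelax
Title: Low-Field MRI Relaxometry and Contrast-Agent Biophysics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative characterization of MRI contrast agents for
    low-field (64 mT) imaging. Simulates multi-tube phantom image series,
    magnetization curves and nuclear magnetic resonance dispersion (NMRD)
    profiles from ground-truth agent specifications; fits voxelwise T1 and
    T2 parametric maps from inversion-recovery and echo-decay series;
    estimates longitudinal and transverse relaxivities with a
    first-inversion-time exclusion rule and concentration rescaling;
    performs Langevin magnetometry analysis (saturation magnetization,
    magnetic diameter, saturation fraction); and models r1 dispersion
    profiles with a heuristic superparamagnetic outer-sphere model
    (Freed and Ayant spectral densities) and Solomon-Bloembergen-Morgan
    theory for Gd chelates, including interpolation of r1 at 64 mT and
    diffusion-medium predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
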