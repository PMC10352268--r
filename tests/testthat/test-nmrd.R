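test_that("Larmor frequency conversions are exact", {
  expect_equal(round_half_up(larmor_frequency(0.064), 2), 2.72)
  expect_equal(larmor_frequency(0), 0)
  expect_equal(larmor_frequency(3), 127.732434)
  expect_equal(field_at_frequency(larmor_frequency(0.7)), 0.7,
               tolerance = 1e-12)
})

test_that("diffusion correlation time is d^2/D", {
  expect_equal(tau_d(15.7, 2.3e-9), (15.7e-9)^2 / 2.3e-9)
  expect_equal(tau_d(15.7, 2.3e-9), 1.07e-7, tolerance = 0.01)
  expect_equal(tau_d(10, 1e-9) / tau_d(5, 1e-9), 4)
  expect_equal(tau_d(5, 2e-9) / tau_d(5, 1e-9), 0.5)
})

test_that("Freed spectral density matches a direct complex-arithmetic oracle", {
  expect_equal(freed_spectral_density(0, 1e-7, Inf), 1)
  expect_lt(freed_spectral_density(1e12, 1e-7, Inf), 1e-4)
  tD <- 1e-7; tN <- 1e-6
  omega <- 1 / tD          # omega tau_D = 1, tau_D/tau_N = 0.1
  z <- exp(0.5 * log(complex(real = 0.1, imaginary = 1)))
  oracle <- Re((1 + 0.25 * z) / (1 + z + (4 / 9) * z * z + (1 / 9) * z^3))
  expect_equal(freed_spectral_density(omega, tD, tN), oracle,
               tolerance = 1e-12)
})

test_that("Ayant spectral density has the exact rational values and decays", {
  expect_equal(ayant_spectral_density(0, 1e-7), 1)
  tD <- 3e-8
  omega_u1 <- 1 / (2 * tD)       # u = sqrt(2 omega tau_D) = 1
  expect_equal(ayant_spectral_density(omega_u1, tD), 1134 / 1769,
               tolerance = 1e-12)
  grid <- 10^seq(3, 10, length.out = 40)
  expect_true(all(diff(ayant_spectral_density(grid, tD)) < 0))
})

test_that("superparamagnetic dispersion peaks lie at 2-10 MHz and move down with size", {
  peaks <- vapply(c("A", "B", "C", "D"), function(nm) {
    spm_peak_frequency(spm_params_for_agent(default_panel[[nm]]))
  }, numeric(1))
  # the three larger cores produce in-range peaks
  expect_true(all(peaks[c("B", "C", "D")] >= 2 & peaks[c("B", "C", "D")] <= 10))
  expect_true(all(diff(peaks) < 0))   # larger diameter -> lower peak
})

test_that("spm weight partition is finite and has the correct zero-field limits", {
  p <- spm_params(d_nm = 12, tau_N = 1e-8, mu = 1e-19, K_scale = 1)
  expect_equal(spm_r1(1:10, spm_params(d_nm = 12, K_scale = 0)), rep(0, 10))
  # at x -> 0 the three weights tend to (0, 1/3, 2/3); at omega ~ 0 the
  # Curie term vanishes and the Freed terms carry J_F(0) = f(tau_D/tau_N)
  lo <- spm_r1(1e-9, p) / (p$K_scale * (10 / p$d_nm))
  z0 <- sqrt(tau_d(12, 2.3e-9) / 1e-8)
  jf0 <- (1 + z0 / 4) / (1 + z0 + 4 * z0^2 / 9 + z0^3 / 9)
  expect_equal(lo, (3 / 3 + 2 * 3.5 / 3) * jf0, tolerance = 1e-4)
  wide <- spm_r1(10^seq(-6, 3, length.out = 200), p)
  expect_true(all(is.finite(wide)) && all(wide >= 0))
})

test_that("SBM low-field plateau matches the hand-evaluated omega -> 0 limit", {
  p <- sbm_params()
  expect_equal(sbm_r1(c(0.01, 1, 40),
                      sbm_params(q = 0, os_amplitude = 0)), rep(0, 3))
  kB <- 1.380649e-23; mu0 <- 4e-7 * pi; muB <- 9.2740100783e-24
  gI <- 2.6752218744e8; g <- 2; NA_ <- 6.02214076e23
  f <- p$delta2 * (4 * p$S * (p$S + 1) - 3) / 25
  R1e0 <- 5 * f * p$tau_V
  tc0 <- 1 / (1 / p$tau_R + 1 / p$tau_M + R1e0)
  Kdd <- (2 / 15) * (mu0 / (4 * pi))^2 * gI^2 * g^2 * muB^2 *
    p$S * (p$S + 1) / p$r_GdH^6
  r1_is0 <- (p$q / 55500) / (1 / (Kdd * 10 * tc0) + p$tau_M)
  tD <- p$d_OS^2 / p$D
  z <- sqrt(tD * R1e0)
  J0 <- (1 + z / 4) / (1 + z + 4 * z^2 / 9 + z^3 / 9)
  Kos <- (32 * pi / 405) * (mu0 / (4 * pi))^2 * gI^2 * g^2 * muB^2 *
    p$S * (p$S + 1) * NA_ / (p$d_OS * p$D)
  plateau <- r1_is0 + Kos * 10 * J0
  expect_equal(sbm_r1(1e-9, p), plateau, tolerance = 1e-9)
  # fast exchange: dispersion steps are non-increasing across the grid
  r <- sbm_r1(nmrd_frequency_grid(64), sbm_params(tau_M = 1e-8))
  expect_true(all(diff(r) <= 1e-9))
})

test_that("background subtraction and normalization invert the forward model", {
  freqs <- nmrd_frequency_grid(16)
  blank <- 0.3 + 0.01 * log(freqs + 1)
  p <- spm_params_for_agent(default_panel$B)
  conc <- 0.98
  sample_rates <- blank + conc * spm_r1(freqs, p)
  prof <- subtract_background_normalize(freqs, sample_rates, blank, conc)
  expect_equal(prof$r1, spm_r1(freqs, p), tolerance = 1e-12)
  zero <- subtract_background_normalize(freqs, blank, blank, 1)
  expect_equal(zero$r1, rep(0, 16))
  half <- subtract_background_normalize(freqs, sample_rates, blank, 2 * conc)
  expect_equal(half$r1, prof$r1 / 2)
  expect_error(subtract_background_normalize(freqs, sample_rates[-1], blank, 1),
               "grids")
  expect_error(subtract_background_normalize(freqs, sample_rates, blank, 0),
               "positive")
})

test_that("dispersion fits round-trip generator parameters", {
  p <- spm_params_for_agent(default_panel$D)
  prof <- simulate_nmrd_profile("spm", p, rel_noise = 0)
  init <- p; init$d_nm <- p$d_nm * 1.5; init$K_scale <- p$K_scale * 0.7
  fit <- fit_nmrd(prof, "spm", init)
  expect_true(fit$converged)
  expect_equal(fit$params$d_nm, p$d_nm, tolerance = 0.01 * p$d_nm)
  expect_equal(fit$params$tau_N, p$tau_N, tolerance = 0.01 * p$tau_N)
  expect_equal(fit$params$K_scale, p$K_scale, tolerance = 0.01 * p$K_scale)
  expect_error(fit_nmrd(nmrd_profile(1:6, rep(1, 6)), "spm", p), "decade|>= 8")
})

test_that("median fitted core diameter stays within 10% at 1% noise (50 repeats)", {
  p <- spm_params_for_agent(default_panel$C)
  init <- p; init$d_nm <- p$d_nm * 1.4; init$K_scale <- p$K_scale * 0.8
  d_fits <- vapply(seq_len(50), function(i) {
    prof <- simulate_nmrd_profile("spm", p, rel_noise = 0.01, seed = 900 + i)
    fit_nmrd(prof, "spm", init)$params$d_nm
  }, numeric(1))
  expect_lt(abs(stats::median(d_fits) - p$d_nm) / p$d_nm, 0.10)
})

test_that("the mismatched model leaves a much larger residual", {
  prof <- simulate_nmrd_profile("sbm", sbm_params(), rel_noise = 0)
  good <- fit_nmrd(prof, "sbm",
                   { q <- sbm_params(); q$tau_R <- q$tau_R * 1.3; q })
  bad <- suppressWarnings(fit_nmrd(prof, "spm",
                                   spm_params(d_nm = 10, K_scale = 5)))
  expect_gt(bad$rss, 10 * good$rss)
})

test_that("r1 interpolation at 64 mT evaluates the fitted curve at 2.72 MHz", {
  p <- spm_params_for_agent(default_panel$D)
  prof <- simulate_nmrd_profile("spm", p, rel_noise = 0)
  fit <- fit_nmrd(prof, "spm", p)
  expect_equal(r1_at_field(fit, 0.064),
               spm_r1(larmor_frequency(0.064), fit$params))
  # generator truth: K_scale calibrated so r1(2.72 MHz) is the 21.5 C value
  expect_equal(r1_at_field(fit, 0.064), 61.5, tolerance = 0.01 * 61.5)
  grid_freq <- prof$freq_MHz[12]
  expect_equal(r1_at_field(fit, field_at_frequency(grid_freq)),
               fit$fitted[12], tolerance = 1e-9)
})

test_that("slower diffusion media raise low-frequency r1 and lower the peak", {
  p <- spm_params_for_agent(default_panel$ferumoxytol)
  Ds <- c(3.0e-9, 2.3e-9, 1.0e-9, 0.7e-9)   # CSF to grey matter scale
  fam <- predict_diffusion_dependence(p, Ds)
  r1_low <- vapply(fam, function(df) df$r1[df$freq_MHz == min(df$freq_MHz)],
                   numeric(1))
  expect_true(all(diff(r1_low) > 0))   # r1 non-increasing in D
  peaks <- vapply(Ds, function(D) {
    pd <- p; pd$D <- D; spm_peak_frequency(pd)
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))    # tau_D = d^2/D grows, peak moves down
  same <- predict_diffusion_dependence(p, p$D)[[1]]
  expect_equal(same$r1, spm_r1(same$freq_MHz, p))
})
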