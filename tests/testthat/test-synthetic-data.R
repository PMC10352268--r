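test_that("default agent panel matches the measured structural/relaxometric properties", {
  ag <- default_panel
  expect_length(ag, 7)
  expect_equal(anyDuplicated(names(ag)), 0)
  expect_equal(ag$D$core_diameter_nm, 15.7)
  expect_equal(ag$D$mass_saturation_magnetization, 42.4)
  expect_equal(ag$D$r1_true[["0.064"]], 67.0)
  expect_equal(ag$ferumoxytol$r1_true[["0.064"]], 36.8)
  expect_equal(ag$`Gd-BOPTA`$agent_class, "chelate")
  for (a in ag) {
    expect_true(all(a$r1_true >= 0) && all(a$r2_true >= 0))
    expect_gt(a$stock_measured_conc, 0)
  }
})

test_that("true_rates follows the linear relaxivity model", {
  ag <- default_panel$D
  bg <- c(R1 = 0.5, R2 = 1.5)
  expect_equal(true_rates(ag, 0, 0.064, bg), c(R1 = 0.5, R2 = 1.5))
  # 0.5 + 67.0 * 0.06 computed by hand
  expect_equal(true_rates(ag, 0.06, 0.064, bg)[["R1"]], 4.52)
  r1 <- true_rates(ag, 0.1, 0.064, bg) - bg
  r2 <- true_rates(ag, 0.2, 0.064, bg) - bg
  expect_equal(unname(r2), unname(2 * r1))
  expect_error(true_rates(ag, 0.1, 1.5), "no r1 relaxivity entry at 1.5 T")
})

test_that("noiseless phantom voxels equal the analytic signal model exactly", {
  ser <- make_noiseless_series(concs = c(0, 0.06))
  layout <- ser$layout
  masks <- tube_masks(layout)
  rates <- true_rates(default_panel$D, 0.06 * 0.97, 0.064,
                      layout$background_rates)
  expected_tube <- ir_signal(ser$times, ser$TR, 1000 / rates[["R1"]], ser$S0)
  expected_bg <- ir_signal(ser$times, ser$TR,
                           1000 / layout$background_rates[["R1"]], ser$S0)
  in_tube <- which(masks[[2]])
  outside <- which(!(masks[[1]] | masks[[2]]))
  for (k in seq_along(ser$times)) {
    vol <- ser$data[, , , k]
    expect_equal(unique(vol[in_tube]), expected_tube[k])
    expect_equal(unique(vol[outside]), expected_bg[k])
  }
})

test_that("phantom simulation is bit-reproducible under a fixed seed", {
  layout <- default_phantom_layout("B", c(0, 0.12), grid = c(16, 16, 1),
                                   radius = 2)
  p1 <- default_protocol(0.064, "echo_decay", noise_sigma = 0.02, seed = 11)
  s1 <- simulate_phantom_series(layout, p1, default_panel)
  s2 <- simulate_phantom_series(layout, p1, default_panel)
  expect_identical(s1$data, s2$data)
  p3 <- default_protocol(0.064, "echo_decay", noise_sigma = 0.02, seed = 12)
  s3 <- simulate_phantom_series(layout, p3, default_panel)
  expect_false(identical(s1$data, s3$data))
})

test_that("Rician tube-ROI mean converges to the noiseless value (Monte Carlo)", {
  layout <- default_phantom_layout("B", 0.12, grid = c(12, 12, 1), radius = 2)
  sigma <- 0.01
  mask <- tube_masks(layout)[[1]]
  noiseless <- simulate_phantom_series(
    layout, default_protocol(0.064, "echo_decay", noise_sigma = 0),
    default_panel)
  ref <- noiseless$data[, , , 1][mask][1]
  sims <- vapply(seq_len(500), function(i) {
    p <- default_protocol(0.064, "echo_decay", noise_sigma = sigma,
                          seed = 5000 + i)
    s <- simulate_phantom_series(layout, p, default_panel)
    mean(s$data[, , , 1][mask])
  }, numeric(1))
  se <- stats::sd(sims) / sqrt(length(sims))
  # Rician bias at SNR 100 is far below 3 SE of this Monte Carlo
  expect_lt(abs(mean(sims) - ref), 3 * se + sigma^2 * noiseless$S0 / 2)
})

test_that("magnetization curves: Langevin for SPIONs, linear for the chelate", {
  cv <- simulate_magnetization_curve(default_panel$D)
  expect_equal(cv$M[cv$field_T == 0], 0)          # zero remanence
  big <- simulate_magnetization_curve(
    agent_spec("big", "spion", core_diameter_nm = 20,
               mass_saturation_magnetization = 50, magnetic_moment = 1e-17,
               neel_time = 1e-8), fields = 7)
  expect_gt(big$M / 50, 0.99)                     # saturation at 7 T
  gd <- simulate_magnetization_curve(default_panel$`Gd-BOPTA`)
  expect_equal(max(abs(diff(diff(gd$M)))), 0)     # exactly linear
  # determinism with noise
  c1 <- simulate_magnetization_curve(default_panel$B, rel_noise = 0.01,
                                     seed = 3)
  c2 <- simulate_magnetization_curve(default_panel$B, rel_noise = 0.01,
                                     seed = 3)
  expect_identical(c1$M, c2$M)
})

test_that("simulated dispersion profiles reproduce the forward model and the instrument grid", {
  p <- spm_params_for_agent(default_panel$C)
  prof0 <- simulate_nmrd_profile("spm", p, rel_noise = 0)
  expect_equal(prof0$r1, spm_r1(prof0$freq_MHz, p))
  expect_equal(range(prof0$freq_MHz), c(0.01, 40))
  pr1 <- simulate_nmrd_profile("spm", p, rel_noise = 0.01, seed = 9)
  pr2 <- simulate_nmrd_profile("spm", p, rel_noise = 0.01, seed = 9)
  expect_identical(pr1$r1, pr2$r1)
  expect_error(simulate_nmrd_profile("foo", p))
})

test_that("image series round-trips through NIfTI + sidecar", {
  ser <- make_noiseless_series(concs = c(0, 0.25))
  dir <- tempfile("series")
  on.exit(unlink(dir, recursive = TRUE))
  write_image_series(ser, dir, "phantom")
  back <- read_image_series(dir, "phantom")
  expect_equal(back$data, ser$data, tolerance = 1e-6)
  expect_equal(back$times, ser$times)
  expect_equal(back$layout$tubes$conc, ser$layout$tubes$conc)
})
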