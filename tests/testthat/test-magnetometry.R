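test_that("Langevin function matches an independent oracle to 1e-12 on [-50, 50]", {
  expect_equal(langevin(0), 0)
  expect_equal(langevin(1), 0.31303529, tolerance = 1e-7)
  x <- c(-50, -5, -1, -0.3, -0.05, -1e-7, 1e-7, 0.05, 0.3, 1, 5, 50)
  expect_equal(langevin(x), langevin_oracle(x), tolerance = 1e-12)
  expect_equal(langevin(-x), -langevin(x))
  expect_equal(langevin(1e4), 1, tolerance = 1e-4)
})

test_that("magnetization model has the Langevin limits", {
  expect_equal(magnetization_model(0, 42.4, 1e-19), 0)
  # initial slope Ms mu / 3 kB T
  eps <- 1e-6
  slope <- magnetization_model(eps, 42.4, 1e-19, 294.65) / eps
  expect_equal(slope, 42.4 * 1e-19 / (3 * 1.380649e-23 * 294.65),
               tolerance = 1e-6)
  expect_equal(magnetization_model(1e3, 42.4, 1e-19), 42.4, tolerance = 1e-4)
})

test_that("Langevin fit recovers generator parameters", {
  B <- seq(0, 7, by = 0.1)
  curve <- list(field_T = B,
                M = magnetization_model(B, 74.6, 1e-19),
                temperature_K = 294.65)
  fit <- fit_langevin(curve)
  expect_true(fit$converged)
  expect_equal(fit$Ms, 74.6, tolerance = 0.005)
  expect_equal(fit$mu / 1e-19, 1, tolerance = 0.005)
  # invariant to reversing the field grid
  rev_curve <- list(field_T = rev(B), M = rev(curve$M),
                    temperature_K = 294.65)
  fit2 <- fit_langevin(rev_curve)
  expect_equal(fit2$Ms, fit$Ms, tolerance = 1e-9)
  expect_error(fit_langevin(list(field_T = B, M = rep(0, length(B)),
                                 temperature_K = 294.65)), "degenerate")
})

test_that("Langevin Ms bias stays below 1% at 1% noise (100 repeats)", {
  ag <- default_panel$B
  fits <- vapply(seq_len(100), function(i) {
    cv <- simulate_magnetization_curve(ag, rel_noise = 0.01, seed = 400 + i)
    fit_langevin(cv)$Ms
  }, numeric(1))
  expect_lt(abs(mean(fits) - ag$mass_saturation_magnetization) /
            ag$mass_saturation_magnetization, 0.01)
})

test_that("magnetic diameter inverts the moment-volume relation", {
  d <- 15.7e-9; Ms_vol <- 4.8e5
  mu <- pi / 6 * d^3 * Ms_vol
  expect_equal(magnetic_diameter(mu, Ms_vol), 15.7, tolerance = 1e-12)
  expect_equal(magnetic_diameter(9.73e-19, 4.8e5), 15.7, tolerance = 0.01)
  expect_equal(magnetic_diameter(2 * mu, Ms_vol) / magnetic_diameter(mu, Ms_vol),
               2^(1 / 3), tolerance = 1e-12)
  expect_error(magnetic_diameter(-1, 4.8e5))
})

test_that("saturation-magnetization error propagates in quadrature", {
  out <- propagate_ms_error(100, 2, 1, 0.03)
  expect_equal(out[["sd_Ms"]] / out[["Ms"]], sqrt(0.0004 + 0.0009),
               tolerance = 1e-12)
  out0 <- propagate_ms_error(100, 2, 1, 0)
  expect_equal(out0[["sd_Ms"]] / out0[["Ms"]], 0.02)
  a <- propagate_ms_error(10, 0.2, 1, 0.03)
  b <- propagate_ms_error(10, 0.3, 1, 0.02)
  expect_equal(a[["sd_Ms"]], b[["sd_Ms"]])
})

test_that("default SPIONs sit at 40-50% of saturation at 64 mT", {
  expect_equal(saturation_fraction(default_panel$A, 0), 0)
  fr <- saturation_fraction(default_panel$D, c(0.01, 0.064, 0.5, 2))
  expect_true(all(diff(fr) > 0))
  for (nm in spion_names) {
    f64 <- saturation_fraction(default_panel[[nm]], 0.064, 294.65)
    expect_gte(f64, 0.40)
    expect_lte(f64, 0.50)
  }
})
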