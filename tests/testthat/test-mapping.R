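test_that("inversion-recovery signal model has the right closed-form behavior", {
  # hand evaluation of 1 - 2 exp(-700/923) + exp(-3000/923)
  expect_equal(ir_signal(700, 3000, 923), 0.101930, tolerance = 1e-5)
  expect_equal(ir_signal(1e7, 1e8, 500, S0 = 3), 3, tolerance = 1e-8)
  expect_lt(ir_signal(500 * log(2), 1e6, 500), 1e-6)  # null point at T1 ln 2
  expect_error(ir_signal(100, 3000, -5), "positive")
})

test_that("echo-decay signal model is exponential", {
  expect_equal(se_signal(0, 150, 7), 7)
  expect_equal(se_signal(200 * log(2), 200, 10), 5)
  expect_equal(se_signal(400, 200, 10), 10 * exp(-2))
  expect_error(se_signal(10, 0), "positive")
})

test_that("T1 voxel fit round-trips noiseless inversion-recovery data", {
  prot <- default_protocol(0.064, "inversion_recovery")
  for (t1_true in c(266, 923, 2500)) {
    sig <- ir_signal(prot$times, prot$TR, t1_true)
    fit <- fit_t1_voxel(prot$times, sig, prot$TR)
    expect_true(fit$converged)
    expect_equal(fit$T, t1_true, tolerance = 1e-3)
  }
  # imperfect inversion recovered to within 1%
  sig <- ir_signal(prot$times, prot$TR, 923, S0 = 50, d = 0.9)
  fit <- fit_t1_voxel(prot$times, sig, prot$TR)
  expect_equal(fit$d, 0.9, tolerance = 0.01)
  expect_equal(fit$T, 923, tolerance = 1e-3 * 923)
})

test_that("T1 fit flags degenerate inputs instead of inventing estimates", {
  expect_error(fit_t1_voxel(c(100, 200), c(1, 2), 3000), "at least 4")
  expect_error(fit_t1_voxel(c(100, 200, 300, 400), rep(0, 4), 3000),
               "all-zero")
  flat <- fit_t1_voxel(c(100, 200, 300, 400), rep(5, 4), 3000)
  expect_false(flat$converged)
  expect_true(is.na(flat$T))
})

test_that("T2 voxel fit matches the log-linear regression oracle on noiseless data", {
  prot <- default_protocol(0.064, "echo_decay")
  for (t2_true in c(60, 150, 400)) {
    sig <- se_signal(prot$times, t2_true, S0 = 20)
    fit <- fit_t2_voxel(prot$times, sig)
    expect_true(fit$converged)
    expect_equal(fit$T, t2_true, tolerance = 1e-3)
    co <- stats::coef(stats::lm(log(sig) ~ prot$times))
    expect_equal(fit$T, -1 / co[[2]], tolerance = 1e-6)
  }
  expect_error(fit_t2_voxel(37, 5), "at least 3")
})

test_that("fitted T1 is monotone in true T1 on noiseless data", {
  prot <- default_protocol(0.064, "inversion_recovery")
  t1s <- c(80, 150, 300, 600, 1200, 2400)
  fitted <- vapply(t1s, function(t1) {
    fit_t1_voxel(prot$times, ir_signal(prot$times, prot$TR, t1), prot$TR)$T
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("voxelwise mapping recovers tube and background T1 on a noiseless phantom", {
  ser <- make_noiseless_series(concs = c(0, 0.06, 0.25))
  map <- map_volume(ser)
  expect_equal(map$shape, dim(ser$data)[1:3])
  tab <- tube_relaxation_table(map, ser$layout)
  truth <- vapply(ser$layout$tubes$conc, function(cc) {
    1000 / true_rates(default_panel$D, cc * 0.97, 0.064,
                      ser$layout$background_rates)[["R1"]]
  }, numeric(1))
  expect_equal(tab$T_ms, truth, tolerance = 1e-3)
  bg_mask <- !Reduce(`|`, tube_masks(ser$layout))
  bg_t1 <- stats::median(map$T[bg_mask & map$converged])
  expect_equal(bg_t1, 1000 / 0.35, tolerance = 1e-3)
})

test_that("median T1 bias at SNR 50 stays within 2%", {
  prot <- default_protocol(0.064, "inversion_recovery", noise_sigma = 0.02,
                           seed = 21)
  t1_true <- 500
  clean <- ir_signal(prot$times, prot$TR, t1_true, S0 = 1)
  set.seed(21)
  fits <- vapply(seq_len(200), function(i) {
    noisy <- sqrt((clean + stats::rnorm(length(clean), 0, 0.02))^2 +
                  stats::rnorm(length(clean), 0, 0.02)^2)
    fit_t1_voxel(prot$times, noisy, prot$TR)$T
  }, numeric(1))
  expect_lt(abs(stats::median(fits) - t1_true) / t1_true, 0.02)
})

test_that("ROI statistics and normalization behave as advertised", {
  vol <- array(2, dim = c(4, 4, 1))
  mask <- array(TRUE, dim = c(4, 4, 1))
  expect_equal(roi_statistics(vol, mask),
               c(mean = 2, sd = 0, n = 16))
  vol[1:3] <- c(1, 2, 3)
  m3 <- array(FALSE, dim = c(4, 4, 1)); m3[1:3] <- TRUE
  expect_equal(roi_statistics(vol, m3), c(mean = 2, sd = 1, n = 3))
  expect_error(roi_statistics(vol, array(FALSE, dim = c(4, 4, 1))), "empty")
  expect_equal(max(normalized_intensity(c(3, 6, 12))), 1)
  expect_equal(normalized_intensity(c(5, 5, 5)), c(1, 1, 1))
  ni <- normalized_intensity(c(8.4, 1.0))
  expect_equal(ni[1] / ni[2], 8.4)
  expect_error(normalized_intensity(c(1, 2), reference = 0), "positive")
})
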