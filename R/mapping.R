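#' Inversion-recovery signal model
#'
#' Magnitude signal of an inversion-recovery acquisition,
#' `S = S0 * |1 - (1 + d) exp(-TI/T1) + exp(-TR/T1)|`, where `d` is the
#' inversion scale factor (1 for a perfect 180-degree inversion).
#'
#' @param TI inversion time, ms (vector).
#' @param TR repetition time, ms.
#' @param T1 longitudinal relaxation time, ms (> 0).
#' @param S0 equilibrium signal amplitude.
#' @param d inversion efficiency scale factor.
#' @return non-negative signal values.
#' @export
ir_signal <- function(TI, TR, T1, S0 = 1, d = 1) {
  if (any(T1 <= 0)) stop("T1 must be positive")
  S0 * abs(1 - (1 + d) * exp(-TI / T1) + exp(-TR / T1))
}

#' Spin-echo decay signal model
#'
#' Monoexponential transverse decay `S = S0 * exp(-TE/T2)`.
#'
#' @param TE echo time, ms (vector).
#' @param T2 transverse relaxation time, ms (> 0).
#' @param S0 signal at TE = 0.
#' @return signal values.
#' @export
se_signal <- function(TE, T2, S0 = 1) {
  if (any(T2 <= 0)) stop("T2 must be positive")
  S0 * exp(-TE / T2)
}

# Common container for a single-voxel fit result.
voxel_fit <- function(T = NA_real_, S0 = NA_real_, d = NA_real_,
                      resid_norm = NA_real_, converged = FALSE) {
  structure(list(T = T, S0 = S0, d = d, resid_norm = resid_norm,
                 converged = converged), class = "voxel_fit")
}

#' Fit the inversion-recovery model to one voxel
#'
#' Bounded Levenberg-Marquardt least squares for `(T1, S0, d)` under the
#' magnitude inversion-recovery model. Because the magnitude model has a
#' null-point local minimum, the optimizer is started from a coarse grid of
#' T1 values and the best (lowest residual) solution is kept. Bounds:
#' T1 in [1 ms, 20 s], d in [0, 1.2].
#'
#' @param TI inversion times, ms (>= 4 values).
#' @param signal measured magnitude signal at each TI (non-negative).
#' @param TR repetition time, ms.
#' @param fit_d fit the inversion scale factor (default) or hold it fixed.
#' @param d_value value of `d` when `fit_d = FALSE`.
#' @param t1_starts coarse grid of T1 starting values, ms.
#' @param rss_stop stop trying further starts once the residual sum of
#'   squares falls below this value (0 disables early exit).
#' @return a `voxel_fit` with elements `T`, `S0`, `d`, `resid_norm`,
#'   `converged`.
#' @export
fit_t1_voxel <- function(TI, signal, TR, fit_d = TRUE, d_value = 1,
                         t1_starts = c(50, 200, 800, 2000), rss_stop = 0) {
  if (length(TI) < 4) stop("need at least 4 inversion-time samples")
  stopifnot(length(TI) == length(signal))
  if (any(signal < 0)) stop("magnitude signals must be non-negative")
  if (all(signal == 0)) stop("all-zero signal: nothing to fit")
  if (stats::sd(signal) == 0) return(voxel_fit())   # no TI dependence
  S0_start <- max(signal)
  best <- NULL
  for (t1s in t1_starts) {
    if (fit_d) {
      resid_fn <- function(p) ir_signal(TI, TR, p[1], p[2], p[3]) - signal
      par0 <- c(T1 = t1s, S0 = S0_start, d = 1)
      lower <- c(1, 1e-12, 0); upper <- c(20000, Inf, 1.2)
    } else {
      resid_fn <- function(p) ir_signal(TI, TR, p[1], p[2], d_value) - signal
      par0 <- c(T1 = t1s, S0 = S0_start)
      lower <- c(1, 1e-12); upper <- c(20000, Inf)
    }
    fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                              lower = lower, upper = upper,
                              control = minpack.lm::nls.lm.control(maxiter = 100))
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
    if (rss_stop > 0 && best$rss <= rss_stop) break
  }
  voxel_fit(T = best$par[["T1"]], S0 = best$par[["S0"]],
            d = if (fit_d) best$par[["d"]] else d_value,
            resid_norm = sqrt(best$rss),
            converged = best$info %in% 1:4 && best$par[["T1"]] < 20000)
}

#' Fit the spin-echo decay model to one voxel
#'
#' Least squares for `(T2, S0)` under the monoexponential decay model,
#' initialized from the log-linear regression of `log(S)` on TE (which is
#' itself exact for noiseless data). Bounds: T2 in [1 ms, 5 s].
#'
#' @param TE echo times, ms (>= 3 values).
#' @param signal measured signal at each TE.
#' @return a `voxel_fit`; the `d` element is `NA` for echo-decay fits.
#' @export
fit_t2_voxel <- function(TE, signal) {
  if (length(TE) < 3) stop("need at least 3 echo-time samples")
  stopifnot(length(TE) == length(signal))
  if (all(signal == 0)) stop("all-zero signal: nothing to fit")
  if (stats::sd(signal) == 0) return(voxel_fit())
  pos <- signal > 0
  if (sum(pos) >= 2) {
    co <- stats::coef(stats::lm(log(signal[pos]) ~ TE[pos]))
    T2_0 <- if (co[[2]] < 0) min(max(-1 / co[[2]], 1), 5000) else 500
    S0_0 <- exp(co[[1]])
  } else {
    T2_0 <- 100; S0_0 <- max(signal)
  }
  resid_fn <- function(p) se_signal(TE, p[1], p[2]) - signal
  fit <- minpack.lm::nls.lm(par = c(T2 = T2_0, S0 = S0_0), fn = resid_fn,
                            lower = c(1, 1e-12), upper = c(5000, Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  voxel_fit(T = fit$par[["T2"]], S0 = fit$par[["S0"]],
            resid_norm = sqrt(fit$deviance),
            converged = fit$info %in% 1:4 && fit$par[["T2"]] < 5000)
}

#' Voxelwise parametric mapping of an image series
#'
#' Applies [fit_t1_voxel()] (inversion-recovery series) or [fit_t2_voxel()]
#' (echo-decay series) to every voxel in the mask and assembles T1 or T2,
#' amplitude, inversion-factor and convergence maps aligned to the series
#' grid. Voxels that fail to converge are flagged in the `converged` map,
#' never silently dropped.
#'
#' The default mask excludes voxels whose maximum signal across the series is
#' below 5x the noise floor (`noise_sigma * S0` from the series metadata);
#' with zero recorded noise every voxel with signal is fitted.
#'
#' @param series an [image_series()].
#' @param mask optional logical array of the series' spatial shape.
#' @param fit_d fit the inversion scale factor per voxel (IR mode only).
#' @return object of class `parametric_map`: arrays `T`, `S0`, `d`,
#'   `resid_norm`, logical `converged` and `mask`, plus `mode` and `shape`.
#' @export
map_volume <- function(series, mask = NULL, fit_d = TRUE) {
  stopifnot(inherits(series, "image_series"))
  dm <- dim(series$data)
  shape <- dm[1:3]
  amax <- apply(series$data, 1:3, max)
  if (is.null(mask)) {
    thr <- 5 * series$noise_sigma * series$S0
    mask <- amax > thr
  }
  stopifnot(identical(dim(mask), shape))
  Tm <- array(NA_real_, shape); S0m <- Tm; dmap <- Tm; rn <- Tm
  conv <- array(FALSE, shape)
  idx <- which(mask)
  nt <- dm[4]
  flat <- matrix(series$data, prod(shape), nt)
  # early-exit residual threshold: once a start reaches the noise floor,
  # further grid starts cannot improve the solution meaningfully
  rss_stop <- if (series$noise_sigma > 0)
    2 * nt * (series$noise_sigma * series$S0)^2 else 0
  for (v in idx) {
    sig <- flat[v, ]
    f <- tryCatch({
      if (series$mode == "inversion_recovery")
        fit_t1_voxel(series$times, sig, series$TR, fit_d = fit_d,
                     rss_stop = rss_stop)
      else
        fit_t2_voxel(series$times, sig)
    }, error = function(e) voxel_fit())
    Tm[v] <- f$T; S0m[v] <- f$S0; dmap[v] <- f$d
    rn[v] <- f$resid_norm; conv[v] <- isTRUE(f$converged)
  }
  structure(list(T = Tm, S0 = S0m, d = dmap, resid_norm = rn,
                 converged = conv, mask = mask,
                 mode = series$mode, field = series$field, shape = shape),
            class = "parametric_map")
}

#' ROI statistics
#'
#' Arithmetic mean, sample standard deviation and voxel count over a masked
#' region of a volume. `NA` voxels (e.g. non-converged fits) are dropped.
#'
#' @param volume numeric array.
#' @param mask logical array of the same shape.
#' @return named numeric `c(mean, sd, n)`.
#' @export
roi_statistics <- function(volume, mask) {
  stopifnot(identical(dim(volume), dim(mask)))
  vals <- volume[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("empty ROI mask")
  c(mean = mean(vals),
    sd = if (length(vals) > 1) stats::sd(vals) else 0,
    n = length(vals))
}

#' Normalize ROI intensities to a reference
#'
#' Divides per-sample ROI means by a reference intensity; by default the
#' maximum ROI mean in the image, so the brightest sample maps to 1 and
#' between-sample ratios are preserved.
#'
#' @param roi_means numeric vector of per-sample ROI mean intensities.
#' @param reference reference intensity (> 0); default `max(roi_means)`.
#' @return normalized intensities.
#' @export
normalized_intensity <- function(roi_means, reference = max(roi_means)) {
  if (reference <= 0) stop("reference intensity must be positive")
  roi_means / reference
}
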