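# Internal helpers: seeded evaluation, Rician noise, rounding, numeric Jacobian.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed evaluates the code with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Magnitude (Rician) noise: two independent Gaussian channels of SD `sigma`
# in absolute signal units, combined in quadrature with the true signal in
# the real channel. sigma = 0 returns the input unchanged.
add_rician_noise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  re <- x + stats::rnorm(n, 0, sigma)
  im <- stats::rnorm(n, 0, sigma)
  out <- sqrt(re^2 + im^2)
  dim(out) <- dim(x)
  out
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (0.05 -> 0.1), the convention used for the reported relaxivity tables,
#' rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Central-difference Jacobian of a vector-valued function at `par`,
# used to compute parameter covariance after Levenberg-Marquardt fits.
numeric_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1e-8)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

# Standard errors from a residual function and its optimum.
lm_fit_se <- function(resid_fn, par) {
  J <- numeric_jacobian(resid_fn, par)
  r <- resid_fn(par)
  dof <- max(length(r) - length(par), 1L)
  s2 <- sum(r^2) / dof
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e) {
    matrix(NA_real_, length(par), length(par))
  })
  sqrt(pmax(diag(cov), 0))
}
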