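#' Langevin function
#'
#' `L(x) = coth(x) - 1/x`, the equilibrium fractional alignment of a
#' classical magnetic moment with argument `x = mu * B / (kB * T)`. Evaluated
#' by its Taylor series near zero for numerical stability; odd in `x` and
#' asymptotes to +/-1.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length, in (-1, 1).
#' @export
langevin <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-5
  # series: x/3 - x^3/45 + 2 x^5/945
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

# 2 L(x)/x with its x -> 0 limit (2/3) handled analytically; used by the
# dispersion model weights as well.
two_l_over_x <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-5
  xs <- x[small]
  out[small] <- 2 / 3 - 2 * xs^2 / 45
  xl <- x[!small]
  out[!small] <- 2 * langevin(xl) / xl
  out
}

#' Superparamagnetic magnetization model
#'
#' Single-population Langevin magnetization `M(B) = Ms * L(mu B / kB T)` of a
#' monodisperse ensemble of non-interacting superparamagnetic particles:
#' zero remanence, saturation at high field.
#'
#' @param B applied field, tesla (vector).
#' @param Ms mass saturation magnetization, A m^2/kg.
#' @param mu per-particle magnetic moment, J/T.
#' @param temperature absolute temperature, K.
#' @return magnetization, A m^2/kg.
#' @export
magnetization_model <- function(B, Ms, mu, temperature = .room_temperature_K) {
  stopifnot(temperature > 0)
  Ms * langevin(mu * B / (.kB * temperature))
}

#' Simulate a magnetization-vs-field curve
#'
#' For a SPION the forward model is the single Langevin function with the
#' agent's calibrated moment and saturation magnetization; for a paramagnetic
#' chelate the curve is linear, `M = chi * B`, with a slope far below the
#' SPION curves over the same range. Gaussian noise with SD `rel_noise *
#' max(|M|)` is added when requested.
#'
#' @param agent an [agent_spec()].
#' @param fields field grid, tesla; default 0-7 T.
#' @param temperature K; default 294.65 K (21.5 C, the measurement temperature).
#' @param rel_noise relative noise SD (fraction of the curve maximum).
#' @param seed RNG seed for reproducibility.
#' @return object of class `magnetization_curve`: list with `field_T`, `M`,
#'   `temperature_K`, `agent`.
#' @export
simulate_magnetization_curve <- function(agent, fields = seq(0, 7, by = 0.1),
                                         temperature = .room_temperature_K,
                                         rel_noise = 0, seed = NULL) {
  stopifnot(inherits(agent, "agent_spec"), temperature > 0)
  M <- if (agent$agent_class == "spion") {
    magnetization_model(fields, agent$mass_saturation_magnetization,
                        agent$magnetic_moment, temperature)
  } else {
    agent$chi_mass * fields
  }
  if (rel_noise > 0) {
    scale <- max(abs(M))
    M <- with_seed(seed, M + stats::rnorm(length(M), 0, rel_noise * scale))
  }
  structure(list(field_T = fields, M = M, temperature_K = temperature,
                 agent = agent$name),
            class = "magnetization_curve")
}

#' Fit a single Langevin function to a magnetization curve
#'
#' Least-squares estimation of the saturation magnetization `Ms` and the
#' per-particle moment `mu` from `M(B)` data, with starting values from the
#' curve maximum and the low-field slope (`Ms mu / 3 kB T`). The effective
#' magnetic diameter is derived from the fitted moment assuming a spherical
#' magnetite core (see [magnetic_diameter()]).
#'
#' @param curve a `magnetization_curve` (or list with `field_T`, `M`,
#'   `temperature_K`).
#' @param density particle material density, kg/m^3 (magnetite default),
#'   used with the fitted mass Ms to form the volumetric Ms for the
#'   diameter conversion.
#' @return object of class `langevin_fit`: `Ms`, `Ms_se`, `mu`, `mu_se`,
#'   `magnetic_diameter_nm`, `temperature_K`, `converged`.
#' @export
fit_langevin <- function(curve, density = .magnetite_density) {
  B <- curve$field_T; M <- curve$M; TK <- curve$temperature_K
  stopifnot(length(B) == length(M), length(B) >= 4)
  if (all(M == 0)) stop("degenerate all-zero magnetization curve")
  if (max(abs(B)) < 2)
    warning("curve spans < 2 T; saturation magnetization weakly constrained")
  ord <- order(B)
  B <- B[ord]; M <- M[ord]
  Ms0 <- max(abs(M))
  # low-field slope from points below a quarter of the field range
  low <- which(abs(B) <= max(abs(B)) / 4 & B != 0)
  slope <- if (length(low) >= 2) stats::coef(stats::lm(M[low] ~ B[low] + 0))[[1]]
           else Ms0 / max(abs(B))
  mu0 <- max(3 * .kB * TK * slope / Ms0, 1e-21)
  resid_fn <- function(p) magnetization_model(B, p[1], p[2], TK) - M
  fit <- minpack.lm::nls.lm(par = c(Ms = Ms0, mu = mu0), fn = resid_fn,
                            lower = c(1e-6, 1e-24), upper = c(1e4, 1e-15),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  se <- lm_fit_se(resid_fn, fit$par)
  Ms_vol <- fit$par[["Ms"]] * density
  structure(list(Ms = fit$par[["Ms"]], Ms_se = se[1],
                 mu = fit$par[["mu"]], mu_se = se[2],
                 magnetic_diameter_nm = magnetic_diameter(fit$par[["mu"]], Ms_vol),
                 temperature_K = TK,
                 converged = fit$info %in% 1:4),
            class = "langevin_fit")
}

#' Effective magnetic diameter from a fitted moment
#'
#' Inverts `mu = (pi/6) d^3 Ms_vol` for the diameter of the magnetically
#' ordered core: `d = (6 mu / (pi Ms_vol))^(1/3)`.
#'
#' @param mu per-particle moment, J/T.
#' @param Ms_volumetric volumetric saturation magnetization, A/m.
#' @return diameter in nm.
#' @export
magnetic_diameter <- function(mu, Ms_volumetric) {
  stopifnot(mu > 0, Ms_volumetric > 0)
  (6 * mu / (pi * Ms_volumetric))^(1 / 3) * 1e9
}

#' Quadrature propagation of saturation-magnetization error
#'
#' The mass saturation magnetization is a measured total moment divided by a
#' measured metal content; its relative uncertainty combines the two sources
#' in quadrature: `sd(Ms)/Ms = sqrt((sd_m/m)^2 + (sd_c/c)^2)`.
#'
#' @param moment measured moment (central value).
#' @param sd_moment its SD.
#' @param conc measured metal content (central value).
#' @param sd_conc its SD.
#' @return named numeric `c(Ms, sd_Ms)` (Ms in the units of moment/conc).
#' @export
propagate_ms_error <- function(moment, sd_moment, conc, sd_conc) {
  stopifnot(moment > 0, conc > 0)
  Ms <- moment / conc
  rel <- sqrt((sd_moment / moment)^2 + (sd_conc / conc)^2)
  c(Ms = Ms, sd_Ms = Ms * rel)
}

#' Fraction of saturation magnetization at a field
#'
#' `L(mu B / kB T)`: how far up its Langevin curve a particle population sits
#' at field `B`. At 64 mT the default SPION panel reaches 40-50% of
#' saturation, the property that underlies their strong low-field r1.
#'
#' @param fit a `langevin_fit`, an `agent_spec` (spion), or a numeric moment
#'   in J/T.
#' @param B field, tesla.
#' @param temperature K.
#' @return fraction in [0, 1).
#' @export
saturation_fraction <- function(fit, B, temperature = .room_temperature_K) {
  mu <- if (inherits(fit, "langevin_fit")) fit$mu
        else if (inherits(fit, "agent_spec")) fit$magnetic_moment
        else fit
  stopifnot(is.numeric(mu), mu > 0, temperature > 0)
  langevin(mu * B / (.kB * temperature))
}
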