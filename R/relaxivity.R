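#' Rescale nominal concentrations to assayed values
#'
#' Dilution-series concentrations are prepared from the manufacturer's
#' labelled stock; when the stock metal content is re-measured (e.g. by
#' ICP-OES), every nominal concentration is rescaled by the common factor
#' `measured/nominal`.
#'
#' @param nominal nominal concentrations, mmol/L.
#' @param stock_nominal labelled stock concentration (> 0).
#' @param stock_measured assayed stock concentration (> 0).
#' @return actual concentrations, mmol/L.
#' @export
rescale_concentrations <- function(nominal, stock_nominal, stock_measured) {
  if (stock_nominal <= 0 || stock_measured <= 0)
    stop("stock concentrations must be positive")
  nominal * stock_measured / stock_nominal
}

#' Concentration exclusion rule for relaxivity fitting
#'
#' An inversion-recovery protocol cannot reliably measure T1 values shorter
#' than its first inversion time. Concentrations whose fitted T1 falls below
#' `first_TI` are excluded from the relaxivity regression; the returned
#' exclusion set is meant to be propagated to the other field/channel fits
#' of the same agent so that all four regressions use identical
#' concentrations.
#'
#' @param t1_values fitted T1 per concentration, ms.
#' @param first_TI first inversion time of the protocol, ms.
#' @return list with integer vectors `included` and `excluded` (1-based
#'   indices into `t1_values`), character `reasons` (parallel to
#'   `excluded`), and logical `fittable` (at least two inclusions).
#' @export
apply_exclusion_rule <- function(t1_values, first_TI) {
  stopifnot(length(t1_values) >= 1, first_TI > 0)
  excluded <- which(is.na(t1_values) | t1_values < first_TI)
  included <- setdiff(seq_along(t1_values), excluded)
  list(included = included, excluded = excluded,
       reasons = ifelse(is.na(t1_values[excluded]),
                        "T1 fit did not converge",
                        sprintf("fitted T1 = %.0f ms below first TI = %.0f ms",
                                t1_values[excluded], first_TI)),
       fittable = length(included) >= 2)
}

#' Relaxivity from a concentration series
#'
#' Ordinary least-squares fit of the linear relaxivity model
#' `rate = intercept + r * conc` over the included rows: the slope is the
#' relaxivity (L mmol^-1 s^-1) and the intercept estimates the background
#' rate `1/T'`. An optional weighted fit uses inverse-variance weights from
#' per-rate SDs.
#'
#' @param conc actual metal concentrations, mmol/L.
#' @param rate relaxation rates, 1/s.
#' @param included indices of rows to use (default all).
#' @param rate_sd optional per-rate SDs enabling weighted least squares.
#' @return object of class `relaxivity_fit`: `r`, `r_se`, `intercept`,
#'   `intercept_se`, `n_used`, `excluded` (indices), `residuals`.
#' @export
fit_relaxivity <- function(conc, rate, included = seq_along(conc),
                           rate_sd = NULL) {
  stopifnot(length(conc) == length(rate))
  if (length(included) < 2) stop("need at least 2 included concentrations")
  x <- conc[included]; y <- rate[included]
  fit <- if (is.null(rate_sd)) stats::lm(y ~ x)
         else stats::lm(y ~ x, weights = 1 / rate_sd[included]^2)
  # summary warns on exactly linear (zero-residual) data; harmless here
  sm <- suppressWarnings(summary(fit)$coefficients)
  structure(list(r = unname(stats::coef(fit)[2]),
                 r_se = if (nrow(sm) == 2 && length(included) > 2) sm[2, 2] else NA_real_,
                 intercept = unname(stats::coef(fit)[1]),
                 intercept_se = if (length(included) > 2) sm[1, 2] else NA_real_,
                 n_used = length(included),
                 excluded = setdiff(seq_along(conc), included),
                 residuals = stats::residuals(fit)),
            class = "relaxivity_fit")
}

#' @export
print.relaxivity_fit <- function(x, ...) {
  cat(sprintf("<relaxivity_fit> r = %.2f +/- %.2f L mmol-1 s-1, intercept = %.3f 1/s, n = %d\n",
              x$r, x$r_se, x$intercept, x$n_used))
  invisible(x)
}

#' Transverse/longitudinal relaxivity ratio
#'
#' `r2/r1`, the figure of merit for positive-contrast agents (values near 1
#' mean transverse decay does not dominate the longitudinal enhancement),
#' with standard error propagated in quadrature from the two relative
#' errors.
#'
#' @param r2,r1 relaxivities (numbers or `relaxivity_fit` objects).
#' @param r2_se,r1_se standard errors when plain numbers are given.
#' @return named numeric `c(ratio, se)`.
#' @export
relaxivity_ratio <- function(r2, r1, r2_se = 0, r1_se = 0) {
  if (inherits(r2, "relaxivity_fit")) { r2_se <- r2$r_se; r2 <- r2$r }
  if (inherits(r1, "relaxivity_fit")) { r1_se <- r1$r_se; r1 <- r1$r }
  if (r1 <= 0) stop("r1 must be positive")
  ratio <- r2 / r1
  rel <- sqrt(ifelse(r2 > 0, (r2_se / r2)^2, 0) + (r1_se / r1)^2)
  c(ratio = ratio, se = ratio * rel)
}

#' Fold-enhancement of one relaxivity over a reference
#'
#' @param r_agent relaxivity of the agent of interest.
#' @param r_reference relaxivity of the reference agent (> 0).
#' @return the quotient (report with [round_half_up()] to 1 decimal).
#' @export
fold_enhancement <- function(r_agent, r_reference) {
  if (inherits(r_agent, "relaxivity_fit")) r_agent <- r_agent$r
  if (inherits(r_reference, "relaxivity_fit")) r_reference <- r_reference$r
  if (r_reference <= 0) stop("reference relaxivity must be positive")
  r_agent / r_reference
}

#' Predicted T1 at a concentration
#'
#' Inverts the linear relaxivity model: `1/T1 = 1/T1_baseline + r1 * conc`,
#' with T1 in ms and rates in 1/s.
#'
#' @param r1 longitudinal relaxivity, L mmol^-1 s^-1.
#' @param baseline_T1 agent-free T1, ms (> 0).
#' @param conc metal concentration, mmol/L (>= 0).
#' @return predicted T1, ms.
#' @export
t1_at_concentration <- function(r1, baseline_T1, conc) {
  stopifnot(baseline_T1 > 0, all(conc >= 0))
  1000 / (1000 / baseline_T1 + r1 * conc)
}
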