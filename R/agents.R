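#' Contrast-agent specification
#'
#' Bundles the ground-truth physical and relaxometric properties of a single
#' contrast agent, used by every synthetic generator. Relaxivities are stored
#' per field (tesla) and, for the fast-field-cycling channel, per temperature
#' (Celsius). Superparamagnetic iron oxide nanoparticles (`agent_class =
#' "spion"`) additionally carry a core diameter, a mass saturation
#' magnetization, a per-particle magnetic moment and a Neel correlation time;
#' paramagnetic chelates carry a mass susceptibility slope instead.
#'
#' @param name agent label.
#' @param agent_class `"spion"` or `"chelate"`.
#' @param core_diameter_nm physical core diameter, nm (spion only).
#' @param mass_saturation_magnetization Ms, A m^2/kg (spion only).
#' @param magnetic_moment per-particle moment, J/T (spion only).
#' @param neel_time Neel correlation time, s (spion only).
#' @param r1_true,r2_true named numeric vectors of true relaxivities
#'   (L mmol^-1 s^-1), names are field strengths in tesla (e.g. `"0.064"`).
#' @param r1_nmrd named numeric vector of true dispersion-channel r1 values,
#'   names are temperatures in Celsius.
#' @param stock_nominal_conc,stock_measured_conc label and assayed metal
#'   concentration of the stock solution, mmol/L.
#' @param chi_mass mass susceptibility slope for chelates, A m^2 kg^-1 T^-1.
#' @return an object of class `agent_spec`.
#' @export
agent_spec <- function(name,
                       agent_class = c("spion", "chelate"),
                       core_diameter_nm = NA_real_,
                       mass_saturation_magnetization = NA_real_,
                       magnetic_moment = NA_real_,
                       neel_time = NA_real_,
                       r1_true = numeric(),
                       r2_true = numeric(),
                       r1_nmrd = numeric(),
                       stock_nominal_conc = 1,
                       stock_measured_conc = 1,
                       chi_mass = NA_real_) {
  agent_class <- match.arg(agent_class)
  if (agent_class == "spion") {
    stopifnot(is.finite(core_diameter_nm), core_diameter_nm > 0,
              is.finite(mass_saturation_magnetization),
              mass_saturation_magnetization > 0,
              is.finite(magnetic_moment), magnetic_moment > 0,
              is.finite(neel_time), neel_time > 0)
  }
  stopifnot(all(r1_true >= 0), all(r2_true >= 0),
            stock_nominal_conc > 0, stock_measured_conc > 0)
  structure(list(
    name = name,
    agent_class = agent_class,
    core_diameter_nm = core_diameter_nm,
    mass_saturation_magnetization = mass_saturation_magnetization,
    magnetic_moment = magnetic_moment,
    neel_time = neel_time,
    r1_true = r1_true,
    r2_true = r2_true,
    r1_nmrd = r1_nmrd,
    stock_nominal_conc = stock_nominal_conc,
    stock_measured_conc = stock_measured_conc,
    chi_mass = chi_mass
  ), class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf("<agent_spec> %s (%s)\n", x$name, x$agent_class))
  if (x$agent_class == "spion")
    cat(sprintf("  core %.1f nm, Ms %.1f A m2/kg, mu %.3g J/T, tau_N %.2g s\n",
                x$core_diameter_nm, x$mass_saturation_magnetization,
                x$magnetic_moment, x$neel_time))
  for (f in names(x$r1_true))
    cat(sprintf("  r1(%s T) = %.1f, r2(%s T) = %.1f L mmol-1 s-1\n",
                f, x$r1_true[[f]], f, x$r2_true[[f]]))
  invisible(x)
}

#' Default contrast-agent panel
#'
#' Returns the seven-agent study panel: four monodisperse carboxylic
#' acid-coated SPIONs (4.9, 8.5, 12.9 and 15.7 nm cores), two clustered
#' therapeutic SPION formulations (ferumoxytol, ferumoxides) and one Gd
#' chelate (Gd-BOPTA, gadobenate dimeglumine). Core diameters and saturation
#' magnetizations are the measured structural/magnetic values; the stored
#' relaxivities at 0.064 T and 3 T, and the dispersion-channel r1 at 21.5 and
#' 37 Celsius, serve as simulation ground truth.
#'
#' Per-particle magnetic moments are calibrated so each SPION sits at 40-50%
#' of saturation at 64 mT and room temperature; Neel times grow with core
#' size over 1-20 ns. Stock rescale factors (measured/nominal) emulate the
#' discrepancy between labelled and assayed metal content.
#'
#' @return named list of [agent_spec()] objects.
#' @export
build_default_agents <- function() {
  mk <- function(name, d, Ms, mu, tauN, r1_64, r2_64, r1_3, r2_3,
                 nmrd_21, nmrd_37, stock_nom, factor) {
    agent_spec(name, "spion",
               core_diameter_nm = d,
               mass_saturation_magnetization = Ms,
               magnetic_moment = mu,
               neel_time = tauN,
               r1_true = c(`0.064` = r1_64, `3` = r1_3),
               r2_true = c(`0.064` = r2_64, `3` = r2_3),
               r1_nmrd = c(`21.5` = nmrd_21, `37` = nmrd_37),
               stock_nominal_conc = stock_nom,
               stock_measured_conc = stock_nom * factor)
  }
  agents <- list(
    A = mk("A", 4.9, 40.3, 8.90e-20, 1e-9,
           3.6, 8.9, 1.5, 67.7, 4.3, 4.0, 89, 0.95),
    B = mk("B", 8.5, 74.6, 9.22e-20, 3e-9,
           31.4, 39.2, 5.3, 93.1, 28.5, 20.7, 89, 1.02),
    C = mk("C", 12.9, 44.8, 9.85e-20, 8e-9,
           33.5, 53.6, 1.2, 113.7, 36.7, 26.8, 89, 0.91),
    D = mk("D", 15.7, 42.4, 1.030e-19, 2e-8,
           67.0, 77.5, 2.9, 181.3, 61.5, 46.3, 89, 0.97),
    ferumoxytol = mk("ferumoxytol", 6.0, 95.7, 9.53e-20, 5e-9,
                     36.8, 56.5, 6.9, 87.9, 42.2, 31.5, 537, 0.99),
    ferumoxides = mk("ferumoxides", 5.5, 52.7, 9.22e-20, 4e-9,
                     30.9, 58.3, 4.5, 170.4, 26.0, 20.4, 200, 0.94),
    `Gd-BOPTA` = agent_spec("Gd-BOPTA", "chelate",
                            r1_true = c(`0.064` = 7.7, `3` = 5.2),
                            r2_true = c(`0.064` = 7.9, `3` = 5.9),
                            r1_nmrd = c(`21.5` = 6.9, `37` = 5.6),
                            stock_nominal_conc = 500,
                            stock_measured_conc = 500,
                            chi_mass = 0.4)
  )
  agents
}

# Look up a relaxivity entry by numeric key (field in T, or temperature in C
# for the dispersion channel), tolerant of numeric formatting.
.field_entry <- function(values, key, agent_name, channel, unit = "T") {
  keys <- suppressWarnings(as.numeric(names(values)))
  hit <- which(is.finite(keys) & abs(keys - key) < 1e-9)
  if (length(hit) != 1L)
    stop(sprintf("agent '%s' has no %s relaxivity entry at %g %s",
                 agent_name, channel, key, unit), call. = FALSE)
  values[[hit]]
}

#' True relaxation rates for an agent at a given concentration
#'
#' The linear relaxivity model: the measured rate is the background
#' (agent-free matrix) rate plus relaxivity times metal concentration,
#' `1/T = 1/T' + r * [CM]`, applied componentwise to R1 and R2.
#'
#' @param agent an [agent_spec()].
#' @param conc metal concentration, mmol/L (>= 0).
#' @param field field strength, tesla; must have an entry in the spec.
#' @param background length-2 numeric `c(R1, R2)` background rates, 1/s.
#' @return named numeric `c(R1, R2)` in 1/s.
#' @export
true_rates <- function(agent, conc, field, background = c(R1 = 0.35, R2 = 1.5)) {
  stopifnot(inherits(agent, "agent_spec"), conc >= 0, length(background) == 2L)
  r1 <- .field_entry(agent$r1_true, field, agent$name, "r1")
  r2 <- .field_entry(agent$r2_true, field, agent$name, "r2")
  c(R1 = unname(background[1]) + r1 * conc,
    R2 = unname(background[2]) + r2 * conc)
}
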