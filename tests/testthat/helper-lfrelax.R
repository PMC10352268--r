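# Shared fixtures: the default agent panel and a small noiseless phantom.

default_panel <- build_default_agents()

spion_names <- names(Filter(function(a) a$agent_class == "spion",
                            default_panel))

make_noiseless_series <- function(agent = "D", field = 0.064,
                                  mode = "inversion_recovery",
                                  concs = c(0, 0.06, 0.25)) {
  layout <- default_phantom_layout(agent, concs, grid = c(20, 20, 1),
                                   radius = 2)
  prot <- default_protocol(field, mode, noise_sigma = 0)
  simulate_phantom_series(layout, prot, default_panel)
}

# independent Langevin oracle: cosh/sinh quotient for moderate |x|, long
# Taylor series near zero (terms through x^9; next term < 1e-16 at |x| 0.1)
langevin_oracle <- function(x) {
  ifelse(abs(x) <= 0.1,
         x / 3 - x^3 / 45 + 2 * x^5 / 945 - x^7 / 4725 + 2 * x^9 / 93555,
         cosh(x) / sinh(x) - 1 / x)
}
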