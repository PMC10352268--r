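# Physical constants (CODATA 2018) and unit conventions shared across modules.
# Fields in tesla, frequencies in MHz (proton Larmor), times in ms for imaging
# and s for correlation times, concentrations in mmol/L, relaxivities in
# L mmol^-1 s^-1, mass magnetization in A m^2/kg.

.kB   <- 1.380649e-23      # Boltzmann constant, J/K
.mu0  <- 4e-7 * pi         # vacuum permeability, T m/A
.muB  <- 9.2740100783e-24  # Bohr magneton, J/T
.gammaI <- 2.6752218744e8  # proton gyromagnetic ratio, rad s^-1 T^-1
.g_electron <- 2.0
.gyro_MHz_per_T <- 42.577478   # proton Larmor frequency per tesla, MHz/T
.omegaS_over_omegaI <- 658.2   # electron/proton Larmor frequency ratio
.N_avogadro <- 6.02214076e23

.bulk_magnetite_Ms <- 92       # bulk Fe3O4 mass saturation magnetization, A m^2/kg
.magnetite_density <- 5180     # kg/m^3, used to convert mass to volumetric Ms

# Room temperature used for magnetometry and MRI experiments (21.5 C).
.room_temperature_K <- 294.65
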