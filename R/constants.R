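#' Physical constants (CODATA 2018)
#'
#' Exact SI values of the Boltzmann constant, the Planck constant and the
#' molar gas constant, as fixed by the 2019 SI redefinition, plus the
#' gyromagnetic ratios used to convert chemical-shift offsets from ppm to
#' rad/s at a given static field.
#'
#' Energies are handled in kJ/mol throughout the package, entropies in
#' kJ/mol/K, so `R_kJ` is the gas constant divided by 1000.
#'
#' @format A list with elements `kB` (J/K), `h` (J s), `R` (J/mol/K),
#'   `R_kJ` (kJ/mol/K), `gamma_H` and `gamma_C` (rad/s/T).
#' @export
codata <- list(
  kB     = 1.380649e-23,
  h      = 6.62607015e-34,
  R      = 8.31446261815324,
  R_kJ   = 8.31446261815324e-3,
  # gyromagnetic ratios, rad s^-1 T^-1
  gamma_H = 267.52218744e6,
  gamma_C = 67.2828e6
)
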