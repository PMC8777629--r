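#' Physical constants and unit conversions
#'
#' All chemical potentials in this package are handled per mole (J/mol), so
#' the thermal energy scale is R*T rather than kB*T; the two conventions
#' differ only by Avogadro's number and the model depends only on the
#' dimensionless ratio (mu_mv - mu_s)/(R*T).
#'
#' @format A named list:
#' \describe{
#'   \item{R_gas}{molar gas constant, J/(mol K)}
#'   \item{N_avogadro}{Avogadro constant, 1/mol}
#'   \item{mm3_to_cm3}{volume conversion}
#'   \item{mm2_to_cm2}{area conversion}
#'   \item{A2_to_cm2}{square Angstrom to cm^2}
#'   \item{mg_per_ml_to_ng_per_cm3}{concentration conversion}
#'   \item{g_to_ng}{mass conversion}
#' }
#' @export
salb_constants <- list(
  R_gas                   = 8.314462618,   # J / (mol K)
  N_avogadro              = 6.02214076e23, # 1 / mol
  mm3_to_cm3              = 1e-3,
  mm2_to_cm2              = 1e-2,
  A2_to_cm2               = 1e-16,
  mg_per_ml_to_ng_per_cm3 = 1e6,
  g_to_ng                 = 1e9
)

# thermal energy per mole, J/mol
rt_energy <- function(temperature) salb_constants$R_gas * temperature
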