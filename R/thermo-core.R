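#' Thermodynamic parameters for the two-state adsorption model
#'
#' Bundles the chemical-potential difference between a lipid in suspended
#' micelles/vesicles and a lipid in the supported layer (mu_mv - mu_s, in
#' J/mol), the absolute temperature, and the substrate class. Only the
#' difference of chemical potentials is identifiable from coverage data, so
#' mu_s is pinned to zero internally.
#'
#' @param mu_diff chemical-potential difference mu_mv - mu_s in J/mol. May be
#'   negative; positive values favor adsorption onto the substrate.
#' @param temperature absolute temperature in K.
#' @param substrate `"hydrophilic"` (supported bilayer forms; leaflet
#'   multiplicity 2) or `"hydrophobic"` (supported monolayer; multiplicity 1).
#' @return An object of class `thermo_params`.
#' @examples
#' thermo_params(mu_diff = 585, temperature = 297.15)
#' @export
thermo_params <- function(mu_diff, temperature, substrate = "hydrophilic") {
  stopifnot(is.numeric(mu_diff), length(mu_diff) == 1L, is.finite(mu_diff))
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  if (temperature <= 0) {
    stop("`temperature` must be a positive absolute temperature (K)")
  }
  substrate <- match.arg(substrate, c("hydrophilic", "hydrophobic"))
  structure(
    list(mu_diff = as.numeric(mu_diff),
         temperature = as.numeric(temperature),
         substrate = substrate),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Thermodynamic parameters\n")
  cat(sprintf("  mu_mv - mu_s : %g J/mol\n", x$mu_diff))
  cat(sprintf("  temperature  : %g K\n", x$temperature))
  cat(sprintf("  substrate    : %s (leaflet multiplicity %d)\n",
              x$substrate, substrate_multiplicity(x$substrate)))
  invisible(x)
}

#' Leaflet multiplicity of the supported layer
#'
#' Hydrophilic substrates (silicon dioxide, bare gold) template a supported
#' bilayer (two leaflets); hydrophobic substrates (alkanethiol-coated gold)
#' template a monolayer. The multiplicity scales the complete-layer mass and
#' hence the complete-layer frequency shift.
#'
#' @param substrate `"hydrophilic"` or `"hydrophobic"`, or a `thermo_params`
#'   object.
#' @return Integer leaflet count: 2 for hydrophilic, 1 for hydrophobic.
#' @export
substrate_multiplicity <- function(substrate) {
  if (inherits(substrate, "thermo_params")) substrate <- substrate$substrate
  substrate <- match.arg(substrate, c("hydrophilic", "hydrophobic"))
  if (substrate == "hydrophilic") 2L else 1L
}

#' System free energy of the partitioned lipid pool
#'
#' Free energy of a state in which `n_supported` of the `n_total` lipids
#' available for adsorption sit in the supported layer and the remainder in
#' suspended micelles/vesicles, in units of R*T per mole of the counting
#' unit. The mixing-entropy term is implemented exactly in the printed
#' two-logarithm form; its stationary point in `n_supported` is the logistic
#' equilibrium returned by [equilibrium_adsorbed_number()].
#'
#' @param n_supported number of lipids in the supported layer; must lie
#'   strictly inside (0, n_total). Vectorized.
#' @param n_total total number of lipids available for adsorption after
#'   solvent-exchange discounting (the pool xi * N0).
#' @param params a [thermo_params()] object; `mu_diff` enters as the
#'   suspended-lipid chemical potential with the supported-lipid potential
#'   pinned at zero.
#' @return Free energy in units of R*T (dimensionless), same length as
#'   `n_supported`.
#' @export
free_energy <- function(n_supported, n_total, params) {
  stopifnot(inherits(params, "thermo_params"))
  stopifnot(is.numeric(n_total), length(n_total) == 1L, n_total > 0)
  if (any(n_supported <= 0 | n_supported >= n_total)) {
    stop("`n_supported` must lie strictly between 0 and `n_total` ",
         "(logarithms undefined at the boundary)")
  }
  ns <- n_supported
  nmv <- n_total - ns
  mu <- params$mu_diff / rt_energy(params$temperature) # dimensionless
  # G/RT = (xi N0 - Ns) * mu_mv  -  [ xi N0 ln(xi N0 / Ns)
  #                                   + (xi N0 - Ns) ln(Ns / (xi N0 - Ns)) ]
  nmv * mu - (n_total * log(n_total / ns) + nmv * log(ns / nmv))
}

#' Equilibrium adsorbed fraction
#'
#' Fraction of the available lipid pool that sits in the supported layer at
#' equilibrium: the logistic 1 / (1 + exp(-(mu_mv - mu_s) / (R*T))). Strictly
#' increasing in `mu_diff`, strictly between 0 and 1, and equal to 1/2 when
#' the two states are degenerate.
#'
#' @inheritParams free_energy
#' @return A fraction in (0, 1).
#' @examples
#' equilibrium_adsorbed_fraction(thermo_params(585, 297.15)) # ~0.5589
#' @export
equilibrium_adsorbed_fraction <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  stats::plogis(params$mu_diff / rt_energy(params$temperature))
}

#' Equilibrium number of adsorbed lipids
#'
#' @inheritParams free_energy
#' @return `n_total` times [equilibrium_adsorbed_fraction()].
#' @export
equilibrium_adsorbed_number <- function(n_total, params) {
  stopifnot(is.numeric(n_total), all(n_total > 0))
  n_total * equilibrium_adsorbed_fraction(params)
}

#' Solvent-exchange profile
#'
#' Parameters of the exponential washout of the organic solvent: the lipid
#' concentration in the chamber decays as c(t) = c0 * exp(-k t) while the
#' aqueous buffer is infused, with k the flow rate over the chamber volume
#' (Q/V), over an exchange window of duration tau.
#'
#' @param flow_rate_over_volume decay rate k = Q/V in 1/s; strictly positive.
#' @param exchange_duration exchange window tau in s; strictly positive.
#' @return An object of class `exchange_profile`.
#' @export
exchange_profile <- function(flow_rate_over_volume, exchange_duration) {
  stopifnot(is.numeric(flow_rate_over_volume), length(flow_rate_over_volume) == 1L,
            is.numeric(exchange_duration), length(exchange_duration) == 1L)
  if (!is.finite(flow_rate_over_volume) || flow_rate_over_volume <= 0) {
    stop("`flow_rate_over_volume` must be strictly positive")
  }
  if (!is.finite(exchange_duration) || exchange_duration <= 0) {
    stop("`exchange_duration` must be strictly positive")
  }
  structure(
    list(flow_rate_over_volume = flow_rate_over_volume,
         exchange_duration = exchange_duration),
    class = "exchange_profile"
  )
}

#' Solvent-exchange scaling factor
#'
#' The scaling factor xi is the time average of the lipid concentration over
#' the exchange window divided by the initial concentration; it discounts the
#' lipid pool available for adsorption. Under the exponential washout model
#' c(t) = c0 * exp(-k t),
#' xi = (1 - exp(-k tau)) / (k tau), which tends to 1 as k*tau -> 0 (no
#' dilution) and decreases monotonically in k*tau. In practice xi is usually
#' supplied directly as a chamber constant (0.05 for the reference flow
#' cell); this calculator supports deriving it from flow parameters.
#'
#' @param profile an [exchange_profile()] object.
#' @return xi in (0, 1].
#' @examples
#' exchange_scaling_factor(exchange_profile(0.03, 100)) # k*tau = 3 -> ~0.3167
#' @export
exchange_scaling_factor <- function(profile) {
  stopifnot(inherits(profile, "exchange_profile"))
  kt <- profile$flow_rate_over_volume * profile$exchange_duration
  # expm1 keeps precision as k*tau -> 0, where xi -> 1
  -expm1(-kt) / kt
}
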