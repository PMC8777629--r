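#' Sauerbrey mass-frequency conversions
#'
#' For a thin rigid film the areal mass change is proportional to the
#' resonance frequency shift: delta_m = -C * delta_f, with C the sensor
#' constant. Adsorption gives a negative shift and a positive mass.
#'
#' @param delta_f frequency shift in Hz (negative for adsorbed mass).
#'   Vectorized.
#' @param chamber a [chamber_config()] supplying the Sauerbrey constant C.
#' @return `sauerbrey_mass()`: areal mass density in ng/cm^2;
#'   `sauerbrey_shift()`: frequency shift in Hz. The two are exact inverses.
#' @examples
#' sauerbrey_mass(-25, dopc_chamber()) # 442.5 ng/cm^2
#' @export
sauerbrey_mass <- function(delta_f, chamber) {
  stopifnot(inherits(chamber, "chamber_config"), is.numeric(delta_f))
  -chamber$sauerbrey_constant * delta_f
}

#' @rdname sauerbrey_mass
#' @param delta_m areal mass density in ng/cm^2. Vectorized.
#' @export
sauerbrey_shift <- function(delta_m, chamber) {
  stopifnot(inherits(chamber, "chamber_config"), is.numeric(delta_m))
  -delta_m / chamber$sauerbrey_constant
}

#' Temperature-dependent area per lipid
#'
#' The mean in-plane area per lipid molecule (APL) grows linearly with
#' temperature within each phase and jumps at the main transition:
#' a0 = apl_gel - slope_gel * (Tm - T) below Tm, and
#' a0 = apl_fluid + slope_fluid * (T - Tm) at and above Tm (T = Tm is on the
#' fluid branch).
#'
#' @param lipid a [lipid_species()] object.
#' @param temperature absolute temperature in K. Vectorized.
#' @return APL in square Angstrom.
#' @examples
#' area_per_lipid(dppc(), 297) # 47.5 - 0.06 * 17 = 46.48
#' @export
area_per_lipid <- function(lipid, temperature) {
  stopifnot(inherits(lipid, "lipid_species"), is.numeric(temperature))
  if (any(temperature <= 0)) stop("`temperature` must be positive (K)")
  tm <- lipid$transition_temperature
  a0 <- ifelse(temperature < tm,
               lipid$apl_gel - lipid$apl_slope_gel * (tm - temperature),
               lipid$apl_fluid + lipid$apl_slope_fluid * (temperature - tm))
  if (any(a0 <= 0)) {
    stop("gel-branch APL is nonpositive: temperature is outside the ",
         "linearization's range of validity")
  }
  a0
}

#' Complete-layer frequency shift from area per lipid
#'
#' Frequency shift of a full-coverage supported layer:
#' delta_fc = -(b * M) / (NA * C * a0), where b is the leaflet multiplicity
#' (2 for a bilayer on a hydrophilic substrate, 1 for a monolayer on a
#' hydrophobic one). Denser packing (smaller a0) gives a larger magnitude
#' shift; the value is always negative.
#'
#' @inheritParams area_per_lipid
#' @param a0 area per lipid in square Angstrom. Vectorized.
#' @param chamber a [chamber_config()] object.
#' @param substrate `"hydrophilic"` or `"hydrophobic"` (or a
#'   [thermo_params()] object, from which the substrate is taken).
#' @return Frequency shift delta_fc in Hz (negative).
#' @export
complete_shift_from_apl <- function(lipid, a0, chamber,
                                    substrate = "hydrophilic") {
  stopifnot(inherits(lipid, "lipid_species"),
            inherits(chamber, "chamber_config"), is.numeric(a0))
  if (any(!is.finite(a0) | a0 <= 0)) stop("`a0` must be strictly positive")
  b <- substrate_multiplicity(substrate)
  a0_cm2 <- a0 * salb_constants$A2_to_cm2
  mass_ng_cm2 <- b * lipid$molecular_weight /
    (salb_constants$N_avogadro * a0_cm2) * salb_constants$g_to_ng
  sauerbrey_shift(mass_ng_cm2, chamber)
}

#' Complete-layer frequency shift as a function of temperature
#'
#' Composition of [area_per_lipid()] with [complete_shift_from_apl()]:
#' |delta_fc| decreases with temperature within each phase (APL expands) and
#' drops discontinuously at Tm by the factor apl_fluid / apl_gel.
#'
#' @inheritParams complete_shift_from_apl
#' @param temperature absolute temperature in K. Vectorized.
#' @return Frequency shift delta_fc in Hz (negative).
#' @examples
#' complete_shift_at_temperature(dppc(), 297, dopc_chamber()) # ~ -29.6 Hz
#' @export
complete_shift_at_temperature <- function(lipid, temperature, chamber,
                                          substrate = "hydrophilic") {
  complete_shift_from_apl(lipid, area_per_lipid(lipid, temperature),
                          chamber, substrate)
}

# linear coverage-per-concentration prefactor K = V*xi / (C*A*|delta_fc|),
# in coverage per (mg/mL); all unit conversion lives here
coverage_prefactor <- function(delta_fc, chamber) {
  stopifnot(inherits(chamber, "chamber_config"))
  if (any(!is.finite(delta_fc) | delta_fc >= 0)) {
    stop("`delta_fc` must be a finite negative frequency shift (Hz)")
  }
  v_cm3 <- chamber$chamber_volume * salb_constants$mm3_to_cm3
  a_cm2 <- chamber$sensor_area * salb_constants$mm2_to_cm2
  v_cm3 * chamber$exchange_factor * salb_constants$mg_per_ml_to_ng_per_cm3 /
    (chamber$sauerbrey_constant * a_cm2 * abs(delta_fc))
}

#' Slope of coverage versus initial lipid concentration
#'
#' The model predicts coverage linear in the initial lipid concentration c0
#' with slope K * p, where K = V*xi / (C*A*|delta_fc|) collects the chamber
#' constants and p is the equilibrium adsorbed fraction. With the reference
#' DOPC constants and mu_mv - mu_s = 585 J/mol at 297.15 K the slope is
#' about 3.776 per (mg/mL).
#'
#' @param delta_fc complete-layer frequency shift in Hz (negative).
#' @param chamber a [chamber_config()] object.
#' @param params a [thermo_params()] object.
#' @return Coverage per (mg/mL).
#' @export
coverage_slope <- function(delta_fc, chamber, params) {
  coverage_prefactor(delta_fc, chamber) * equilibrium_adsorbed_fraction(params)
}

#' Predict SLB coverage from initial lipid concentration
#'
#' Coverage is the ratio delta_f / delta_fc of the measured frequency shift
#' to the complete-layer shift; the model gives
#' coverage = K * p * c0 (see [coverage_slope()]). The raw (uncapped) value
#' is reported alongside a value clipped to [0, 1]; raw coverage above 1
#' indicates a supersaturated layer.
#'
#' @param c0 initial lipid concentration(s) in mg/mL; nonnegative.
#' @inheritParams coverage_slope
#' @return A data frame with columns `concentration_mg_per_ml`,
#'   `coverage_raw` and `coverage_clipped`.
#' @examples
#' predict_coverage(0.25, -25, dopc_chamber(), thermo_params(585, 297.15))
#' @export
predict_coverage <- function(c0, delta_fc, chamber, params) {
  stopifnot(is.numeric(c0))
  if (any(!is.finite(c0) | c0 < 0)) stop("`c0` must be nonnegative (mg/mL)")
  raw <- coverage_slope(delta_fc, chamber, params) * c0
  data.frame(concentration_mg_per_ml = c0,
             coverage_raw = raw,
             coverage_clipped = pmin(pmax(raw, 0), 1))
}

#' SLB coverage as a function of temperature and concentration
#'
#' The general coverage expression: the complete-layer shift is evaluated at
#' the requested temperature through the APL model and combined with the
#' equilibrium adsorbed fraction, so coverage responds to temperature both
#' through the thermal energy R*T and through lipid packing. Equals
#' [predict_coverage()] composed with [complete_shift_at_temperature()]; the
#' layer-multiplicity factor is taken from the substrate class in `params`.
#' The explicit `temperature` overrides the one stored in `params`, so a
#' single temperature drives both the thermal energy and the lipid packing.
#'
#' @inheritParams predict_coverage
#' @param lipid a [lipid_species()] object.
#' @param temperature absolute temperature in K (scalar here; vectorize over
#'   `c0`).
#' @return A data frame as in [predict_coverage()], with an added
#'   `temperature_K` column.
#' @export
coverage_general <- function(c0, lipid, temperature, chamber, params) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  p_at_t <- thermo_params(params$mu_diff, temperature, params$substrate)
  dfc <- complete_shift_at_temperature(lipid, temperature, chamber,
                                       params$substrate)
  out <- predict_coverage(c0, dfc, chamber, p_at_t)
  out$temperature_K <- temperature
  out[c("temperature_K", "concentration_mg_per_ml",
        "coverage_raw", "coverage_clipped")]
}

#' Minimum concentration for full SLB coverage
#'
#' The initial lipid concentration at which predicted coverage reaches
#' exactly 1:
#' cmin = (b * M * A) / (NA * V * xi) * (1 + exp(-(mu_mv - mu_s)/(R*T))) / a0(T),
#' in mg/mL. Decreases with temperature within each phase and drops at Tm.
#'
#' @inheritParams coverage_general
#' @param temperature absolute temperature in K. Vectorized.
#' @return cmin in mg/mL.
#' @examples
#' min_concentration(dppc(), 297, dopc_chamber(), thermo_params(1000, 297))
#' @export
min_concentration <- function(lipid, temperature, chamber, params) {
  vapply(temperature, function(tt) {
    p_at_t <- thermo_params(params$mu_diff, tt, params$substrate)
    dfc <- complete_shift_at_temperature(lipid, tt, chamber, params$substrate)
    1 / coverage_slope(dfc, chamber, p_at_t)
  }, numeric(1))
}
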