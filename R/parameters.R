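#' Lipid species parameters
#'
#' Physical constants of a phospholipid species needed by the coverage model:
#' molecular weight, main (gel-to-fluid) transition temperature, and the
#' piecewise-linear area-per-lipid (APL) parameterization around the
#' transition: APL at Tm and the thermal expansion slope, one pair per phase.
#'
#' @param name species label, e.g. `"DPPC"`.
#' @param molecular_weight molar mass M in g/mol.
#' @param transition_temperature main transition temperature Tm in K.
#' @param apl_gel APL at Tm approached from the gel phase, in square Angstrom.
#' @param apl_fluid APL at Tm in the fluid phase, in square Angstrom; at least
#'   `apl_gel` (chains disorder across the transition).
#' @param apl_slope_gel APL slope below Tm, square Angstrom per K.
#' @param apl_slope_fluid APL slope at and above Tm, square Angstrom per K.
#' @return An object of class `lipid_species`.
#' @seealso [dppc()] for the packaged DPPC parameter set.
#' @export
lipid_species <- function(name, molecular_weight, transition_temperature,
                          apl_gel, apl_fluid,
                          apl_slope_gel, apl_slope_fluid) {
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single positive number", what))
    }
    as.numeric(x)
  }
  out <- structure(
    list(name = as.character(name),
         molecular_weight = num1(molecular_weight, "molecular_weight"),
         transition_temperature = num1(transition_temperature,
                                       "transition_temperature"),
         apl_gel = num1(apl_gel, "apl_gel"),
         apl_fluid = num1(apl_fluid, "apl_fluid"),
         apl_slope_gel = num1(apl_slope_gel, "apl_slope_gel"),
         apl_slope_fluid = num1(apl_slope_fluid, "apl_slope_fluid")),
    class = "lipid_species"
  )
  if (out$apl_fluid < out$apl_gel) {
    stop("`apl_fluid` must be >= `apl_gel` (APL expands across the transition)")
  }
  out
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("Lipid species: %s\n", x$name))
  cat(sprintf("  M  = %g g/mol, Tm = %g K\n",
              x$molecular_weight, x$transition_temperature))
  cat(sprintf("  APL at Tm: gel %g, fluid %g (Angstrom^2)\n",
              x$apl_gel, x$apl_fluid))
  cat(sprintf("  APL slope: gel %g, fluid %g (Angstrom^2/K)\n",
              x$apl_slope_gel, x$apl_slope_fluid))
  invisible(x)
}

#' DPPC parameter set
#'
#' 1,2-dipalmitoyl-sn-glycero-3-phosphocholine: M = 734.039 g/mol,
#' Tm = 314 K, gel/fluid APL at Tm of 47.5 / 61.3 square Angstrom, with
#' thermal APL slopes 0.06 (gel) and 0.2 (fluid) square Angstrom per K.
#'
#' @return A [lipid_species()] object.
#' @export
dppc <- function() {
  lipid_species(
    name = "DPPC",
    molecular_weight = 734.039,
    transition_temperature = 314,
    apl_gel = 47.5,
    apl_fluid = 61.3,
    apl_slope_gel = 0.06,
    apl_slope_fluid = 0.2
  )
}

#' QCM-D flow-cell and sensor configuration
#'
#' @param chamber_volume fluidic chamber volume V in cubic mm.
#' @param sensor_area active quartz crystal area A in square mm.
#' @param sauerbrey_constant sensor mass-sensitivity constant C in
#'   ng cm^-2 Hz^-1.
#' @param exchange_factor solvent-exchange scaling factor xi in (0, 1]; the
#'   fraction of the initial lipid pool effectively available for adsorption.
#'   See [exchange_scaling_factor()] for a washout-model calculator.
#' @return An object of class `chamber_config`.
#' @seealso [dopc_chamber()] for the reference flow-cell constants.
#' @export
chamber_config <- function(chamber_volume, sensor_area,
                           sauerbrey_constant, exchange_factor) {
  vals <- c(chamber_volume = chamber_volume, sensor_area = sensor_area,
            sauerbrey_constant = sauerbrey_constant,
            exchange_factor = exchange_factor)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all chamber parameters must be finite and strictly positive")
  }
  if (exchange_factor > 1) {
    stop("`exchange_factor` must lie in (0, 1]")
  }
  structure(as.list(vals), class = "chamber_config")
}

#' @export
print.chamber_config <- function(x, ...) {
  cat("QCM-D chamber configuration\n")
  cat(sprintf("  V  = %g mm^3, A = %g mm^2\n",
              x$chamber_volume, x$sensor_area))
  cat(sprintf("  C  = %g ng cm^-2 Hz^-1, xi = %g\n",
              x$sauerbrey_constant, x$exchange_factor))
  invisible(x)
}

#' Reference flow-cell constants from the DOPC calibration experiment
#'
#' V = 58 mm^3, A = 97 mm^2, C = 17.7 ng cm^-2 Hz^-1, xi = 0.05 — the
#' silicon-dioxide-coated sensor setup in which a complete DOPC bilayer gave
#' a -25 Hz shift.
#'
#' @return A [chamber_config()] object.
#' @export
dopc_chamber <- function() {
  chamber_config(chamber_volume = 58, sensor_area = 97,
                 sauerbrey_constant = 17.7, exchange_factor = 0.05)
}

# ---- JSON parameter I/O (unit-suffixed keys make unit errors loud) --------

lipid_json_keys <- c(
  name                        = "name",
  molecular_weight            = "molecular_weight_g_per_mol",
  transition_temperature      = "transition_temperature_K",
  apl_gel                     = "apl_gel_A2",
  apl_fluid                   = "apl_fluid_A2",
  apl_slope_gel               = "apl_slope_gel_A2_per_K",
  apl_slope_fluid             = "apl_slope_fluid_A2_per_K"
)

chamber_json_keys <- c(
  chamber_volume     = "chamber_volume_mm3",
  sensor_area        = "sensor_area_mm2",
  sauerbrey_constant = "sauerbrey_constant_ng_per_cm2_per_hz",
  exchange_factor    = "exchange_factor"
)

thermo_json_keys <- c(
  mu_diff     = "mu_diff_J_per_mol",
  temperature = "temperature_K",
  substrate   = "substrate"
)

read_keyed_json <- function(path, keys, what) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(unname(keys), names(raw))
  if (length(missing)) {
    stop(sprintf("%s file '%s' is missing required key(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  }
  stats::setNames(raw[unname(keys)], names(keys))
}

write_keyed_json <- function(x, path, keys) {
  out <- stats::setNames(x[names(keys)], unname(keys))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write parameter-set JSON files
#'
#' Parameter files use unit-suffixed keys (`chamber_volume_mm3`,
#' `mu_diff_J_per_mol`, ...) so that unit mistakes are caught at the file
#' boundary. Missing keys raise an error naming them.
#'
#' @param path file path.
#' @return The corresponding parameter object; writers return `path`
#'   invisibly.
#' @name parameter_json
#' @export
read_lipid_json <- function(path) {
  v <- read_keyed_json(path, lipid_json_keys, "lipid")
  do.call(lipid_species, v)
}

#' @rdname parameter_json
#' @param lipid a [lipid_species()] object.
#' @export
write_lipid_json <- function(lipid, path) {
  stopifnot(inherits(lipid, "lipid_species"))
  write_keyed_json(lipid, path, lipid_json_keys)
}

#' @rdname parameter_json
#' @export
read_chamber_json <- function(path) {
  v <- read_keyed_json(path, chamber_json_keys, "chamber")
  do.call(chamber_config, lapply(v, as.numeric))
}

#' @rdname parameter_json
#' @param chamber a [chamber_config()] object.
#' @export
write_chamber_json <- function(chamber, path) {
  stopifnot(inherits(chamber, "chamber_config"))
  write_keyed_json(chamber, path, chamber_json_keys)
}

#' @rdname parameter_json
#' @export
read_thermo_json <- function(path) {
  v <- read_keyed_json(path, thermo_json_keys, "thermo")
  thermo_params(mu_diff = as.numeric(v$mu_diff),
                temperature = as.numeric(v$temperature),
                substrate = as.character(v$substrate))
}

#' @rdname parameter_json
#' @param params a [thermo_params()] object.
#' @export
write_thermo_json <- function(params, path) {
  stopifnot(inherits(params, "thermo_params"))
  write_keyed_json(params, path, thermo_json_keys)
}
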