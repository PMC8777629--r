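sig9 <- function(x) signif(x, 9)

resolve_lipid <- function(lipid) {
  if (inherits(lipid, "lipid_species")) lipid else read_lipid_json(lipid)
}
resolve_chamber <- function(chamber) {
  if (inherits(chamber, "chamber_config")) chamber else read_chamber_json(chamber)
}
resolve_thermo <- function(params) {
  if (inherits(params, "thermo_params")) params else read_thermo_json(params)
}

#' File-level pipeline commands
#'
#' Thin file-in/file-out wrappers binding the model, fitting, phase-diagram
#' and simulation stages; these back the `inst/cli/salb.R` command-line
#' dispatcher but are equally usable from R. Parameter arguments accept
#' either the in-memory objects or paths to the corresponding JSON files.
#' All numeric output is serialized with 9 significant digits for
#' reproducible diffs, and every command writes/returns the resolved
#' parameter set alongside its results.
#'
#' @param dataset_csv endpoint dataset CSV (schema
#'   `concentration_mg_per_ml,replicate,delta_f_hz`) with its JSON metadata
#'   sidecar.
#' @param out output file path.
#' @param metadata_path metadata sidecar path (defaults to
#'   `<dataset_csv>.json`).
#' @param bootstrap,seed bootstrap settings passed to
#'   [fit_mu_difference()].
#' @return `run_fit()`: the fit report list, invisibly (also written as
#'   JSON).
#' @name run_commands
#' @export
run_fit <- function(dataset_csv, out = NULL,
                    metadata_path = paste0(dataset_csv, ".json"),
                    bootstrap = 0, seed = NULL) {
  dataset <- read_coverage_csv(dataset_csv, metadata_path)
  fit <- fit_mu_difference(dataset, bootstrap = bootstrap, seed = seed)
  chamber <- attr(dataset, "chamber")
  report <- list(
    inputs = list(
      dataset = dataset_csv,
      n_rows = nrow(dataset),
      lipid = attr(dataset, "lipid"),
      temperature_K = sig9(attr(dataset, "temperature")),
      complete_shift_hz = sig9(attr(dataset, "complete_shift")),
      chamber_volume_mm3 = sig9(chamber$chamber_volume),
      sensor_area_mm2 = sig9(chamber$sensor_area),
      sauerbrey_constant_ng_per_cm2_per_hz = sig9(chamber$sauerbrey_constant),
      exchange_factor = sig9(chamber$exchange_factor)
    ),
    fit = list(
      slope_per_mg_per_ml = sig9(fit$slope),
      slope_se = sig9(fit$slope_se),
      mu_diff_J_per_mol = sig9(fit$mu_diff),
      mu_diff_se_J_per_mol = sig9(fit$mu_diff_se),
      mu_diff_se_boot_J_per_mol =
        if (is.finite(fit$mu_diff_se_boot)) sig9(fit$mu_diff_se_boot) else NULL,
      r_squared = sig9(fit$r_squared),
      n_points = fit$n_points,
      implied_fraction = sig9(fit$fraction),
      near_saturated = fit$near_saturated,
      intercept_diagnostic = sig9(fit$intercept_diagnostic)
    )
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' @rdname run_commands
#' @param lipid a [lipid_species()] or path to a lipid JSON.
#' @param chamber a [chamber_config()] or path to a chamber JSON.
#' @param params a [thermo_params()] or path to a thermo JSON.
#' @param concentrations concentration list in mg/mL.
#' @param temperature evaluation temperature in K; defaults to the one in
#'   `params`.
#' @param rule a [regime_rule()].
#' @return `run_predict()`: data frame of raw/clipped coverage and regime
#'   per concentration, invisibly (written as CSV when `out` is given).
#' @export
run_predict <- function(lipid, chamber, params, concentrations,
                        temperature = NULL, out = NULL,
                        rule = regime_rule()) {
  lipid <- resolve_lipid(lipid)
  chamber <- resolve_chamber(chamber)
  params <- resolve_thermo(params)
  if (is.null(temperature)) temperature <- params$temperature
  tab <- coverage_general(concentrations, lipid, temperature, chamber, params)
  tab$regime <- classify_regime(tab$coverage_raw, rule)
  tab$coverage_raw <- sig9(tab$coverage_raw)
  tab$coverage_clipped <- sig9(tab$coverage_clipped)
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  invisible(tab)
}

#' @rdname run_commands
#' @param temperatures temperature axis for the phase diagram / cmin table,
#'   K.
#' @return `run_phase_diagram()`: the `phase_diagram` object, invisibly
#'   (grid written as long CSV when `out` is given).
#' @export
run_phase_diagram <- function(lipid, chamber, params,
                              temperatures = seq(290, 330, by = 0.5),
                              concentrations = seq(0, 1, by = 0.01),
                              rule = regime_rule(), out = NULL) {
  lipid <- resolve_lipid(lipid)
  chamber <- resolve_chamber(chamber)
  params <- resolve_thermo(params)
  pd <- build_phase_diagram(lipid, chamber, params, temperatures,
                            concentrations, rule)
  if (!is.null(out)) export_grid(pd, out)
  invisible(pd)
}

#' @rdname run_commands
#' @param mu_diff_true,complete_shift,replicates,noise_sd simulation
#'   settings; see [generator_spec()].
#' @return `run_simulate()`: the simulated [coverage_dataset()], invisibly
#'   (CSV plus JSON sidecar written when `out` is given).
#' @export
run_simulate <- function(lipid, chamber, mu_diff_true, seed,
                         temperature = 297.15, complete_shift = -25,
                         concentrations = seq(0.025, 0.25, length.out = 8),
                         replicates = 5, noise_sd = 1, out = NULL) {
  # a character `lipid` may be a JSON path or a bare label
  if (is.character(lipid) && file.exists(lipid)) lipid <- read_lipid_json(lipid)
  chamber <- resolve_chamber(chamber)
  spec <- generator_spec(lipid, chamber, mu_diff_true,
                         temperature = temperature,
                         complete_shift = complete_shift,
                         concentrations = concentrations,
                         replicates = replicates,
                         noise_sd = noise_sd, seed = seed)
  dataset <- generate_endpoint_dataset(spec)
  if (!is.null(out)) write_coverage_csv(dataset, out)
  invisible(dataset)
}

#' @rdname run_commands
#' @return `run_cmin()`: data frame of minimum concentration versus
#'   temperature, invisibly (written as CSV when `out` is given).
#' @export
run_cmin <- function(lipid, chamber, params,
                     temperatures = seq(290, 330, by = 0.5), out = NULL) {
  lipid <- resolve_lipid(lipid)
  chamber <- resolve_chamber(chamber)
  params <- resolve_thermo(params)
  tab <- data.frame(
    temperature_K = temperatures,
    cmin_mg_per_ml = sig9(min_concentration(lipid, temperatures, chamber,
                                            params))
  )
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  invisible(tab)
}
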