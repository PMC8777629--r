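#' Specification for a synthetic endpoint experiment
#'
#' Describes a simulated solvent-exchange endpoint experiment: a series of
#' initial lipid concentrations, each measured in replicate, with i.i.d.
#' Gaussian noise added to the frequency shifts. Noise lives in the
#' measurement domain (Hz on delta_f), not on coverage. Defaults mirror the
#' reference DOPC calibration: eight concentrations spanning
#' 0.025-0.25 mg/mL, five replicates, 1 Hz noise.
#'
#' @param lipid a [lipid_species()] object, or a bare character label: the
#'   endpoint generator uses only the name (coverage is driven by the
#'   complete shift, not the APL model).
#' @param chamber a [chamber_config()] object.
#' @param mu_diff_true true chemical-potential difference in J/mol.
#' @param temperature experiment temperature in K.
#' @param complete_shift complete-layer shift delta_fc in Hz (negative).
#' @param concentrations concentration series in mg/mL.
#' @param replicates replicates per concentration (>= 1).
#' @param noise_sd Gaussian noise standard deviation on delta_f, in Hz
#'   (>= 0).
#' @param seed RNG seed; mandatory whenever `noise_sd > 0`.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(lipid, chamber, mu_diff_true,
                           temperature = 297.15,
                           complete_shift = -25,
                           concentrations = seq(0.025, 0.25, length.out = 8),
                           replicates = 5,
                           noise_sd = 1,
                           seed = NULL) {
  if (is.character(lipid) && length(lipid) == 1L) {
    lipid <- structure(list(name = lipid), class = "lipid_label")
  }
  stopifnot(inherits(lipid, "lipid_species") || inherits(lipid, "lipid_label"),
            inherits(chamber, "chamber_config"),
            is.numeric(mu_diff_true), length(mu_diff_true) == 1L,
            is.finite(mu_diff_true),
            is.numeric(temperature), temperature > 0,
            is.numeric(complete_shift), complete_shift < 0,
            is.numeric(concentrations), length(concentrations) >= 1L,
            all(concentrations >= 0))
  if (!is.numeric(replicates) || replicates < 1) {
    stop("`replicates` must be >= 1")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0")
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("`seed` is mandatory for stochastic output (noise_sd > 0)")
  }
  structure(
    list(lipid = lipid, chamber = chamber,
         mu_diff_true = as.numeric(mu_diff_true),
         temperature = as.numeric(temperature),
         complete_shift = as.numeric(complete_shift),
         concentrations = as.numeric(concentrations),
         replicates = as.integer(replicates),
         noise_sd = as.numeric(noise_sd),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_spec"
  )
}

#' Generate a synthetic endpoint dataset
#'
#' Simulates the endpoint frequency shifts of a coverage-versus-
#' concentration experiment from the linear coverage model with a known
#' true chemical-potential difference:
#' delta_f = coverage(c0; mu_true) * delta_fc + noise. The result is a
#' [coverage_dataset()] ready for [fit_mu_difference()], with the generating
#' truth stored in its `truth` attribute for recovery tests. Deterministic
#' given (spec, seed).
#'
#' @param spec a [generator_spec()].
#' @return A [coverage_dataset()] with a `truth` attribute.
#' @export
generate_endpoint_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  params <- thermo_params(spec$mu_diff_true, spec$temperature)
  cov <- predict_coverage(spec$concentrations, spec$complete_shift,
                          spec$chamber, params)$coverage_raw
  c0 <- rep(spec$concentrations, each = spec$replicates)
  rep_id <- rep(seq_len(spec$replicates), times = length(spec$concentrations))
  df_clean <- rep(cov, each = spec$replicates) * spec$complete_shift
  noise <- 0
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    noise <- stats::rnorm(length(df_clean), sd = spec$noise_sd)
  }
  out <- coverage_dataset(
    data.frame(concentration_mg_per_ml = c0,
               replicate = rep_id,
               delta_f_hz = df_clean + noise),
    temperature = spec$temperature,
    complete_shift = spec$complete_shift,
    chamber = spec$chamber,
    lipid = spec$lipid$name
  )
  attr(out, "truth") <- list(mu_diff_true = spec$mu_diff_true,
                             noise_sd = spec$noise_sd,
                             seed = spec$seed)
  out
}

#' Generate a temperature series of complete-layer shifts and cmin
#'
#' Evaluates the complete-layer frequency shift and the minimum
#' concentration for full coverage over a list of temperatures, optionally
#' adding Gaussian measurement noise to the shifts. A series straddling the
#' lipid's transition temperature contains exactly one discontinuity in both
#' columns.
#'
#' @param lipid a [lipid_species()] object.
#' @param chamber a [chamber_config()] object.
#' @param params a [thermo_params()] object (mu_diff and substrate are used;
#'   each row's temperature comes from `temperatures`).
#' @param temperatures temperature list in K.
#' @param noise_sd Gaussian noise SD on delta_fc, Hz (default 0:
#'   deterministic).
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @return A data frame with columns `temperature_K`, `delta_fc_hz`,
#'   `cmin_mg_per_ml`.
#' @export
generate_temperature_series <- function(lipid, chamber, params, temperatures,
                                        noise_sd = 0, seed = NULL) {
  stopifnot(inherits(lipid, "lipid_species"),
            inherits(chamber, "chamber_config"),
            inherits(params, "thermo_params"),
            is.numeric(temperatures), length(temperatures) >= 1L,
            all(temperatures > 0))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (noise_sd > 0 && is.null(seed)) {
    stop("`seed` is mandatory for stochastic output (noise_sd > 0)")
  }
  dfc <- complete_shift_at_temperature(lipid, temperatures, chamber,
                                       params$substrate)
  if (noise_sd > 0) {
    set.seed(seed)
    dfc <- dfc + stats::rnorm(length(dfc), sd = noise_sd)
  }
  data.frame(
    temperature_K = temperatures,
    delta_fc_hz = dfc,
    cmin_mg_per_ml = min_concentration(lipid, temperatures, chamber, params)
  )
}

#' Generate a solvent washout concentration trace
#'
#' Samples the relative lipid concentration c(t)/c0 = exp(-k t) on a uniform
#' time grid over the exchange window. The trapezoid-rule mean of the trace
#' converges to the analytic solvent-exchange scaling factor
#' [exchange_scaling_factor()] as the grid is refined.
#'
#' @param profile an [exchange_profile()].
#' @param n_steps number of grid intervals (>= 1); the trace has
#'   `n_steps + 1` samples.
#' @return A data frame with columns `time_s` and `relative_concentration`.
#' @export
generate_washout_trace <- function(profile, n_steps = 1e4) {
  stopifnot(inherits(profile, "exchange_profile"))
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1) {
    stop("`n_steps` must be a positive integer")
  }
  tt <- seq(0, profile$exchange_duration, length.out = n_steps + 1)
  data.frame(time_s = tt,
             relative_concentration = exp(-profile$flow_rate_over_volume * tt))
}
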