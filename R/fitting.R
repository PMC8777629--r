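salb_error <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "salb_error"),
                      call = call))
}

#' QCM-D coverage-versus-concentration endpoint dataset
#'
#' Tabular endpoint measurements: the final frequency shift reached at each
#' initial lipid concentration, possibly with replicates, together with the
#' metadata needed to convert shifts to coverage (the complete-layer shift,
#' the chamber constants and the temperature of the experiment).
#'
#' @param data a data frame with columns `concentration_mg_per_ml`
#'   (nonnegative), `replicate` and `delta_f_hz`.
#' @param temperature experiment temperature in K.
#' @param complete_shift complete-layer frequency shift delta_fc in Hz
#'   (negative).
#' @param chamber a [chamber_config()] object.
#' @param lipid lipid label (character).
#' @return An object of class `coverage_dataset` (a data frame with metadata
#'   attributes).
#' @export
coverage_dataset <- function(data, temperature, complete_shift, chamber,
                             lipid = "unknown") {
  required <- c("concentration_mg_per_ml", "replicate", "delta_f_hz")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    salb_error("salb_schema_error",
               sprintf("dataset is missing column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  bad <- which(!is.finite(data$concentration_mg_per_ml) |
                 data$concentration_mg_per_ml < 0)
  if (length(bad)) {
    salb_error("salb_schema_error",
               sprintf("nonnegative finite concentrations required; bad row(s): %s",
                       paste(bad, collapse = ", ")))
  }
  bad <- which(!is.finite(data$delta_f_hz))
  if (length(bad)) {
    salb_error("salb_schema_error",
               sprintf("finite frequency shifts required; bad row(s): %s",
                       paste(bad, collapse = ", ")))
  }
  stopifnot(inherits(chamber, "chamber_config"),
            is.numeric(temperature), temperature > 0)
  if (!is.finite(complete_shift) || complete_shift >= 0) {
    salb_error("salb_schema_error",
               "`complete_shift` must be a negative frequency shift (Hz)")
  }
  out <- as.data.frame(data)[required]
  attr(out, "temperature") <- as.numeric(temperature)
  attr(out, "complete_shift") <- as.numeric(complete_shift)
  attr(out, "chamber") <- chamber
  attr(out, "lipid") <- as.character(lipid)
  class(out) <- c("coverage_dataset", "data.frame")
  out
}

#' @export
print.coverage_dataset <- function(x, ...) {
  cat(sprintf("QCM-D endpoint dataset: %s, %d rows, %d concentration(s)\n",
              attr(x, "lipid"), nrow(x),
              length(unique(x$concentration_mg_per_ml))))
  cat(sprintf("  T = %g K, delta_fc = %g Hz\n",
              attr(x, "temperature"), attr(x, "complete_shift")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Coverage from a measured frequency shift
#'
#' Coverage is the ratio of the measured shift to the complete-layer shift,
#' delta_f / delta_fc; both are negative for adsorption, so the ratio is a
#' positive fraction (1 at complete coverage).
#'
#' @param shift measured frequency shift delta_f in Hz. Vectorized.
#' @param complete_shift complete-layer shift delta_fc in Hz; must be
#'   negative.
#' @return Dimensionless coverage.
#' @export
coverage_from_shift <- function(shift, complete_shift) {
  if (!is.numeric(complete_shift) || length(complete_shift) != 1L ||
      !is.finite(complete_shift) || complete_shift >= 0) {
    salb_error("salb_schema_error",
               "`complete_shift` must be a single negative value (Hz)")
  }
  shift / complete_shift
}

#' Infer the chemical-potential difference from endpoint data
#'
#' Fits the linear coverage model to an endpoint dataset: each measured
#' shift is converted to coverage delta_f / delta_fc, the through-origin
#' least-squares slope s against concentration is computed (the model line
#' passes through the origin by construction), and the slope is inverted for
#' the chemical-potential difference via the logistic link:
#' with K = V*xi / (C*A*|delta_fc|) the implied adsorbed fraction is
#' f = s / K and mu_mv - mu_s = R*T * log(f / (1 - f)). The standard error
#' of mu is propagated from the slope standard error by the delta method,
#' d(mu)/d(s) = R*T * K / (s * (K - s)); optionally a seeded residual
#' bootstrap gives a resampling-based standard error.
#'
#' A free-intercept diagnostic fit is also run and reported in the result
#' (but never used for mu). Fits whose implied fraction exceeds 0.999 are
#' flagged `near_saturated`: mu is numerically unstable there because the
#' logistic link is nearly flat.
#'
#' @param dataset a [coverage_dataset()].
#' @param bootstrap number of residual-bootstrap draws for the mu standard
#'   error (0 disables; 1000 is typical).
#' @param seed RNG seed for the bootstrap (required when `bootstrap > 0`).
#' @return An object of class `salb_fit`: slope and slope SE (per mg/mL),
#'   `mu_diff` and `mu_diff_se` (J/mol), uncentered `r_squared`, `n_points`,
#'   the prefactor `K`, the implied fraction, the diagnostic intercept fit,
#'   and flags.
#' @export
fit_mu_difference <- function(dataset, bootstrap = 0, seed = NULL) {
  stopifnot(inherits(dataset, "coverage_dataset"))
  x <- dataset$concentration_mg_per_ml
  y <- coverage_from_shift(dataset$delta_f_hz, attr(dataset, "complete_shift"))
  if (sum(x > 0) < 2L || length(unique(x[x > 0])) < 2L) {
    salb_error("salb_insufficient_data_error",
               "need at least 2 distinct positive concentrations to fit")
  }

  fit0 <- stats::lm(y ~ 0 + x)
  s <- unname(stats::coef(fit0)[["x"]])
  rss <- sum(stats::residuals(fit0)^2)
  # through-origin slope SE (n - 1 residual df); avoids summary()'s
  # perfect-fit warning on noiseless data
  se_s <- sqrt(rss / (length(y) - 1L) / sum(x^2))
  # uncentered R^2 (regression through the origin)
  r2 <- 1 - rss / sum(y^2)

  temperature <- attr(dataset, "temperature")
  K <- coverage_prefactor(attr(dataset, "complete_shift"),
                          attr(dataset, "chamber"))
  if (!is.finite(s) || s <= 0) {
    salb_error("salb_identifiability_error",
               "fitted slope is nonpositive: no finite chemical-potential difference")
  }
  if (s >= K) {
    salb_error("salb_identifiability_error",
               sprintf(paste0("fitted slope %.4g implies adsorbed fraction >= 1 ",
                              "(prefactor K = %.4g): unphysical, mu is not finite"),
                       s, K))
  }
  f <- s / K
  rt <- rt_energy(temperature)
  mu <- rt * log(f / (1 - f))
  dmu_ds <- rt * K / (s * (K - s))
  mu_se <- abs(dmu_ds) * se_s

  boot_se <- NA_real_
  if (bootstrap > 0) {
    if (is.null(seed)) {
      salb_error("salb_schema_error", "`seed` is required when bootstrapping")
    }
    fitted0 <- stats::fitted(fit0)
    res0 <- stats::residuals(fit0)
    set.seed(seed)
    draws <- vapply(seq_len(bootstrap), function(i) {
      yb <- fitted0 + sample(res0, length(res0), replace = TRUE)
      sb <- sum(x * yb) / sum(x^2)
      if (sb <= 0 || sb >= K) return(NA_real_)
      rt * log(sb / (K - sb))
    }, numeric(1))
    boot_se <- stats::sd(draws, na.rm = TRUE)
  }

  diag_fit <- stats::lm(y ~ x)
  structure(
    list(slope = s, slope_se = se_s,
         mu_diff = mu, mu_diff_se = mu_se,
         mu_diff_se_boot = boot_se,
         r_squared = r2, n_points = length(y),
         K = K, fraction = f,
         temperature = temperature,
         near_saturated = f > 0.999,
         intercept_diagnostic = unname(stats::coef(diag_fit)),
         lipid = attr(dataset, "lipid")),
    class = "salb_fit"
  )
}

#' @export
print.salb_fit <- function(x, ...) {
  cat(sprintf("Coverage-concentration fit (%s, T = %g K, n = %d)\n",
              x$lipid, x$temperature, x$n_points))
  cat(sprintf("  slope        : %.6g +/- %.3g per (mg/mL)  [R^2 = %.4f]\n",
              x$slope, x$slope_se, x$r_squared))
  cat(sprintf("  mu_mv - mu_s : %.6g +/- %.3g J/mol\n",
              x$mu_diff, x$mu_diff_se))
  if (is.finite(x$mu_diff_se_boot)) {
    cat(sprintf("  bootstrap SE : %.3g J/mol\n", x$mu_diff_se_boot))
  }
  cat(sprintf("  implied adsorbed fraction: %.4f%s\n", x$fraction,
              if (x$near_saturated) "  (near-saturated: mu unstable)" else ""))
  cat(sprintf("  diagnostic intercept fit : intercept %.3g, slope %.6g\n",
              x$intercept_diagnostic[1], x$intercept_diagnostic[2]))
  invisible(x)
}

#' Read and write endpoint-dataset CSV files
#'
#' The CSV schema is `concentration_mg_per_ml,replicate,delta_f_hz`; the
#' metadata (temperature, complete shift, chamber constants, lipid label)
#' travels in a JSON sidecar written next to the CSV (same path with a
#' `.json` extension added) or supplied explicitly.
#'
#' @param path CSV file path.
#' @param metadata_path JSON sidecar path; defaults to `<path>.json`.
#' @return `read_coverage_csv()`: a [coverage_dataset()];
#'   `write_coverage_csv()`: `path`, invisibly.
#' @name coverage_csv
#' @export
read_coverage_csv <- function(path, metadata_path = paste0(path, ".json")) {
  if (!file.exists(path)) {
    salb_error("salb_io_error", sprintf("dataset file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("concentration_mg_per_ml", "replicate", "delta_f_hz")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    salb_error("salb_schema_error",
               sprintf("CSV '%s' is missing column(s): %s", path,
                       paste(missing, collapse = ", ")))
  }
  if (!file.exists(metadata_path)) {
    salb_error("salb_io_error",
               sprintf("metadata sidecar not found: %s", metadata_path))
  }
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  chamber <- chamber_config(meta$chamber_volume_mm3, meta$sensor_area_mm2,
                            meta$sauerbrey_constant_ng_per_cm2_per_hz,
                            meta$exchange_factor)
  out <- coverage_dataset(df,
                          temperature = meta$temperature_K,
                          complete_shift = meta$complete_shift_hz,
                          chamber = chamber,
                          lipid = if (is.null(meta$lipid)) "unknown"
                                  else meta$lipid)
  if (!is.null(meta$truth)) attr(out, "truth") <- meta$truth
  out
}

#' @rdname coverage_csv
#' @param dataset a [coverage_dataset()].
#' @export
write_coverage_csv <- function(dataset, path,
                               metadata_path = paste0(path, ".json")) {
  stopifnot(inherits(dataset, "coverage_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  chamber <- attr(dataset, "chamber")
  meta <- list(
    temperature_K = attr(dataset, "temperature"),
    complete_shift_hz = attr(dataset, "complete_shift"),
    chamber_volume_mm3 = chamber$chamber_volume,
    sensor_area_mm2 = chamber$sensor_area,
    sauerbrey_constant_ng_per_cm2_per_hz = chamber$sauerbrey_constant,
    exchange_factor = chamber$exchange_factor,
    lipid = attr(dataset, "lipid")
  )
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
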