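#' Regime classification rule
#'
#' "Complete" coverage is a band around 1 rather than an exact contour (an
#' exact-equality contour has measure zero on a grid). Raw coverage below
#' 1 - tolerance is `incomplete`, above 1 + tolerance `supersaturated`.
#'
#' @param complete_tolerance half-width of the complete band; in (0, 0.5).
#' @return An object of class `regime_rule`.
#' @export
regime_rule <- function(complete_tolerance = 0.02) {
  stopifnot(is.numeric(complete_tolerance), length(complete_tolerance) == 1L)
  if (!is.finite(complete_tolerance) ||
      complete_tolerance <= 0 || complete_tolerance >= 0.5) {
    stop("`complete_tolerance` must lie in (0, 0.5)")
  }
  structure(list(complete_tolerance = complete_tolerance),
            class = "regime_rule")
}

classify_regime <- function(coverage_raw, rule) {
  tol <- rule$complete_tolerance
  out <- character(length(coverage_raw))
  out[coverage_raw < 1 - tol] <- "incomplete"
  out[coverage_raw >= 1 - tol & coverage_raw <= 1 + tol] <- "complete"
  out[coverage_raw > 1 + tol] <- "supersaturated"
  out
}

#' Temperature-concentration phase diagram of SLB quality
#'
#' Evaluates the general coverage model over a temperature x concentration
#' grid and classifies each cell as incomplete, complete or supersaturated.
#' At every temperature the regimes are ordered
#' incomplete -> complete -> supersaturated with increasing concentration
#' (coverage is linear in c0), and the coverage = 1 contour coincides with
#' the minimum-concentration curve [min_concentration()]. For lipids with a
#' gel-to-fluid transition inside the temperature range the regime boundary
#' drops discontinuously at Tm.
#'
#' @param lipid a [lipid_species()] object.
#' @param chamber a [chamber_config()] object.
#' @param params a [thermo_params()] object (its temperature slot is
#'   overridden by the grid temperatures).
#' @param temperatures ordered temperature axis in K. Defaults span the DPPC
#'   transition, 290-330 K in 0.5 K steps.
#' @param concentrations ordered concentration axis in mg/mL, 0-1 mg/mL in
#'   0.01 steps by default.
#' @param rule a [regime_rule()].
#' @return An object of class `phase_diagram`: the axes, a
#'   temperatures x concentrations matrix of raw coverage, the matching
#'   regime label matrix, and the inputs.
#' @examples
#' pd <- build_phase_diagram(dppc(), dopc_chamber(), thermo_params(1000, 300),
#'                           temperatures = seq(300, 320, 5),
#'                           concentrations = seq(0.1, 0.5, 0.1))
#' pd
#' @export
build_phase_diagram <- function(lipid, chamber, params,
                                temperatures = seq(290, 330, by = 0.5),
                                concentrations = seq(0, 1, by = 0.01),
                                rule = regime_rule()) {
  stopifnot(inherits(lipid, "lipid_species"),
            inherits(chamber, "chamber_config"),
            inherits(params, "thermo_params"),
            inherits(rule, "regime_rule"))
  if (!length(temperatures) || !length(concentrations)) {
    stop("temperature and concentration axes must be nonempty")
  }
  if (is.unsorted(temperatures, strictly = TRUE) ||
      is.unsorted(concentrations, strictly = TRUE)) {
    stop("axes must be strictly increasing")
  }
  cov <- t(vapply(temperatures, function(tt) {
    coverage_general(concentrations, lipid, tt, chamber, params)$coverage_raw
  }, numeric(length(concentrations))))
  dimnames(cov) <- list(format(temperatures, trim = TRUE),
                        format(concentrations, trim = TRUE))
  regime <- matrix(classify_regime(as.vector(cov), rule), nrow = nrow(cov),
                   dimnames = dimnames(cov))
  structure(
    list(temperatures = as.numeric(temperatures),
         concentrations = as.numeric(concentrations),
         coverage = cov, regime = regime,
         rule = rule, lipid = lipid, chamber = chamber, params = params),
    class = "phase_diagram"
  )
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("SLB phase diagram: %s, %d temperatures x %d concentrations\n",
              x$lipid$name, length(x$temperatures), length(x$concentrations)))
  cat(sprintf("  T in [%g, %g] K; c0 in [%g, %g] mg/mL\n",
              min(x$temperatures), max(x$temperatures),
              min(x$concentrations), max(x$concentrations)))
  tab <- table(factor(x$regime,
                      c("incomplete", "complete", "supersaturated")))
  cat("  regime cells:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Export and re-import a phase diagram as a long-format table
#'
#' Writes one row per grid cell with columns `temperature_K`,
#' `concentration_mg_per_ml`, `coverage_raw` and `regime`. Numbers are
#' written with full (17 significant digit) precision so a read-back
#' reproduces the grid exactly; users can re-threshold the raw coverage with
#' their own [regime_rule()].
#'
#' @param grid a `phase_diagram` from [build_phase_diagram()].
#' @param path output CSV path.
#' @return `export_grid()`: the long-format data frame, invisibly;
#'   `read_grid()`: the long-format data frame.
#' @name grid_io
#' @export
export_grid <- function(grid, path) {
  stopifnot(inherits(grid, "phase_diagram"))
  long <- data.frame(
    temperature_K = rep(grid$temperatures, times = length(grid$concentrations)),
    concentration_mg_per_ml = rep(grid$concentrations,
                                  each = length(grid$temperatures)),
    coverage_raw = as.vector(grid$coverage),
    regime = as.vector(grid$regime)
  )
  fmt <- long
  fmt$temperature_K <- sprintf("%.17g", long$temperature_K)
  fmt$concentration_mg_per_ml <- sprintf("%.17g", long$concentration_mg_per_ml)
  fmt$coverage_raw <- sprintf("%.17g", long$coverage_raw)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(long)
}

#' @rdname grid_io
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) {
    salb_error("salb_io_error", sprintf("grid file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("temperature_K", "concentration_mg_per_ml",
                "coverage_raw", "regime")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    salb_error("salb_schema_error",
               sprintf("grid CSV is missing column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  df
}

#' Heatmap of a phase diagram
#'
#' Convenience ggplot2 rendering of the coverage heatmap with the complete
#' band outlined; requires ggplot2.
#'
#' @param x a `phase_diagram`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.phase_diagram <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting phase diagrams")
  }
  long <- data.frame(
    temperature_K = rep(x$temperatures, times = length(x$concentrations)),
    concentration_mg_per_ml = rep(x$concentrations,
                                  each = length(x$temperatures)),
    coverage_raw = as.vector(x$coverage),
    regime = as.vector(x$regime)
  )
  long$coverage_capped <- pmin(long$coverage_raw, 2)
  ggplot2::ggplot(long, ggplot2::aes(
    x = temperature_K, y = concentration_mg_per_ml,
    fill = coverage_capped)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "coverage (capped at 2)") +
    ggplot2::labs(x = "temperature (K)",
                  y = "initial lipid concentration (mg/mL)")
}
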