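# Shared fixtures and independent arithmetic oracles.
# Oracle helpers recompute model quantities from first principles with
# explicit unit conversion, independently of the package's internals.

R_GAS <- 8.314462618
N_AV <- 6.02214076e23

ref_chamber <- function() dopc_chamber()
ref_lipid <- function() dppc()

# logistic adsorbed fraction, direct arithmetic
oracle_fraction <- function(mu, temp) 1 / (1 + exp(-mu / (R_GAS * temp)))

# coverage-per-concentration slope from printed constants, explicit units:
# V mm^3 -> cm^3, A mm^2 -> cm^2, c0 mg/mL -> ng/cm^3
oracle_slope <- function(mu, temp, v_mm3 = 58, a_mm2 = 97, c_sauer = 17.7,
                         xi = 0.05, dfc = -25) {
  (v_mm3 * 1e-3) * xi * 1e6 / (c_sauer * (a_mm2 * 1e-2) * abs(dfc)) *
    oracle_fraction(mu, temp)
}

# complete-layer shift from areal mass: b lipids of mass M/NA grams per a0
oracle_dfc <- function(a0_A2, m = 734.039, c_sauer = 17.7, b = 2) {
  mass_ng_cm2 <- b * m / (N_AV * a0_A2 * 1e-16) * 1e9
  -mass_ng_cm2 / c_sauer
}

# minimum concentration, g/cm^3 -> mg/mL is *1e3
oracle_cmin <- function(a0_A2, mu, temp, m = 734.039, v_mm3 = 58,
                        a_mm2 = 97, xi = 0.05, b = 2) {
  b * m * (a_mm2 * 1e-2) / (N_AV * (v_mm3 * 1e-3) * xi) *
    (1 + exp(-mu / (R_GAS * temp))) / (a0_A2 * 1e-16) * 1e-3 * 1e6
}

# brute-force grid minimizer of the printed free energy (one refinement pass)
oracle_argmin_free_energy <- function(n_total, params, n_grid = 1e5,
                                      refine = TRUE) {
  grid <- seq(n_total / n_grid, n_total * (1 - 1 / n_grid),
              length.out = n_grid)
  i <- which.min(free_energy(grid, n_total, params))
  if (!refine) return(grid[i])
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  fine <- seq(lo, hi, length.out = 2e5)
  fine[which.min(free_energy(fine, n_total, params))]
}

make_noiseless_dataset <- function(mu_true, temp = 297.15, dfc = -25,
                                   concentrations = seq(0.025, 0.25,
                                                        length.out = 8),
                                   replicates = 2) {
  spec <- generator_spec("DOPC", ref_chamber(), mu_true,
                         temperature = temp, complete_shift = dfc,
                         concentrations = concentrations,
                         replicates = replicates, noise_sd = 0)
  generate_endpoint_dataset(spec)
}
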