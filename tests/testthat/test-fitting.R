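test_that("coverage from shift is the ratio of magnitudes", {
  expect_equal(coverage_from_shift(-25, -25), 1)
  expect_equal(coverage_from_shift(0, -25), 0)
  expect_equal(coverage_from_shift(-12.5, -25), 0.5)
  expect_error(coverage_from_shift(-5, 0), class = "salb_schema_error")
  expect_error(coverage_from_shift(-5, 25), class = "salb_schema_error")
})

test_that("noiseless datasets recover the generating mu exactly", {
  for (mu_true in c(-400, 0, 585, 1500)) {
    fit <- fit_mu_difference(make_noiseless_dataset(mu_true))
    if (mu_true == 0) {
      expect_lt(abs(fit$mu_diff), 1e-6)
      # logistic midpoint: slope is half the prefactor
      expect_equal(fit$slope, fit$K / 2, tolerance = 1e-12)
    } else {
      expect_lt(abs(fit$mu_diff - mu_true) / abs(mu_true), 1e-9)
    }
    expect_gt(fit$r_squared, 1 - 1e-12)
  }
})

test_that("degenerate and unphysical datasets raise typed errors", {
  ch <- ref_chamber()
  base <- data.frame(
    concentration_mg_per_ml = rep(seq(0.025, 0.25, length.out = 8), 2),
    replicate = rep(1:2, each = 8)
  )

  # all shifts zero -> zero slope, mu unidentifiable
  flat <- base
  flat$delta_f_hz <- 0
  expect_error(
    fit_mu_difference(coverage_dataset(flat, 297.15, -25, ch)),
    class = "salb_identifiability_error")

  # data above the physical line: implied fraction >= 1
  k_pref <- oracle_slope(1e9, 297.15) # fraction ~ 1 -> bare prefactor K
  hot <- base
  hot$delta_f_hz <- 2 * k_pref * hot$concentration_mg_per_ml * -25
  expect_error(
    fit_mu_difference(coverage_dataset(hot, 297.15, -25, ch)),
    class = "salb_identifiability_error")

  # a single concentration cannot anchor a slope inversion
  single <- data.frame(concentration_mg_per_ml = rep(0.1, 5),
                       replicate = 1:5, delta_f_hz = rep(-9.4, 5))
  expect_error(
    fit_mu_difference(coverage_dataset(single, 297.15, -25, ch)),
    class = "salb_insufficient_data_error")
})

test_that("fit is invariant to row order and robust to replicate averaging", {
  spec <- generator_spec("DOPC", ref_chamber(), 585, seed = 12,
                         noise_sd = 1)
  ds <- generate_endpoint_dataset(spec)
  fit <- fit_mu_difference(ds)

  set.seed(99)
  perm <- sample(nrow(ds))
  shuffled <- coverage_dataset(as.data.frame(ds)[perm, ],
                               attr(ds, "temperature"),
                               attr(ds, "complete_shift"),
                               attr(ds, "chamber"), attr(ds, "lipid"))
  fit_sh <- fit_mu_difference(shuffled)
  expect_equal(fit_sh$mu_diff, fit$mu_diff, tolerance = 1e-12)
  expect_equal(fit_sh$slope_se, fit$slope_se, tolerance = 1e-12)

  # replicate means give the same mu within the reported SE
  agg <- aggregate(delta_f_hz ~ concentration_mg_per_ml, as.data.frame(ds),
                   mean)
  agg$replicate <- 1
  fit_mean <- fit_mu_difference(
    coverage_dataset(agg, attr(ds, "temperature"),
                     attr(ds, "complete_shift"), attr(ds, "chamber")))
  expect_lt(abs(fit_mean$mu_diff - fit$mu_diff), fit$mu_diff_se)
})

test_that("bias and uncertainty vanish as measurement noise vanishes", {
  errs <- c()
  ses <- c()
  for (sd in c(1, 0.1, 0.01)) {
    spec <- generator_spec("DOPC", ref_chamber(), 585, seed = 31,
                           noise_sd = sd)
    fit <- fit_mu_difference(generate_endpoint_dataset(spec))
    errs <- c(errs, abs(fit$mu_diff - 585))
    ses <- c(ses, fit$mu_diff_se)
  }
  expect_true(all(diff(errs) < 0))
  expect_true(all(diff(ses) < 0))
  expect_lt(errs[3], 2) # J/mol at sigma = 0.01 Hz
})

test_that("recovered mu falls within three standard errors across seeds", {
  hits <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    spec <- generator_spec("DOPC", ref_chamber(), 585, seed = 1000L + s,
                           noise_sd = 1)
    fit <- fit_mu_difference(generate_endpoint_dataset(spec))
    if (abs(fit$mu_diff - 585) <= 3 * fit$mu_diff_se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("bootstrap SE is seeded, reproducible and close to the delta method", {
  spec <- generator_spec("DOPC", ref_chamber(), 585, seed = 5, noise_sd = 1)
  ds <- generate_endpoint_dataset(spec)
  f1 <- fit_mu_difference(ds, bootstrap = 400, seed = 7)
  f2 <- fit_mu_difference(ds, bootstrap = 400, seed = 7)
  expect_identical(f1$mu_diff_se_boot, f2$mu_diff_se_boot)
  expect_equal(f1$mu_diff_se_boot, f1$mu_diff_se, tolerance = 0.5)
  expect_error(fit_mu_difference(ds, bootstrap = 10),
               class = "salb_schema_error")
})

test_that("near-saturated fits are flagged rather than silently returned", {
  # huge mu: fraction ~ 1, slope ~ K, still finite but flagged
  fit <- fit_mu_difference(make_noiseless_dataset(30000))
  expect_true(fit$near_saturated)
  expect_true(is.finite(fit$mu_diff))
})
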