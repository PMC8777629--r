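test_that("endpoint generation is a deterministic function of spec and seed", {
  spec <- generator_spec("DOPC", ref_chamber(), 585, seed = 3, noise_sd = 1)
  d1 <- generate_endpoint_dataset(spec)
  d2 <- generate_endpoint_dataset(spec)
  expect_identical(as.data.frame(d1), as.data.frame(d2))

  spec2 <- generator_spec("DOPC", ref_chamber(), 585, seed = 4, noise_sd = 1)
  expect_false(identical(d1$delta_f_hz,
                         generate_endpoint_dataset(spec2)$delta_f_hz))

  # seed mandatory for stochastic output
  expect_error(generator_spec("DOPC", ref_chamber(), 585, noise_sd = 1),
               "seed")
})

test_that("noiseless endpoints lie exactly on the model line", {
  ds <- make_noiseless_dataset(585)
  params <- thermo_params(585, 297.15)
  expected <- predict_coverage(ds$concentration_mg_per_ml, -25,
                               ref_chamber(), params)$coverage_raw * -25
  expect_equal(ds$delta_f_hz, expected, tolerance = 1e-12)
})

test_that("replicate means converge to the model expectation", {
  # E[delta_f] at c0 = 0.1 is slope * 0.1 * delta_fc ~ 0.3776 * -25
  spec <- generator_spec("DOPC", ref_chamber(), 585,
                         concentrations = 0.1, replicates = 4000,
                         noise_sd = 1, seed = 21)
  ds <- generate_endpoint_dataset(spec)
  expected <- oracle_slope(585, 297.15) * 0.1 * -25
  expect_equal(mean(ds$delta_f_hz), expected,
               tolerance = 3 / sqrt(4000) / abs(expected))
})

test_that("generator-to-fit pipeline closes on the truth", {
  for (mu_true in c(300, 585, 1000)) {
    # noiseless: exact closure
    fit0 <- fit_mu_difference(make_noiseless_dataset(mu_true))
    expect_lt(abs(fit0$mu_diff - mu_true) / mu_true, 1e-9)
    # noisy: within 3 SE for this fixed seed
    spec <- generator_spec("DOPC", ref_chamber(), mu_true, seed = 17,
                           noise_sd = 1)
    fit <- fit_mu_difference(generate_endpoint_dataset(spec))
    expect_lt(abs(fit$mu_diff - mu_true), 3 * fit$mu_diff_se)
    truth <- attr(generate_endpoint_dataset(spec), "truth")
    expect_identical(truth$mu_diff_true, mu_true)
  }
})

test_that("temperature series reproduces the model pointwise", {
  params <- thermo_params(1000, 300)
  temps <- seq(300, 330, by = 1)
  tab <- generate_temperature_series(ref_lipid(), ref_chamber(), params,
                                     temps)
  expect_equal(tab$delta_fc_hz,
               complete_shift_at_temperature(ref_lipid(), temps,
                                             ref_chamber()),
               tolerance = 1e-12)
  expect_equal(tab$cmin_mg_per_ml,
               min_concentration(ref_lipid(), temps, ref_chamber(), params),
               tolerance = 1e-12)

  # model shifts at 297/323 K (distinct from any measured values)
  two <- generate_temperature_series(ref_lipid(), ref_chamber(), params,
                                     c(297, 323))
  expect_equal(two$delta_fc_hz, c(-29.6318551769, -21.8270781081),
               tolerance = 1e-9)

  # a series straddling Tm has exactly one discontinuity
  dense <- generate_temperature_series(ref_lipid(), ref_chamber(), params,
                                       seq(310, 318, by = 0.1))
  steps <- abs(diff(dense$delta_fc_hz))
  expect_identical(sum(steps > 5 * stats::median(steps)), 1L)

  # noise requires a seed and is reproducible with one
  expect_error(generate_temperature_series(ref_lipid(), ref_chamber(),
                                           params, temps, noise_sd = 0.5),
               "seed")
  n1 <- generate_temperature_series(ref_lipid(), ref_chamber(), params,
                                    temps, noise_sd = 0.5, seed = 9)
  n2 <- generate_temperature_series(ref_lipid(), ref_chamber(), params,
                                    temps, noise_sd = 0.5, seed = 9)
  expect_identical(n1, n2)
})

test_that("washout traces start at one and average to the scaling factor", {
  prof <- exchange_profile(0.03, 100) # k*tau = 3
  trace <- generate_washout_trace(prof, n_steps = 1e4)
  expect_identical(trace$relative_concentration[1], 1)
  h <- diff(trace$time_s[1:2])
  y <- trace$relative_concentration
  trap <- h * (sum(y) - (y[1] + y[length(y)]) / 2) / prof$exchange_duration
  expect_equal(trap, 0.316737643877, tolerance = 1e-6)

  # mean concentration rises as washout slows
  means <- vapply(c(0.03, 0.015, 0.0075), function(k) {
    mean(generate_washout_trace(exchange_profile(k, 100),
                                n_steps = 4000)$relative_concentration)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_error(generate_washout_trace(prof, 0), "positive")
})
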