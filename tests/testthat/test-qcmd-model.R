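test_that("Sauerbrey conversions are linear, sign-flipping and inverse", {
  ch <- ref_chamber()
  expect_equal(sauerbrey_mass(0, ch), 0)
  expect_equal(sauerbrey_mass(-25, ch), 442.5) # 17.7 * 25
  expect_equal(sauerbrey_shift(442.5, ch), -25)
  set.seed(7)
  x <- rnorm(20, sd = 30)
  expect_equal(sauerbrey_shift(sauerbrey_mass(x, ch), ch), x)
})

test_that("area per lipid follows the piecewise-linear APL model", {
  lp <- ref_lipid()
  # arithmetic from the packaged coefficients
  expect_equal(area_per_lipid(lp, 297), 47.5 - 0.06 * 17) # 46.48
  expect_equal(area_per_lipid(lp, 323), 61.3 + 0.2 * 9)   # 63.1
  # T = Tm sits on the fluid branch
  expect_equal(area_per_lipid(lp, 314), 61.3)
  expect_equal(area_per_lipid(lp, 314 - 1e-9), 47.5, tolerance = 1e-9)

  expect_error(area_per_lipid(lp, -3), "positive")
  # a steep synthetic gel slope drives the linearization nonpositive
  steep <- lipid_species("synthetic", 700, 300, 1, 1.5, 0.5, 0.1)
  expect_error(area_per_lipid(steep, 200), "nonpositive")
})

test_that("complete-layer shift matches the areal-mass oracle", {
  lp <- ref_lipid()
  ch <- ref_chamber()
  # frozen values from the independent mass-per-area arithmetic
  expect_equal(complete_shift_at_temperature(lp, 297, ch), -29.6318551769,
               tolerance = 1e-9)
  expect_equal(complete_shift_at_temperature(lp, 323, ch), -21.8270781081,
               tolerance = 1e-9)
  expect_equal(complete_shift_at_temperature(lp, 297, ch),
               oracle_dfc(46.48), tolerance = 1e-12)

  # inverse proportionality in a0; monolayer is exactly half the bilayer
  s1 <- complete_shift_from_apl(lp, 50, ch)
  expect_equal(complete_shift_from_apl(lp, 100, ch), s1 / 2)
  expect_equal(complete_shift_from_apl(lp, 50, ch, "hydrophobic"), s1 / 2)
  expect_lt(s1, 0)
  expect_error(complete_shift_from_apl(lp, 0, ch), "positive")
})

test_that("shift magnitude decreases in temperature with one jump at Tm", {
  lp <- ref_lipid()
  ch <- ref_chamber()
  temps <- seq(280, 340, by = 0.1)
  mag <- abs(complete_shift_at_temperature(lp, temps, ch))
  expect_true(all(diff(mag) < 0))

  # the drop at Tm equals the gel/fluid APL ratio
  ratio <- abs(complete_shift_at_temperature(lp, 314 - 1e-9, ch)) /
    abs(complete_shift_at_temperature(lp, 314, ch))
  expect_equal(ratio, 61.3 / 47.5, tolerance = 1e-6)
})

test_that("predicted coverage is linear in concentration with the oracle slope", {
  ch <- ref_chamber()
  params <- thermo_params(585, 297.15)

  expect_equal(predict_coverage(0, -25, ch, params)$coverage_raw, 0)
  # frozen slope 3.776 per (mg/mL) -> coverage 0.944 at 0.25 mg/mL
  pred <- predict_coverage(0.25, -25, ch, params)
  expect_equal(pred$coverage_raw, 0.944066807375, tolerance = 1e-9)
  expect_equal(coverage_slope(-25, ch, params), oracle_slope(585, 297.15),
               tolerance = 1e-12)

  # exact linearity of the raw value; clipping at 1
  c0 <- c(0.05, 0.1, 0.2, 0.4)
  raw <- predict_coverage(c0, -25, ch, params)$coverage_raw
  expect_equal(raw[2], 2 * raw[1])
  expect_equal(raw[4], 2 * raw[3])
  clipped <- predict_coverage(c0, -25, ch, params)$coverage_clipped
  expect_true(all(clipped <= 1))
  expect_equal(clipped[4], 1)

  expect_error(predict_coverage(0.1, 25, ch, params), "negative")
  expect_error(predict_coverage(-0.1, -25, ch, params), "nonnegative")
})

test_that("general coverage equals the composed pipeline", {
  lp <- ref_lipid()
  ch <- ref_chamber()
  set.seed(11)
  for (i in 1:200) {
    tt <- runif(1, 285, 335)
    c0 <- runif(1, 0, 1)
    params <- thermo_params(runif(1, -2000, 2000), tt)
    composed <- predict_coverage(
      c0, complete_shift_at_temperature(lp, tt, ch), ch, params)$coverage_raw
    expect_equal(coverage_general(c0, lp, tt, ch, params)$coverage_raw,
                 composed, tolerance = 1e-12)
  }

  # coverage rises with temperature (APL expansion) and jumps up at Tm
  params <- thermo_params(1000, 300)
  covs <- vapply(seq(290, 330, 1), function(tt)
    coverage_general(0.3, lp, tt, ch, params)$coverage_raw, numeric(1))
  expect_true(all(diff(covs) > 0))
  jump <- coverage_general(0.3, lp, 314, ch, params)$coverage_raw /
    coverage_general(0.3, lp, 314 - 1e-9, ch, params)$coverage_raw
  expect_equal(jump, 61.3 / 47.5, tolerance = 1e-5)
})

test_that("minimum concentration matches its oracle and closes with coverage", {
  lp <- ref_lipid()
  ch <- ref_chamber()
  params <- thermo_params(1000, 297)
  cmin <- min_concentration(lp, 297, ch, params)
  expect_equal(cmin, 0.292444058195, tolerance = 1e-9)
  expect_equal(cmin, oracle_cmin(46.48, 1000, 297), tolerance = 1e-12)

  # coverage at cmin is exactly full
  expect_equal(coverage_general(cmin, lp, 297, ch, params)$coverage_raw, 1,
               tolerance = 1e-12)

  # strictly decreasing in T with a single downward jump at Tm
  temps <- seq(290, 330, by = 0.5)
  cm <- min_concentration(lp, temps, ch, params)
  expect_true(all(diff(cm) < 0))
  jump <- min_concentration(lp, 314 - 1e-9, ch, params) /
    min_concentration(lp, 314, ch, params)
  expect_equal(jump, 61.3 / 47.5, tolerance = 1e-5)
})
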