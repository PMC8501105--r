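test_that("mono-layer ideal closed form: half-saturation, limits, bounds", {
  p <- mono_ideal_params(n = 0.94, P_M = 421.4, c_half = 0.008)
  expect_equal(q_mono_ideal(0.008, p), 0.94 * 421.4 / 2)
  expect_identical(q_mono_ideal(0, p), 0)
  # half-saturation holds for any n: the exponent cancels at c = c_half
  for (n in c(0.3, 1, 2.7)) {
    pn <- mono_ideal_params(n, 100, 0.004)
    expect_equal(q_mono_ideal(0.004, pn), n * 100 / 2)
  }
  cg <- default_grid(200)
  q <- q_mono_ideal(cg, p)
  expect_true(all(diff(q) > 0))
  expect_true(all(q >= 0 & q <= saturation_value(p)))
  expect_error(q_mono_ideal(-0.1, p), "finite and >= 0")
})

test_that("double-layer ideal closed form matches arithmetic oracle and limits", {
  p <- double_ideal_params(n = 0.73, P_M = 279.4, c1 = 0.0031, c2 = 0.025)
  # frozen value from an independent single-expression evaluation
  expect_equal(q_double_ideal(0.01, p), 162.3325, tolerance = 1e-6)
  expect_identical(q_double_ideal(0, p), 0)
  # symmetric layers: c1 = c2 = c gives exactly n * P_M
  ps <- double_ideal_params(0.6, 150, 0.005, 0.005)
  expect_equal(q_double_ideal(0.005, ps), 0.6 * 150)
  # large-c limit is the two-layer saturation
  expect_equal(q_double_ideal(1e6, p), 2 * p$n * p$P_M, tolerance = 1e-3)
  expect_true(all(q_double_ideal(default_grid(100), p) <= 2 * p$n * p$P_M))
})

test_that("real-gas forms reduce to ideal at a = b = 0 and respect the covolume pole", {
  cg <- default_grid(50)
  pm <- mono_real_params(0.84, 355.2, 0.0069, a = 0, b = 0)
  pm_id <- mono_ideal_params(0.84, 355.2, 0.0069)
  expect_lt(rel_err(q_mono_real(cg, pm), q_mono_ideal(cg, pm_id)), 1e-12)
  pd <- double_real_params(0.6, 200, 0.003, 0.02, a = 0, b = 0)
  pd_id <- double_ideal_params(0.6, 200, 0.003, 0.02)
  expect_lt(rel_err(q_double_real(cg, pd), q_double_ideal(cg, pd_id)), 1e-12)
  # published-magnitude corrections are numerically inert at these concentrations
  pn <- mono_real_params(0.84, 355.2, 0.0069, a = 7.13e-9, b = 4.4e-12)
  expect_equal(q_mono_real(0.0069, pn), 0.84 * 355.2 / 2, tolerance = 1e-6)
  pb <- mono_real_params(1, 100, 0.01, a = 0, b = 2)
  expect_error(q_mono_real(0.6, pb), "covolume pole")
})

test_that("partition function takes its textbook values at the anchor points", {
  p <- mono_ideal_params(1.3, 100, 0.004)
  expect_equal(partition_function(0.004, p), 2)
  expect_equal(partition_function(0, p), 1)
  ps <- double_ideal_params(0.5, 100, 0.006, 0.006)
  expect_equal(partition_function(0.006, ps), 3)
  expect_true(all(partition_function(default_grid(30), ps) >= 1))
})

test_that("closed forms agree with the partition-function derivative route", {
  cg <- exp(seq(log(1e-4), log(0.04), length.out = 20))
  for (model in iso_models()) {
    for (s in 1:5) {
      p <- random_params(model, rng_seed = 100 * s + match(model, iso_models()))
      q_closed <- iso_q(cg, p)
      q_deriv <- q_partition_deriv(cg, p)
      keep <- q_closed > 1e-12
      expect_lt(max(abs(q_deriv[keep] / q_closed[keep] - 1)), 1e-6)
    }
  }
})

test_that("saturation values follow the layer count", {
  expect_equal(saturation_value(mono_ideal_params(0.94, 421.4, 0.008)), 396.116)
  expect_equal(saturation_value(double_ideal_params(1, 100, 0.01, 0.02)), 200)
})

test_that("adsorption energy converts energetic concentrations with the solubility anchor", {
  expect_equal(adsorption_energy(0.008, S = exp(1) * 0.008, T = 300),
               8.314 * 300 / 1000)
  expect_equal(adsorption_energy(0.008, S = 31.7, T = 300), 20.66,
               tolerance = 1e-3)
  expect_warning(e0 <- adsorption_energy(0.01, S = 0.01, T = 300),
                 "non-physical")
  expect_equal(e0, 0)
  expect_warning(adsorption_energy(0.02, S = 0.01, T = 300), "non-physical")
  expect_error(adsorption_energy(-1, S = 1, T = 300))
})
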