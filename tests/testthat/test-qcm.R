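test_that("Sauerbrey mass conversion is linear and involutive", {
  expect_identical(sauerbrey_mass(0, C = 56.6), 0)
  expect_equal(sauerbrey_mass(-56.6, C = 56.6), 1)
  expect_equal(sauerbrey_mass(-113.2, C = 56.6), 2)
  m <- c(0.1, 1, 7.5, 300)
  expect_equal(sauerbrey_mass(-56.6 * m, C = 56.6), m)
  expect_error(sauerbrey_mass(10, C = 0), "positive")
})

test_that("injection volumes follow matter conservation and stay small", {
  expect_identical(injection_volume(0, 150, 0.1), 0)
  expect_equal(injection_volume(1e-3, V_s = 150, c0 = 0.1), 1.5)
  # targets up to 1.33e-3 mol/L from a 0.1 mol/L stock need at most 2 mL
  cf <- seq(0, 1.33e-3, length.out = 100)
  expect_true(all(injection_volume(cf, 150, 0.1) <= 2))
  expect_error(injection_volume(0.2, 150, 0.1), "exceeds the stock")
})

test_that("reduce_trace rebuilds concentrations and masses from a log", {
  cfg <- qcm_config(C = 56.6, V_s = 150)
  # five equal injections with delta_f = -C * k give q = 1..5
  rec <- injection_records(c0 = 0.1, v_injected = rep(1.5, 5),
                           delta_f = -56.6 * (1:5))
  iso <- reduce_trace(rec, cfg, T = 300)
  expect_equal(iso$q, 1:5)
  expect_equal(iso$c, (1:5) * 0.1 * 1.5 / 150)
  # mole bookkeeping: final c equals sum(c0 * v) / V_s
  expect_equal(max(iso$c), sum(0.1 * rep(1.5, 5)) / 150, tolerance = 1e-12)
  # c_target route gives the same curve
  rec2 <- injection_records(c0 = 0.1, c_target = iso$c,
                            delta_f = -56.6 * (1:5))
  expect_equal(reduce_trace(rec2, cfg, T = 300)$c, iso$c)
  # volume accounting changes concentrations only slightly
  iso_v <- reduce_trace(rec, cfg, T = 300, account_added_volume = TRUE)
  expect_true(all(iso_v$c < iso$c))
  expect_lt(rel_err(iso_v$c, iso$c), 0.06)
})

test_that("invalid traces are rejected", {
  cfg <- qcm_config(C = 56.6)
  expect_error(injection_records(c0 = 0.1, delta_f = -5,
                                 v_injected = 1, c_target = 1e-3),
               "not both")
  expect_error(injection_records(c0 = 0.1, delta_f = -5), "one of")
  short <- injection_records(c0 = 0.1, v_injected = 1, delta_f = 0)
  expect_error(reduce_trace(short, cfg, T = 300), "at least 4")
  dec <- injection_records(c0 = 0.1, c_target = c(2e-3, 1e-3, 3e-3, 4e-3),
                           delta_f = -(1:4))
  expect_error(reduce_trace(dec, cfg, T = 300), "non-monotone")
})

test_that("generator -> reducer round trip reproduces the model exactly", {
  cfg <- qcm_config(C = 56.6, V_s = 150)
  p <- mono_ideal_params(0.94, 421.4, 0.008)
  targets <- exp(seq(log(2e-4), log(0.02), length.out = 12))
  rec <- generate_qcm_trace(p, targets, cfg, c0 = 0.1)
  iso <- reduce_trace(rec, cfg, T = 300)
  expect_equal(iso$c, targets, tolerance = 1e-12)
  expect_equal(iso$q, q_mono_ideal(targets, p), tolerance = 1e-12)
  # and the fitter recovers the generating parameters from the round trip
  f <- isofit(iso, "mono_ideal")
  expect_lt(rel_err(coef(f), c(0.94, 421.4, 0.008)), 1e-4)
})

test_that("file dialects round-trip isotherms, logs and configs", {
  iso <- fixture_curve("ZnCl2", 300, n_points = 10)
  fp <- tempfile(fileext = ".csv")
  write_isotherm(iso, fp)
  back <- read_isotherm(fp)
  expect_equal(back$c, iso$c)
  expect_equal(back$q, iso$q)
  expect_equal(back$T, 300)

  cfg <- qcm_config(C = 56.6, V_s = 150)
  rec <- generate_qcm_trace(mono_ideal_params(1, 100, 0.01),
                            c(1e-3, 2e-3, 4e-3, 8e-3), cfg)
  lp <- tempfile(fileext = ".csv")
  write_injection_log(rec, lp)
  rec2 <- read_injection_log(lp)
  expect_equal(rec2$delta_f_Hz, rec$delta_f_Hz)
  expect_true(all(is.na(rec2$c_target_mol_per_L)))

  cp <- tempfile(fileext = ".txt")
  writeLines(c("C: 56.6", "V_s: 150", "f0: 5e6"), cp)
  cfg2 <- read_qcm_config(cp)
  expect_equal(cfg2$C, 56.6)
  expect_equal(cfg2$V_s, 150)
})
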