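test_that("chemical potentials follow their closed forms", {
  expect_equal(mu_ideal(1, z_tr = 1), 0)
  expect_equal(mu_ideal(exp(1) * 2, z_tr = 2), 1)
  expect_equal(mu_ideal(0.008), log(0.008))
  expect_warning(m0 <- mu_ideal(0), "-Inf")
  expect_identical(m0, -Inf)
  expect_equal(mu_real(0.01, a = 0, b = 0), mu_ideal(0.01))
  # b c = 0.5 at c = z_tr: -ln(0.5) + 1
  expect_equal(mu_real(1, z_tr = 1, a = 0, b = 0.5), -log(0.5) + 1)
  expect_error(mu_real(1, b = 2), "b \\* c >= 1")
})

test_that("mono-layer entropy peaks exactly at the half-saturation concentration", {
  p <- mono_ideal_params(0.75, 299.2, c_half = 0.007)
  tc <- thermo_curves(p, T = 285)
  expect_equal(entropy_curve(p, 0.007), p$P_M * log(2))
  expect_true(all(tc$entropy >= 0))
  pk <- entropy_peaks(tc)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$c, 0.007, tolerance = 1e-5)
  # single interior maximum for a range of n values
  for (n in c(0.3, 1, 2)) {
    pn <- mono_ideal_params(n, 100, 0.004)
    tcn <- thermo_curves(pn, c_grid = exp(seq(log(1e-5), log(1), length.out = 600)))
    pkn <- entropy_peaks(tcn)
    expect_equal(nrow(pkn), 1)
    expect_equal(pkn$c, 0.004, tolerance = 1e-5)
  }
  # vanishing limits
  expect_equal(entropy_curve(p, 0), 0)
  expect_lt(entropy_curve(p, 1e4), 1e-2 * p$P_M)
})

test_that("entropy matches the beta-derivative of the partition function", {
  # S/k_B per site = ln z - beta (E + mu) x / (1 + x), evaluated by central
  # finite difference of ln z in beta at fixed energy and chemical potential
  p <- mono_ideal_params(0.8, 1, 0.005)
  cg <- exp(seq(log(2e-4), log(0.03), length.out = 15))
  lnx <- p$n * log(cg / p$c_half)     # beta (E + mu) at beta = 1
  h <- 1e-6
  lnz <- function(beta) log(1 + exp(beta * lnx))
  s_fd <- lnz(1) - (lnz(1 + h) - lnz(1 - h)) / (2 * h)
  expect_lt(max(abs(s_fd / entropy_curve(p, cg) - 1)), 1e-4)
})

test_that("free enthalpy is negative below z_tr and anchored at half saturation", {
  p <- mono_ideal_params(0.94, 421.4, 0.008)
  # G/(k_B T) at c = c_half with z_tr = 1: n P_M ln(c_half) / 2
  expect_equal(gibbs_curve(p, 0.008), p$n * p$P_M * log(0.008) / 2)
  cg <- default_grid(100)
  expect_true(all(gibbs_curve(p, cg) < 0))
  expect_equal(gibbs_curve(p, 0), 0)
  # occupancy factor beats the log divergence near zero
  expect_lt(abs(gibbs_curve(p, 1e-10)), 1e-3)
})

test_that("real-gas thermodynamics collapse onto the ideal forms at a = b = 0", {
  cg <- default_grid(60)
  pr <- mono_real_params(0.84, 355.2, 0.0069, a = 0, b = 0)
  pi <- mono_ideal_params(0.84, 355.2, 0.0069)
  expect_lt(rel_err(entropy_curve(pr, cg), entropy_curve(pi, cg)), 1e-12)
  expect_equal(gibbs_curve(pr, cg), gibbs_curve(pi, cg))
  expect_error(thermo_curves(double_real_params(1, 1, 0.01, 0.1)),
               "implemented for")
})

test_that("well-separated double layers show a peak at c1 and at the crossover", {
  # frozen from an independent dense-grid evaluation: peaks at c = 1e-4 and
  # at c2^2 / c1 = 1e4, both of height ln 2 per site
  p <- double_ideal_params(n = 1, P_M = 1, c1 = 1e-4, c2 = 1)
  tc <- thermo_curves(p, c_grid = exp(seq(log(1e-6), log(1e6),
                                          length.out = 2000)))
  pk <- entropy_peaks(tc)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$c[1], 1e-4, tolerance = 1e-3)
  expect_equal(pk$c[2], 1e4, tolerance = 1e-3)
  expect_equal(pk$S_over_kB, rep(log(2), 2), tolerance = 1e-4)
  # the published-variant exponent gives a different curve (kept as a switch)
  cg <- default_grid(30)
  pcr <- double_ideal_params(0.73, 279.4, 0.0031, 0.025)
  expect_gt(max(abs(entropy_curve(pcr, cg, as_printed = TRUE) -
                    entropy_curve(pcr, cg))), 1e-3)
})

test_that("monotone entropy sections yield no interior peaks", {
  p <- mono_ideal_params(0.9, 100, 0.01)
  tc <- thermo_curves(p, c_grid = exp(seq(log(1e-5), log(0.002),
                                          length.out = 300)))
  expect_equal(nrow(entropy_peaks(tc)), 0)
})

test_that("thermo curve files carry the configuration header", {
  p <- mono_ideal_params(0.75, 299.2, 0.007)
  tc <- thermo_curves(p, T = 285, z_tr = 1)
  fp <- tempfile(fileext = ".csv")
  write_thermo_curve(tc, fp)
  lines <- readLines(fp)
  expect_true(any(grepl("# z_tr=1", lines)))
  expect_true(any(grepl("beta_convention=reduced", lines)))
  body <- read.csv(fp, comment.char = "#")
  expect_equal(body$S_over_kB, tc$entropy, tolerance = 1e-10)
})
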