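test_that("selection is self-consistent on noiseless data", {
  zn <- fixture_curve("ZnCl2", 300)
  sel <- select_model(zn, c("mono_ideal", "double_ideal"))
  expect_equal(sel$chosen, "mono_ideal")
  expect_true(sel$gap_ok)
  # well-separated layers: the double model is identified
  pd <- double_ideal_params(0.73, 279.4, c1 = 5e-4, c2 = 0.015)
  dbl <- generate_isotherm(pd, T = 300)
  sel2 <- select_model(dbl, c("mono_ideal", "double_ideal"))
  expect_equal(sel2$chosen, "double_ideal")
})

test_that("ties fall to the more parsimonious candidate", {
  zn <- fixture_curve("ZnCl2", 300)
  # identical candidates: parameter-count rule keeps the first stable choice
  sel <- select_model(zn, c("mono_ideal", "mono_ideal"))
  expect_equal(sel$chosen, "mono_ideal")
  # a nested pair fitting equally well resolves to fewer parameters
  sel2 <- select_model(zn, c("mono_ideal", "double_ideal", "double_real"))
  expect_equal(sel2$chosen, "mono_ideal")
  expect_error(select_model(zn, "mono_ideal"), "at least 2")
})

test_that("temperature grids recover every fixture column", {
  curves <- lapply(c(285, 290, 295, 300), function(Tk) fixture_curve("ZnCl2", Tk))
  grid <- fit_temperatures(curves, "mono_ideal")
  truth <- rbind(n = c(0.75, 0.84, 0.91, 0.94),
                 P_M = c(299.2, 351.6, 379.5, 421.4),
                 c_half = c(0.007, 0.008, 0.009, 0.008))
  expect_lt(rel_err(as.matrix(grid$table), truth), 1e-4)
  expect_error(fit_temperatures(curves[1], "mono_ideal"), ">= 2")
})

test_that("trend classification reads the fitted parameter movements", {
  tab <- data.frame(T_285 = c(0.75, 299.2, 0.007),
                    T_290 = c(0.84, 351.6, 0.008),
                    T_295 = c(0.91, 379.5, 0.009),
                    T_300 = c(0.94, 421.4, 0.008))
  rownames(tab) <- c("n", "P_M", "c_half")
  tr <- trend_report(tab)
  expect_equal(tr$thermal_character, "endothermic")
  expect_equal(unname(tr$verdicts["c_half"]), "non-monotone")
  # reversed columns flip the verdict
  rev_tab <- tab[, 4:1]
  colnames(rev_tab) <- colnames(tab)
  expect_equal(trend_report(rev_tab)$thermal_character, "exothermic")
  # cohesion pressure trend is reported on its own
  ni <- data.frame(T_285 = c(0.55, 239.6, 9.9e-9),
                   T_290 = c(0.64, 259.2, 8.2e-9),
                   T_295 = c(0.72, 317.5, 7.6e-9),
                   T_300 = c(0.84, 355.2, 7.13e-9))
  rownames(ni) <- c("n", "P_M", "a")
  trn <- trend_report(ni)
  expect_equal(trn$thermal_character, "endothermic")
  expect_equal(unname(trn$verdicts["a"]), "decreasing")
  expect_error(trend_report(tab[, 1:2]), ">= 3")
  shuffled <- tab[, c(2, 1, 3, 4)]
  expect_warning(tr2 <- trend_report(shuffled), "unsorted")
  expect_equal(tr2$thermal_character, "endothermic")
})

test_that("noisy replicates keep parameter bias small and selection accurate", {
  fx <- published_fit_params()
  p <- fx$ZnCl2$params[["300"]]
  pd <- double_ideal_params(0.73, 279.4, c1 = 5e-4, c2 = 0.015)
  n_bias <- pm_bias <- numeric(20)
  correct <- 0
  for (r in 1:20) {
    iso <- generate_isotherm(p, noise = noise_model("mult_gauss", 0.02,
                                                    seed = 1234 + r), T = 300)
    f <- isofit(iso, "mono_ideal", weights = "relative")
    n_bias[r] <- coef(f)["n"] / p$n - 1
    pm_bias[r] <- coef(f)["P_M"] / p$P_M - 1
    correct <- correct +
      (select_model(iso, c("mono_ideal", "double_ideal"),
                    weights = "relative")$chosen == "mono_ideal")
    dbl <- generate_isotherm(pd, noise = noise_model("mult_gauss", 0.02,
                                                     seed = 5678 + r), T = 300)
    correct <- correct +
      (select_model(dbl, c("mono_ideal", "double_ideal"),
                    weights = "relative")$chosen == "double_ideal")
  }
  expect_lt(abs(median(n_bias)), 0.02)
  expect_lt(abs(median(pm_bias)), 0.02)
  expect_gte(correct / 40, 0.95)
})
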