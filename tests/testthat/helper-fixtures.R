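# shared helpers for the test suite

rel_err <- function(x, ref) max(abs(x / ref - 1))

# one noiseless synthetic curve per fixture system/temperature
fixture_curve <- function(system, T_K, n_points = 50) {
  fx <- published_fit_params()[[system]]
  generate_isotherm(fx$params[[as.character(T_K)]],
                    c_grid = default_grid(n_points), T = T_K)
}

# random but valid parameter sets for property tests
random_params <- function(model, rng_seed) {
  set.seed(rng_seed)
  n <- runif(1, 0.3, 2)
  P_M <- runif(1, 50, 500)
  cx <- sort(10^runif(2, -3.5, -1.5))
  switch(model,
    mono_ideal   = mono_ideal_params(n, P_M, cx[1]),
    mono_real    = mono_real_params(n, P_M, cx[1],
                                    a = runif(1, 0, 5), b = runif(1, 0, 1)),
    double_ideal = double_ideal_params(n, P_M, cx[1], cx[2]),
    double_real  = double_real_params(n, P_M, cx[1], cx[2],
                                      a = runif(1, 0, 5), b = runif(1, 0, 1))
  )
}
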