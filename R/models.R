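#' Closed-form isotherm models
#'
#' Adsorbed quantity `Q_a(c)` (ug/cm^2) as a function of equilibrium bulk
#' concentration `c` (mol/L) for the four grand-canonical adsorption models.
#' Each model is the occupancy of a per-site partition function `z_gc`,
#' `Q_a = n * P_M * d ln(z_gc) / d(beta mu)`, expressed in the concentration
#' representation where each Boltzmann factor `exp(beta (E + mu))` maps to a
#' concentration ratio:
#' \describe{
#'   \item{mono-layer ideal}{`Q_a = n P_M / (1 + (c_half / c)^n)`; saturates
#'     at `n P_M`, half-saturation exactly at `c = c_half`.}
#'   \item{mono-layer real}{`c_half` replaced by the lateral-interaction
#'     corrected `w_half * (1 - b c) * exp(2 beta a c) * exp(-b c / (1 - b c))`;
#'     can rise and then decline when the dimensionless groups `2 beta a c`
#'     and `b c` reach order one.}
#'   \item{double-layer ideal}{`Q_a = n P_M ((c/c1)^n + 2 (c/c2)^(2n)) /
#'     (1 + (c/c1)^n + (c/c2)^(2n))`; saturates at `2 n P_M` through an
#'     intermediate first-layer plateau when `c1 << c2`.}
#'   \item{double-layer real}{as double-layer ideal with `c/cx` replaced by
#'     the real-gas corrected ratio.}
#' }
#'
#' `c = 0` is handled by the analytic limit `Q_a(0) = 0`. Real-gas forms are
#' defined only for `b * c < 1` (covolume pole).
#'
#' @param c Concentration(s), mol/L, >= 0.
#' @param params Matching [iso_params] object.
#' @param T Temperature in K (used by the physical beta convention only).
#' @param mode A [units_mode()] object; default reduced (`beta = 1`).
#' @return Numeric vector of adsorbed quantities, ug/cm^2.
#' @examples
#' p <- mono_ideal_params(n = 0.94, P_M = 421.4, c_half = 0.008)
#' q_mono_ideal(0.008, p)   # half of the saturation n * P_M
#' @name iso_q_models
NULL

check_conc <- function(c) {
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentrations must be finite and >= 0")
  c
}

# real-gas correction factor g(c) multiplying the energetic concentration:
# c_eff = w * g(c),  g = (1 - b c) exp(2 beta a c) exp(-b c / (1 - b c))
real_gas_factor <- function(c, a, b, T, mode) {
  if (any(b * c >= 1))
    stop("real-gas form undefined: b * c >= 1 (covolume pole)")
  beta <- beta_value(mode, T)
  (1 - b * c) * exp(2 * beta * a * c) * exp(-b * c / (1 - b * c))
}

# occupation ratios y_i = exp(beta (E.. + k mu)) in concentration representation
model_ratios <- function(model, c, params, T = NULL, mode = units_mode()) {
  check_conc(c)
  p <- params
  switch(model,
    mono_ideal = {
      x <- ifelse(c == 0, 0, (c / p$c_half)^p$n)
      list(y = list(x), mult = 1)
    },
    mono_real = {
      g <- real_gas_factor(c, p$a, p$b, T, mode)
      x <- ifelse(c == 0, 0, (c / (p$w_half * g))^p$n)
      list(y = list(x), mult = 1)
    },
    double_ideal = {
      y1 <- ifelse(c == 0, 0, (c / p$c1)^p$n)
      y2 <- ifelse(c == 0, 0, (c / p$c2)^(2 * p$n))
      list(y = list(y1, y2), mult = c(1, 2))
    },
    double_real = {
      g <- real_gas_factor(c, p$a, p$b, T, mode)
      y1 <- ifelse(c == 0, 0, (c / (p$w1 * g))^p$n)
      y2 <- ifelse(c == 0, 0, (c / (p$w2 * g))^(2 * p$n))
      list(y = list(y1, y2), mult = c(1, 2))
    }
  )
}

q_from_ratios <- function(r, n, P_M) {
  num <- 0; den <- 1
  for (i in seq_along(r$y)) {
    num <- num + r$mult[i] * r$y[[i]]
    den <- den + r$y[[i]]
  }
  out <- n * P_M * num / den
  # saturation limit when ratios overflow
  sat <- n * P_M * max(r$mult)
  out[!is.finite(num) | !is.finite(den)] <- sat
  out
}

#' @rdname iso_q_models
#' @export
q_mono_ideal <- function(c, params) {
  stopifnot(params_model(params) == "mono_ideal")
  q_from_ratios(model_ratios("mono_ideal", c, params), params$n, params$P_M)
}

#' @rdname iso_q_models
#' @export
q_mono_real <- function(c, params, T = NULL, mode = units_mode()) {
  stopifnot(params_model(params) == "mono_real")
  q_from_ratios(model_ratios("mono_real", c, params, T, mode),
                params$n, params$P_M)
}

#' @rdname iso_q_models
#' @export
q_double_ideal <- function(c, params) {
  stopifnot(params_model(params) == "double_ideal")
  q_from_ratios(model_ratios("double_ideal", c, params), params$n, params$P_M)
}

#' @rdname iso_q_models
#' @export
q_double_real <- function(c, params, T = NULL, mode = units_mode()) {
  stopifnot(params_model(params) == "double_real")
  q_from_ratios(model_ratios("double_real", c, params, T, mode),
                params$n, params$P_M)
}

#' @rdname iso_q_models
#' @param model A model id (see [iso_models()]); defaults to the model of
#'   `params`.
#' @export
iso_q <- function(c, params, model = params_model(params), T = NULL,
                  mode = units_mode()) {
  model <- match_model(model)
  stopifnot(params_model(params) == model)
  q_from_ratios(model_ratios(model, c, params, T, mode), params$n, params$P_M)
}

#' Grand-canonical partition function
#'
#' Per-site partition function `z_gc` in the concentration representation:
#' `1 + x` for mono-layer models (`x` the occupation ratio) and
#' `1 + y1 + y2` for double-layer models. `z_gc >= 1` always, with equality
#' only at `c = 0` (empty-site state).
#'
#' @inheritParams iso_q_models
#' @inheritParams iso_q
#' @return Numeric vector of `z_gc` values (dimensionless).
#' @examples
#' p <- mono_ideal_params(1, 100, 0.01)
#' partition_function(0.01, p)   # 2 at half saturation
#' @export
partition_function <- function(c, params, model = params_model(params),
                               T = NULL, mode = units_mode()) {
  model <- match_model(model)
  r <- model_ratios(model, c, params, T, mode)
  Reduce(`+`, r$y, 1)
}

#' Occupancy by numerical differentiation of the partition function
#'
#' Independent route to the adsorbed quantity: computes
#' `Q_a = n * P_M * d ln(z_gc) / d(beta mu)` by a central finite difference in
#' the reduced chemical potential (each occupation ratio `y_k` scales as
#' `exp(k * h)` under a shift `h` of `beta mu`, with `k` the layer's adsorbate
#' count). Serves as a brute-force cross-check of the closed forms.
#'
#' @inheritParams iso_q
#' @param h Finite-difference step in `beta mu`; a warning is issued if the
#'   step is too large for the local curvature (checked against a half-step).
#' @return Numeric vector of adsorbed quantities, ug/cm^2.
#' @examples
#' p <- double_ideal_params(0.73, 279.4, 0.0031, 0.025)
#' q_partition_deriv(0.01, p)    # matches q_double_ideal(0.01, p)
#' @export
q_partition_deriv <- function(c, params, model = params_model(params),
                              T = NULL, mode = units_mode(), h = 1e-6) {
  model <- match_model(model)
  r <- model_ratios(model, c, params, T, mode)
  lnz_at <- function(s) {
    z <- 1
    for (i in seq_along(r$y)) {
      k <- if (r$mult[i] == 2) 2 else 1
      z <- z + r$y[[i]] * exp(k * s)
    }
    log(z)
  }
  d  <- (lnz_at(h) - lnz_at(-h)) / (2 * h)
  d2 <- (lnz_at(h / 2) - lnz_at(-h / 2)) / h
  bad <- is.finite(d) & is.finite(d2) & abs(d - d2) > 1e-3 * pmax(abs(d), 1)
  if (any(bad))
    warning("finite-difference step h too large for the local curvature; ",
            "reduce h")
  params$n * params$P_M * d
}

#' Saturation adsorbed quantity
#'
#' Large-concentration limit of each model: `n * P_M` for mono-layer models,
#' `2 * n * P_M` for double-layer models (both layers filled).
#'
#' @inheritParams iso_q
#' @return Saturation quantity, ug/cm^2.
#' @export
saturation_value <- function(params, model = params_model(params)) {
  model <- match_model(model)
  layers <- if (startsWith(model, "double")) 2 else 1
  layers * params$n * params$P_M
}

#' Adsorption energy from an energetic concentration parameter
#'
#' The energetic parameters of the isotherm models encode the adsorption
#' energy through `c_x = S * exp(-E_x / (k_B T))` with `S` the adsorbate
#' solubility, so `|E_x| = R T ln(S / c_x)` per mole. Energies are reported
#' as magnitudes in kJ/mol (`R = 8.314` J mol^-1 K^-1); magnitudes above
#' about 40 kJ/mol indicate chemisorption, below it physisorption.
#'
#' If `S <= c_x` the implied binding is weaker than solvation; the
#' (non-positive) magnitude is returned with a warning rather than an error.
#'
#' @param c_x Energetic concentration parameter(s), mol/L, > 0.
#' @param S Adsorbate solubility, mol/L, > 0.
#' @param T Temperature, K, > 0.
#' @return Energy magnitude(s) in kJ/mol.
#' @examples
#' adsorption_energy(0.008, S = exp(1) * 0.008, T = 300)  # R*T/1000
#' @export
adsorption_energy <- function(c_x, S, T) {
  if (any(!is.finite(c_x)) || any(c_x <= 0)) stop("c_x must be > 0")
  if (!is.finite(S) || S <= 0) stop("solubility S must be > 0")
  if (!is.finite(T) || T <= 0) stop("temperature T must be > 0")
  E <- .R_GAS * T * log(S / c_x) / 1000
  if (any(E <= 0))
    warning("S <= c_x: non-physical (binding weaker than solvation); ",
            "energy magnitude is not positive")
  E
}
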