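#' Noise models for synthetic data
#'
#' Multiplicative Gaussian noise is the natural error model for QCM-derived
#' adsorbed quantities, which span about two decades: each point is scaled by
#' `1 + eps` with `eps ~ N(0, sigma_rel^2)`. `kind = "none"` produces exact
#' curves.
#'
#' @param kind `"none"` or `"mult_gauss"`.
#' @param sigma_rel Relative standard deviation (>= 0; forced to 0 for
#'   `"none"`).
#' @param seed Integer seed; the same seed reproduces the same draws.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "mult_gauss"), sigma_rel = 0.02,
                        seed = 1) {
  kind <- match.arg(kind)
  if (kind == "none") sigma_rel <- 0
  if (!is.numeric(sigma_rel) || sigma_rel < 0)
    stop("sigma_rel must be >= 0")
  structure(list(kind = kind, sigma_rel = sigma_rel, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(q, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$kind == "none" || noise$sigma_rel == 0) return(q)
  eps <- with_seed(noise$seed, rnorm(length(q), 0, noise$sigma_rel))
  out <- q * (1 + eps)
  if (any(out < 0)) {
    warning("negative noisy adsorbed quantities clipped at 0")
    out[out < 0] <- 0
  }
  out
}

#' Default synthetic concentration grid
#'
#' 50 log-spaced concentrations on \[1e-4, 0.05\] mol/L, inside the range
#' reachable by diluting 1e-3 to 0.1 mol/L stocks into a 150 mL cell.
#'
#' @param n Number of points.
#' @param lo,hi Grid limits, mol/L.
#' @return Numeric vector.
#' @export
default_grid <- function(n = 50, lo = 1e-4, hi = 0.05) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Published fitted-parameter fixtures
#'
#' The fitted parameters of the three metal-chloride/porphyrin systems at
#' 285, 290, 295 and 300 K, with each system's adopted model: ZnCl2 with the
#' mono-layer ideal-gas model, NiCl2 with the mono-layer real-gas model and
#' CrCl2 with the double-layer ideal-gas model. These serve as generating
#' truths for synthetic isotherms and as recovery targets for the fitter.
#'
#' @return A named list (`ZnCl2`, `NiCl2`, `CrCl2`); each element has
#'   `system`, `model` and `params`, a list keyed by temperature (`"285"`,
#'   ..., `"300"`) of [iso_params] objects.
#' @examples
#' fx <- published_fit_params()
#' fx$ZnCl2$params[["300"]]
#' @export
published_fit_params <- function() {
  list(
    ZnCl2 = list(
      system = "ZnCl2", model = "mono_ideal",
      params = list(
        "285" = mono_ideal_params(n = 0.75, P_M = 299.2, c_half = 0.007),
        "290" = mono_ideal_params(n = 0.84, P_M = 351.6, c_half = 0.008),
        "295" = mono_ideal_params(n = 0.91, P_M = 379.5, c_half = 0.009),
        "300" = mono_ideal_params(n = 0.94, P_M = 421.4, c_half = 0.008)
      )
    ),
    NiCl2 = list(
      system = "NiCl2", model = "mono_real",
      params = list(
        "285" = mono_real_params(n = 0.55, P_M = 239.6, w_half = 0.006,
                                 a = 9.9e-9, b = 1.4e-12),
        "290" = mono_real_params(n = 0.64, P_M = 259.2, w_half = 0.0067,
                                 a = 8.2e-9, b = 2.1e-12),
        "295" = mono_real_params(n = 0.72, P_M = 317.5, w_half = 0.0073,
                                 a = 7.6e-9, b = 3.8e-12),
        "300" = mono_real_params(n = 0.84, P_M = 355.2, w_half = 0.0069,
                                 a = 7.13e-9, b = 4.4e-12)
      )
    ),
    CrCl2 = list(
      system = "CrCl2", model = "double_ideal",
      params = list(
        "285" = double_ideal_params(n = 0.41, P_M = 147.9, c1 = 0.0029, c2 = 0.026),
        "290" = double_ideal_params(n = 0.52, P_M = 184.8, c1 = 0.0032, c2 = 0.025),
        "295" = double_ideal_params(n = 0.64, P_M = 239.5, c1 = 0.0034, c2 = 0.024),
        "300" = double_ideal_params(n = 0.73, P_M = 279.4, c1 = 0.0031, c2 = 0.025)
      )
    )
  )
}

#' Write the fixture parameter sets as a delimited-text table
#'
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fixture_table <- function(path) {
  fx <- published_fit_params()
  rows <- list()
  for (s in fx) for (Tk in names(s$params)) {
    v <- params_vector(s$params[[Tk]])
    rows[[length(rows) + 1]] <- data.frame(
      system = s$system, model = s$model, T_K = as.numeric(Tk),
      parameter = names(v), value = unname(v))
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic isotherm
#'
#' Forward-simulates an [isotherm] from a model's closed form on a
#' concentration grid, optionally with multiplicative Gaussian noise.
#'
#' @param params An [iso_params] object (defines the model).
#' @param c_grid Concentration grid, mol/L (default [default_grid()]).
#' @param noise A [noise_model()] (default: none).
#' @param T Temperature, K.
#' @param mode A [units_mode()].
#' @return An [isotherm].
#' @examples
#' generate_isotherm(mono_ideal_params(0.94, 421.4, 0.008), T = 300)
#' @export
generate_isotherm <- function(params, c_grid = default_grid(),
                              noise = noise_model("none"), T = 298.15,
                              mode = units_mode()) {
  q <- iso_q(c_grid, params, T = T, mode = mode)
  q <- apply_noise(q, noise)
  isotherm(c_grid, q, T = T,
           provenance = sprintf("synthetic %s (noise %s, sigma_rel %g, seed %d)",
                                params_model(params), noise$kind,
                                noise$sigma_rel, noise$seed))
}

#' Mono-layer real-gas parameters with visible lateral interactions
#'
#' A synthetic parameter set in which the lateral-interaction groups reach
#' order one inside the default grid (`2 a c = 1` near `c = 0.017` and
#' `b c = 0.1` at `c = 0.05` mol/L, reduced beta convention), so the
#' generated isotherm rises and then declines past its maximum -- the signature of
#' adsorbate-adsorbate cohesion destabilising the adsorbed layer at high
#' concentration. Published fitted magnitudes of `a` (~1e-9) and `b` (~1e-12)
#' leave these groups around 1e-10 at such concentrations and cannot produce
#' a visible downtrend; this set exists so the non-monotone regime is
#' testable.
#'
#' @return A `mono_real` [iso_params] object.
#' @examples
#' p <- nickel_like_params()
#' q <- q_mono_real(default_grid(), p)
#' which.max(q) < length(q)   # interior maximum
#' @export
nickel_like_params <- function() {
  mono_real_params(n = 0.84, P_M = 355.2, w_half = 0.0069, a = 30, b = 2)
}

#' Generate a synthetic QCM injection trace
#'
#' Simulates the titration protocol that [reduce_trace()] inverts: for each
#' target concentration the injected stock volume follows matter conservation
#' (`v = delta_c * V_s / c0`), and the cumulative frequency shift is the
#' Sauerbrey image of the model's adsorbed quantity,
#' `delta_f = -C * Q_a(c) * (1 + eps)`.
#'
#' @param params An [iso_params] object.
#' @param targets Strictly increasing target concentrations, mol/L.
#' @param cfg A [qcm_config()].
#' @param c0 Stock concentration, mol/L (targets must stay below it).
#' @param noise A [noise_model()].
#' @param T Temperature, K.
#' @param mode A [units_mode()].
#' @return An `injection_log` data frame (see [injection_records()]).
#' @export
generate_qcm_trace <- function(params, targets, cfg, c0 = 0.1,
                               noise = noise_model("none"), T = 298.15,
                               mode = units_mode()) {
  stopifnot(inherits(cfg, "qcm_config"))
  check_conc(targets)
  if (any(diff(targets) <= 0)) stop("target concentrations must be strictly increasing")
  if (any(targets > c0)) stop("target concentration exceeds the stock concentration")
  dc <- diff(c(0, targets))
  v <- injection_volume(dc, cfg$V_s, c0)
  q <- apply_noise(iso_q(targets, params, T = T, mode = mode), noise)
  injection_records(c0 = c0, delta_f = -cfg$C * q, v_injected = v)
}
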