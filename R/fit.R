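#' Goodness-of-fit criteria
#'
#' The three criteria used to score and compare isotherm fits:
#' `R^2 = 1 - RSS/TSS`, `RMSE = sqrt(RSS / (N - k))` (residual
#' degrees-of-freedom convention) and the least-squares Akaike information
#' criterion `AIC = N * ln(RSS / N) + 2 k`. The RSS is floored at 1e-30 so a
#' numerically perfect fit yields a finite AIC. A model with `RMSE < 2` is
#' conventionally flagged as well-fitting; the lowest AIC picks the
#' descriptive model among candidates on the same data.
#'
#' @param observed,predicted Numeric vectors of equal length (>= `k_params + 2`).
#' @param k_params Number of freely fitted parameters.
#' @param rss_floor Lower bound applied to the RSS inside the AIC logarithm.
#'   [isofit()] raises it to the fit's numerical resolution (relative 1e-11
#'   per point) so that fits whose residuals are numerical dust score as
#'   exact ties instead of spurious AIC differences.
#' @return A list with `rss`, `r2`, `rmse`, `aic`, and `degenerate` (`TRUE`
#'   when the observed series has zero variance, in which case `r2` is `NA`).
#' @examples
#' goodness(c(1, 2, 3, 4), c(1, 2, 3, 5), k_params = 1)
#' @export
goodness <- function(observed, predicted, k_params, rss_floor = 1e-30) {
  N <- length(observed)
  if (length(predicted) != N) stop("observed and predicted lengths differ")
  if (N < k_params + 2) stop("need at least k_params + 2 points")
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  degenerate <- tss <= 0
  r2 <- if (degenerate) NA_real_ else 1 - rss / tss
  rmse <- sqrt(rss / (N - k_params))
  aic <- N * log(max(rss, rss_floor) / N) + 2 * k_params
  list(rss = rss, r2 = r2, rmse = rmse, aic = aic, degenerate = degenerate)
}

default_bounds <- function(model, curve) {
  qmax <- max(curve$q, 0)
  pm_hi <- max(10 * qmax, 1)
  nm <- param_names(model)
  lower <- c(n = 0.05, P_M = 1e-3,
             setNames(rep(1e-6, length(nm) - 2), nm[-(1:2)]))
  upper <- c(n = 5, P_M = pm_hi,
             setNames(rep(10, length(nm) - 2), nm[-(1:2)]))
  ab <- intersect(c("a", "b"), nm)
  lower[ab] <- 0
  upper[ab] <- 1e-6
  list(lower = lower[nm], upper = upper[nm])
}

default_start <- function(model, curve) {
  qmax <- max(curve$q, 1e-3)
  cmed <- median(curve$c)
  st <- switch(model,
    mono_ideal   = c(n = 1, P_M = qmax, c_half = cmed),
    mono_real    = c(n = 1, P_M = qmax, w_half = cmed, a = 0, b = 0),
    double_ideal = c(n = 1, P_M = qmax / 2, c1 = cmed, c2 = cmed),
    double_real  = c(n = 1, P_M = qmax / 2, w1 = cmed, w2 = cmed, a = 0, b = 0)
  )
  st
}

# log-uniform jitter of a start vector inside the box; a, b stay where they are
jitter_start <- function(start, lower, upper) {
  out <- start
  for (nm in names(start)) {
    if (nm %in% c("a", "b")) next
    f <- exp(runif(1, -log(20), log(20)))
    out[nm] <- min(max(start[nm] * f, lower[nm] * 1.0001),
                   upper[nm] * 0.9999)
  }
  out
}

#' Fit one isotherm model by multi-start Levenberg--Marquardt least squares
#'
#' Fits the chosen statistical-physics model to an [isotherm] by nonlinear
#' least squares (Levenberg--Marquardt via \pkg{minpack.lm}), restarting from
#' `n_starts` seeded log-uniform jitters of the default start and keeping the
#' converged solution with the lowest residual sum of squares. Parameters can
#' be held fixed (excluded from the fitted count `k_params`); bounds keep the
#' search in the physical region. Results are deterministic for a given seed.
#'
#' The real-gas lateral-interaction parameters `a` and `b` are numerically
#' inert when their dimensionless groups `2 beta a c` and `b c` are far below
#' one, which makes them ill-conditioned to fit freely; fixing them (e.g. at
#' independently known values) is recommended in that regime.
#'
#' @param curve An [isotherm].
#' @param model Model id, see [iso_models()].
#' @param start Optional named start vector (full parameter set).
#' @param lower,upper Optional named bound vectors overriding the defaults
#'   (`n` in \[0.05, 5\], `P_M` in \[1e-3, 10 max(q)\], energetic
#'   concentrations in \[1e-6, 10\] mol/L, `a`, `b` in \[0, 1e-6\]).
#' @param fixed Optional named vector of parameters to hold constant.
#' @param n_starts Number of starts (>= 1).
#' @param seed Integer seed for the start jitters.
#' @param T Temperature, K; defaults to the curve's.
#' @param mode A [units_mode()].
#' @param weights `"none"` minimises raw residuals (the conventional choice
#'   when absolute deviations are what matter); `"relative"` minimises
#'   residuals divided by the model prediction, the maximum-likelihood
#'   estimator when measurement noise is multiplicative (as QCM-derived
#'   quantities spanning two decades typically are). `rss` and `aic` refer to
#'   the minimised objective; `r2` and `rmse` are always reported on the raw
#'   scale.
#' @return An object of class `isofit` with components `model`, `params`
#'   (an [iso_params] object), `theta` (free fitted values), `fixed`, `rss`,
#'   `r2`, `rmse`, `aic`, `n_points`, `k_params`, `converged`, `degenerate`,
#'   `n_starts`, `seed`, `curve`, `T`, `mode`.
#' @examples
#' p <- mono_ideal_params(0.94, 421.4, 0.008)
#' iso <- generate_isotherm(p, T = 300)
#' fit <- isofit(iso, "mono_ideal")
#' coef(fit)
#' @export
isofit <- function(curve, model = "mono_ideal", start = NULL,
                   lower = NULL, upper = NULL, fixed = NULL,
                   n_starts = 5, seed = 1, T = curve$T,
                   mode = units_mode(), weights = c("none", "relative")) {
  stopifnot(inherits(curve, "isotherm"))
  weights <- match.arg(weights)
  model <- match_model(model)
  nm <- param_names(model)
  bounds <- default_bounds(model, curve)
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper
  st <- default_start(model, curve)
  if (!is.null(start)) st[names(start)] <- start
  st <- pmin(pmax(st, bounds$lower), bounds$upper)

  fixed <- unlist(fixed)
  if (length(fixed) && !all(names(fixed) %in% nm))
    stop("unknown fixed parameter(s): ",
         paste(setdiff(names(fixed), nm), collapse = ", "))
  free <- setdiff(nm, names(fixed))
  if (!length(free)) stop("no free parameters left to fit")
  k <- length(free)
  if (length(curve$c) < k + 2)
    stop("curve has fewer than k_params + 2 points")

  make_params <- function(theta) {
    full <- st
    full[names(fixed)] <- fixed
    full[names(theta)] <- theta
    do.call(iso_params, c(list(model = model), as.list(full)))
  }
  resid_fn <- function(theta) {
    p <- make_params(theta)
    pred <- iso_q(curve$c, p, T = T, mode = mode)
    r <- curve$q - pred
    if (weights == "relative") r <- r / pmax(abs(pred), 1e-9)
    r[!is.finite(r)] <- 1e6
    r
  }

  starts <- list(st[free])
  if (startsWith(model, "double")) {
    # layer-separated start: first layer in the lower grid decade, second near
    # the grid top, where the two-plateau structure actually lives
    cw <- intersect(c("c1", "c2", "w1", "w2"), nm)
    st2 <- st
    st2["P_M"] <- max(curve$q, 1e-3)
    st2[cw[2]] <- max(curve$c)
    st2 <- pmin(pmax(st2, bounds$lower), bounds$upper)
    starts <- c(starts, list(st2[free]))
  }
  if (n_starts > 1) {
    jit <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i)
      jitter_start(st, bounds$lower, bounds$upper)[free]))
    starts <- c(starts, jit)
  }

  best <- NULL
  for (s0 in starts) {
    res <- try(minpack.lm::nls.lm(
      par = s0, fn = resid_fn,
      lower = bounds$lower[free], upper = bounds$upper[free],
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-14, ptol = 1e-14)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    cand <- list(fit = res, ok = res$info %in% 1:4, rss = res$deviance)
    if (is.null(best) || (cand$ok && !best$ok) ||
        (cand$ok == best$ok && cand$rss < best$rss))
      best <- cand
  }
  if (is.null(best))
    stop("all optimisation starts failed for model ", model)

  theta <- best$fit$par
  params <- make_params(theta)
  pred <- iso_q(curve$c, params, T = T, mode = mode)
  scale <- if (weights == "relative") 1 else max(abs(curve$q), 1)
  floor_num <- max(1e-30, length(curve$q) * (1e-11 * scale)^2)
  g <- goodness(curve$q, pred, k_params = k, rss_floor = floor_num)
  if (weights == "relative") {
    # criteria on the minimised (relative) objective; r2/rmse stay raw-scale
    g$rss <- best$rss
    g$aic <- length(curve$q) * log(max(best$rss, floor_num) /
                                     length(curve$q)) + 2 * k
  }
  at_lower <- free[abs(theta - bounds$lower[free]) <
                     1e-8 * pmax(abs(bounds$lower[free]), 1)]

  structure(list(
    model = model, params = params, theta = theta, fixed = fixed,
    rss = g$rss, r2 = g$r2, rmse = g$rmse, aic = g$aic,
    n_points = length(curve$c), k_params = k,
    converged = best$ok, degenerate = g$degenerate,
    at_lower_bound = at_lower, weights = weights,
    n_starts = n_starts, seed = seed,
    curve = curve, T = T, mode = mode
  ), class = "isofit")
}

#' @export
print.isofit <- function(x, ...) {
  cat(sprintf("<isofit> %s, T = %g K, %d points%s\n", x$model, x$T,
              x$n_points,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  v <- params_vector(x$params)
  fx <- names(x$fixed)
  lbl <- ifelse(names(v) %in% fx, " (fixed)", "")
  cat(paste0("  ", format(names(v), width = 7), " = ",
             signif(v, 6), lbl, collapse = "\n"), "\n")
  cat(sprintf("  R2 = %s, RMSE = %.4g, AIC = %.4g\n",
              if (is.na(x$r2)) "NA (zero-variance data)" else sprintf("%.6f", x$r2),
              x$rmse, x$aic))
  if (x$degenerate) cat("  flagged degenerate (constant observations)\n")
  if (length(x$at_lower_bound))
    cat("  at lower bound:", paste(x$at_lower_bound, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.isofit <- function(object, ...) params_vector(object$params)

#' @export
predict.isofit <- function(object, newdata = NULL, ...) {
  c <- if (is.null(newdata)) object$curve$c
       else if (is.data.frame(newdata)) {
         cn <- intersect(c("c", "c_mol_per_L"), names(newdata))
         if (!length(cn)) stop("newdata must contain a 'c' column")
         newdata[[cn[1]]]
       } else as.numeric(newdata)
  iso_q(c, object$params, T = object$T, mode = object$mode)
}

#' @export
fitted.isofit <- function(object, ...) predict(object)

#' @export
residuals.isofit <- function(object, ...) object$curve$q - fitted(object)

#' @export
AIC.isofit <- function(object, ...) object$aic

#' @export
summary.isofit <- function(object, ...) {
  structure(list(fit = object), class = "summary.isofit")
}

#' @export
print.summary.isofit <- function(x, ...) {
  f <- x$fit
  print(f)
  r <- residuals(f)
  cat(sprintf("  residuals: min %.4g / median %.4g / max %.4g\n",
              min(r), median(r), max(r)))
  cat(sprintf("  saturation value: %.6g ug/cm^2\n",
              saturation_value(f$params)))
  cat(sprintf("  starts: %d (seed %d); free parameters: %d\n",
              f$n_starts, f$seed, f$k_params))
  invisible(x)
}

#' @export
plot.isofit <- function(x, n_grid = 200, ...) {
  cr <- x$curve
  plot(cr$c, cr$q, xlab = "c [mol/L]",
       ylab = expression(Q[a] ~ "[" * mu * g / cm^2 * "]"),
       main = sprintf("%s fit at %g K", x$model, x$T), ...)
  cg <- exp(seq(log(max(min(cr$c), 1e-12)), log(max(cr$c)), length.out = n_grid))
  lines(cg, predict(x, cg), col = "red3")
  invisible(x)
}

#' Simulate replicate isotherms from a fitted model
#'
#' Draws `nsim` noisy isotherms from the fitted model on the fitted curve's
#' concentration grid, with multiplicative Gaussian noise of relative
#' standard deviation `sigma_rel` (the generative model assumed by the
#' analysis).
#'
#' @param object An `isofit`.
#' @param nsim Number of replicate curves.
#' @param seed Integer seed.
#' @param sigma_rel Relative noise standard deviation.
#' @param ... Unused.
#' @return A list of [isotherm] objects.
#' @export
simulate.isofit <- function(object, nsim = 1, seed = 1, sigma_rel = 0.02, ...) {
  lapply(seq_len(nsim), function(i)
    generate_isotherm(object$params, c_grid = object$curve$c,
                      noise = noise_model("mult_gauss", sigma_rel = sigma_rel,
                                          seed = seed + i - 1),
                      T = object$T, mode = object$mode))
}
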