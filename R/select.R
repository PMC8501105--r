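#' Fit several candidate models and select the descriptive one
#'
#' Fits every candidate model to the same isotherm with [isofit()] and picks
#' the converged fit with the lowest AIC. Models within `delta_aic_tie` AIC
#' units of the minimum are treated as statistically equivalent and the most
#' parsimonious of them is preferred (the conventional "delta AIC < 2"
#' equivalence band; set `delta_aic_tie = 0` for strict AIC minimisation);
#' residual ties are broken by higher `R^2`, then by fewer free parameters.
#' The report also states whether the chosen
#' fit's maximum relative residual is within 5\% (the conventional 95\%
#' confidence gap for a descriptive fit; evaluated on points above 1\% of the
#' curve maximum so near-zero observations do not dominate the ratio).
#'
#' @param curve An [isotherm].
#' @param candidates Character vector of model ids (>= 2), see [iso_models()].
#' @param delta_aic_tie AIC-equivalence band width (default 2).
#' @param ... Passed on to [isofit()] (e.g. `n_starts`, `seed`, `fixed`).
#' @return An object of class `iso_selection`: list with `fits` (named list
#'   of `isofit`), `chosen` (model id), `criteria` (data frame of R^2, RMSE,
#'   AIC per candidate), `gap_ok` and `max_rel_residual`.
#' @examples
#' iso <- generate_isotherm(mono_ideal_params(0.94, 421.4, 0.008), T = 300)
#' sel <- select_model(iso, c("mono_ideal", "double_ideal"))
#' sel$chosen
#' @export
select_model <- function(curve, candidates = iso_models(), delta_aic_tie = 2,
                         ...) {
  candidates <- vapply(candidates, match_model, "")
  if (length(candidates) < 2) stop("need at least 2 candidate models")
  fits <- lapply(candidates, function(m)
    try(isofit(curve, model = m, ...), silent = TRUE))
  names(fits) <- make.unique(candidates)
  failed <- vapply(fits, inherits, TRUE, what = "try-error")
  fits <- fits[!failed]
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(conv)) stop("no candidate model converged")

  crit <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    k_params = vapply(fits, `[[`, 0, "k_params"),
    r2 = vapply(fits, `[[`, 0, "r2"),
    rmse = vapply(fits, `[[`, 0, "rmse"),
    aic = vapply(fits, `[[`, 0, "aic"),
    converged = conv,
    row.names = NULL
  )
  pool <- which(conv)
  best_aic <- min(crit$aic[pool])
  # models within delta_aic_tie of the minimum are equivalent: prefer the
  # most parsimonious, then higher r2, then lower AIC
  band <- pool[crit$aic[pool] <= best_aic + delta_aic_tie]
  o <- band[order(crit$k_params[band], -crit$r2[band], crit$aic[band])]
  chosen_i <- o[1]
  chosen_fit <- fits[[chosen_i]]

  res <- residuals(chosen_fit)
  keep <- curve$q > 0.01 * max(curve$q)
  max_rel <- if (any(keep)) max(abs(res[keep]) / curve$q[keep]) else NA_real_

  structure(list(
    fits = fits, chosen = chosen_fit$model, chosen_fit = chosen_fit,
    criteria = crit, gap_ok = isTRUE(max_rel <= 0.05),
    max_rel_residual = max_rel, T = curve$T
  ), class = "iso_selection")
}

#' @export
print.iso_selection <- function(x, ...) {
  cat(sprintf("<iso_selection> T = %g K; chosen model: %s\n", x$T, x$chosen))
  df <- x$criteria
  df$r2 <- signif(df$r2, 4); df$rmse <- signif(df$rmse, 4)
  df$aic <- signif(df$aic, 5)
  print(df, row.names = FALSE)
  cat(sprintf("  max relative residual %.3g -> 5%% gap %s\n",
              x$max_rel_residual, if (x$gap_ok) "satisfied" else "exceeded"))
  invisible(x)
}

#' Fit one model across several temperatures
#'
#' Fits the same model to each temperature's isotherm and assembles the
#' fitted parameters into a parameters-by-temperature table (one column per
#' temperature, as fitted-parameter tables are conventionally printed). A
#' failed temperature is recorded and the others continue.
#'
#' @param curves A list of [isotherm] objects at distinct temperatures (>= 2).
#' @param model Model id.
#' @param mode A [units_mode()] (an explicit formal here so that it is never
#'   partially matched against `model`).
#' @param ... Passed on to [isofit()].
#' @return An object of class `isofit_grid`: list with `fits` (per
#'   temperature), `table` (data frame, rows = parameters, columns = `T_<K>`),
#'   `model`, `temperatures`, `errors`.
#' @export
fit_temperatures <- function(curves, model, mode = units_mode(), ...) {
  if (length(curves) < 2) stop("need isotherms at >= 2 temperatures")
  stopifnot(all(vapply(curves, inherits, TRUE, what = "isotherm")))
  Ts <- vapply(curves, `[[`, 0, "T")
  ord <- order(Ts)
  curves <- curves[ord]; Ts <- Ts[ord]
  fits <- vector("list", length(curves))
  errors <- character(0)
  for (i in seq_along(curves)) {
    f <- try(isofit(curves[[i]], model = model, mode = mode, ...),
             silent = TRUE)
    if (inherits(f, "try-error")) {
      errors <- c(errors, sprintf("T=%g: %s", Ts[i], conditionMessage(attr(f, "condition"))))
      fits[i] <- list(NULL)
    } else fits[[i]] <- f
  }
  if (all(vapply(fits, is.null, TRUE))) stop("every temperature failed to fit")
  nm <- param_names(model)
  tab <- as.data.frame(setNames(lapply(fits, function(f)
    if (is.null(f)) rep(NA_real_, length(nm)) else unname(params_vector(f$params))),
    sprintf("T_%g", Ts)))
  rownames(tab) <- nm
  structure(list(fits = fits, table = tab, model = model,
                 temperatures = Ts, errors = errors),
            class = "isofit_grid")
}

#' @export
print.isofit_grid <- function(x, ...) {
  cat(sprintf("<isofit_grid> model %s at %d temperatures (%s K)\n",
              x$model, length(x$temperatures),
              paste(x$temperatures, collapse = ", ")))
  print(signif(as.matrix(x$table), 5))
  if (length(x$errors)) cat("  failed:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

monotone_verdict <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 2) return("undetermined")
  d <- diff(v)
  if (all(d > 0)) "increasing"
  else if (all(d < 0)) "decreasing"
  else if (all(d == 0)) "constant"
  else "non-monotone"
}

#' Temperature-trend report and thermal character
#'
#' Classifies how the fitted parameters move with temperature. A monotone
#' increase of both steric parameters `n` and `P_M` with temperature marks
#' the adsorption as endothermic (heating activates additional receptor
#' sites); a monotone decrease of both marks it exothermic; anything else is
#' mixed. The cohesion pressure `a`, where present, is reported with its own
#' trend (lateral interactions typically weaken on heating).
#'
#' @param x An `isofit_grid`, or a data frame shaped like its `table`
#'   (rows = parameters incl. `n` and `P_M`, one column per temperature in
#'   increasing order).
#' @return An object of class `iso_trend`: list with `table`, `verdicts`
#'   (named character), `thermal_character`.
#' @export
trend_report <- function(x) {
  if (inherits(x, "isofit_grid")) {
    tab <- x$table; Ts <- x$temperatures
  } else {
    tab <- as.data.frame(x)
    Ts <- suppressWarnings(as.numeric(sub("^T_", "", colnames(tab))))
    if (any(is.na(Ts))) Ts <- seq_len(ncol(tab))
  }
  if (ncol(tab) < 3) stop("trend classification needs >= 3 temperatures")
  if (is.unsorted(Ts)) {
    warning("temperatures were unsorted; sorting")
    o <- order(Ts); tab <- tab[, o, drop = FALSE]; Ts <- Ts[o]
  }
  if (!all(c("n", "P_M") %in% rownames(tab)))
    stop("parameter table must contain rows 'n' and 'P_M'")
  verdicts <- vapply(rownames(tab), function(p)
    monotone_verdict(as.numeric(tab[p, ])), "")
  thermal <- if (verdicts["n"] == "increasing" && verdicts["P_M"] == "increasing")
    "endothermic"
  else if (verdicts["n"] == "decreasing" && verdicts["P_M"] == "decreasing")
    "exothermic"
  else "mixed"
  structure(list(table = tab, temperatures = Ts,
                 verdicts = verdicts, thermal_character = thermal),
            class = "iso_trend")
}

#' @export
print.iso_trend <- function(x, ...) {
  cat("<iso_trend> thermal character:", x$thermal_character, "\n")
  for (p in names(x$verdicts))
    cat(sprintf("  %-7s %s\n", p, x$verdicts[p]))
  invisible(x)
}
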