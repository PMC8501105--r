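#' Isotherm model identifiers
#'
#' The four statistical-physics isotherm models: mono-layer or double-layer
#' site occupation, each under the ideal-gas or real-gas (van der Waals
#' lateral interaction) chemical potential.
#'
#' @return Character vector of the four model ids.
#' @examples
#' iso_models()
#' @export
iso_models <- function() {
  c("mono_ideal", "mono_real", "double_ideal", "double_real")
}

match_model <- function(model) {
  match.arg(model, iso_models())
}

#' Model parameter constructors
#'
#' Build validated parameter sets for the four isotherm models. All models
#' share the steric parameters `n` (ions captured per receptor site,
#' dimensionless; `n < 1` is interpreted as multi-docking) and `P_M`
#' (receptor-site density, ug/cm^2). The energetic parameters are
#' concentrations (mol/L) encoding the adsorption energy through
#' `c_x = S * exp(-E_x / (k_B T))`:
#' \describe{
#'   \item{mono-layer ideal}{`c_half`, the half-saturation concentration.}
#'   \item{mono-layer real}{`w_half` plus the lateral-interaction parameters
#'     `a` (cohesion pressure) and `b` (covolume).}
#'   \item{double-layer ideal}{`c1`, `c2`: first and second layer energetic
#'     concentrations.}
#'   \item{double-layer real}{`w1`, `w2`, `a`, `b`.}
#' }
#'
#' @param n Ions per site, > 0.
#' @param P_M Receptor-site density in ug/cm^2, > 0.
#' @param c_half,w_half,c1,c2,w1,w2 Energetic concentration parameters, mol/L, > 0.
#' @param a Cohesion pressure (declared-unit scalar, >= 0).
#' @param b Covolume (declared-unit scalar, >= 0); evaluation requires `b*c < 1`.
#' @return A named list of class `iso_params` with attribute `model`.
#' @examples
#' mono_ideal_params(n = 0.94, P_M = 421.4, c_half = 0.008)
#' double_ideal_params(n = 0.73, P_M = 279.4, c1 = 0.0031, c2 = 0.025)
#' @name iso_params
NULL

new_params <- function(model, fields) {
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a finite numeric scalar", nm))
  }
  strict_pos <- setdiff(names(fields), c("a", "b"))
  bad <- strict_pos[vapply(fields[strict_pos], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  if (!is.null(fields$a) && fields$a < 0) stop("cohesion pressure a must be >= 0")
  if (!is.null(fields$b) && fields$b < 0) stop("covolume b must be >= 0")
  structure(fields, class = "iso_params", model = model)
}

#' @rdname iso_params
#' @export
mono_ideal_params <- function(n, P_M, c_half) {
  new_params("mono_ideal", list(n = n, P_M = P_M, c_half = c_half))
}

#' @rdname iso_params
#' @export
mono_real_params <- function(n, P_M, w_half, a = 0, b = 0) {
  new_params("mono_real", list(n = n, P_M = P_M, w_half = w_half, a = a, b = b))
}

#' @rdname iso_params
#' @export
double_ideal_params <- function(n, P_M, c1, c2) {
  new_params("double_ideal", list(n = n, P_M = P_M, c1 = c1, c2 = c2))
}

#' @rdname iso_params
#' @export
double_real_params <- function(n, P_M, w1, w2, a = 0, b = 0) {
  new_params("double_real", list(n = n, P_M = P_M, w1 = w1, w2 = w2, a = a, b = b))
}

#' @rdname iso_params
#' @param model A model id (see [iso_models()]).
#' @param ... Fields passed to the matching constructor.
#' @export
iso_params <- function(model, ...) {
  model <- match_model(model)
  switch(model,
    mono_ideal   = mono_ideal_params(...),
    mono_real    = mono_real_params(...),
    double_ideal = double_ideal_params(...),
    double_real  = double_real_params(...)
  )
}

param_names <- function(model) {
  switch(match_model(model),
    mono_ideal   = c("n", "P_M", "c_half"),
    mono_real    = c("n", "P_M", "w_half", "a", "b"),
    double_ideal = c("n", "P_M", "c1", "c2"),
    double_real  = c("n", "P_M", "w1", "w2", "a", "b")
  )
}

params_model <- function(params) {
  m <- attr(params, "model")
  if (is.null(m)) stop("not an iso_params object (missing model attribute)")
  m
}

params_vector <- function(params) {
  unlist(params[param_names(params_model(params))])
}

#' @export
print.iso_params <- function(x, ...) {
  cat("<iso_params:", params_model(x), ">\n")
  v <- params_vector(x)
  cat(paste0("  ", format(names(v), width = 7), " = ", signif(v, 6),
             collapse = "\n"), "\n")
  invisible(x)
}
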