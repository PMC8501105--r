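#' Units and beta conventions
#'
#' The real-gas chemical potential and the lateral-interaction correction
#' `exp(2 * beta * a * c)` depend on the inverse thermal energy `beta`. Two
#' conventions are supported:
#' \describe{
#'   \item{`"reduced"`}{`beta == 1`; the cohesion pressure `a` and covolume `b`
#'     are used verbatim as dimensionless-group scalars. This is the default,
#'     so that published fitted magnitudes of `a` and `b` can be plugged in
#'     directly without a unit declaration.}
#'   \item{`"physical"`}{`beta == 1 / (R * T)` with
#'     `R = 8.314` J mol^-1 K^-1, for unit-explicit work where `a * c` carries
#'     J/mol.}
#' }
#' Concentrations are mol/L and adsorbed quantities ug/cm^2 throughout.
#'
#' @param convention `"reduced"` or `"physical"`.
#' @return An object of class `units_mode`.
#' @examples
#' units_mode()                      # reduced, beta = 1
#' beta_value(units_mode("physical"), T = 300)
#' @export
units_mode <- function(convention = c("reduced", "physical")) {
  convention <- match.arg(convention)
  structure(list(convention = convention), class = "units_mode")
}

#' @rdname units_mode
#' @param mode A `units_mode` object.
#' @param T Temperature in K (used only for the physical convention).
#' @export
beta_value <- function(mode = units_mode(), T = NULL) {
  stopifnot(inherits(mode, "units_mode"))
  if (mode$convention == "reduced") return(1)
  if (is.null(T) || !is.finite(T) || T <= 0)
    stop("physical beta convention requires a positive temperature T [K]")
  1 / (.R_GAS * T)
}

#' @export
print.units_mode <- function(x, ...) {
  cat("units_mode:", x$convention,
      if (x$convention == "reduced") "(beta = 1)" else "(beta = 1/(R T))",
      "\n  concentration: mol/L; adsorbed quantity: ug/cm^2\n")
  invisible(x)
}

# run code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
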