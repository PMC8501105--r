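#' Isotherm curves
#'
#' An `isotherm` holds one temperature's equilibrium adsorption series: a
#' strictly increasing concentration grid `c` (mol/L) and the matching
#' adsorbed quantities `q` (ug/cm^2). At least 4 points are required for a
#' curve to be fittable.
#'
#' @param c Equilibrium concentrations, mol/L, strictly increasing.
#' @param q Adsorbed quantities, ug/cm^2, finite, same length as `c`.
#' @param T Temperature, K.
#' @param provenance Free-text origin tag (file name, generator call, ...).
#' @return An object of class `isotherm`.
#' @examples
#' iso <- isotherm(c = c(0.001, 0.005, 0.01, 0.05),
#'                 q = c(50, 150, 220, 260), T = 300)
#' iso
#' @export
isotherm <- function(c, q, T, provenance = "") {
  c <- as.numeric(c); q <- as.numeric(q)
  if (length(c) != length(q)) stop("c and q must have equal length")
  if (length(c) < 4L) stop("an isotherm needs at least 4 points")
  if (any(!is.finite(c)) || any(c < 0)) stop("c must be finite and >= 0")
  if (any(diff(c) <= 0)) stop("c must be strictly increasing")
  if (any(!is.finite(q))) stop("q must be finite")
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("T must be a positive scalar temperature in K")
  structure(list(c = c, q = q, T = T, provenance = as.character(provenance)),
            class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("<isotherm> T = %g K, %d points, c in [%g, %g] mol/L, max q = %g ug/cm^2\n",
              x$T, length(x$c), min(x$c), max(x$c), max(x$q)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
plot.isotherm <- function(x, ...) {
  plot(x$c, x$q, xlab = "c [mol/L]", ylab = expression(Q[a] ~ "[" * mu * g / cm^2 * "]"),
       main = sprintf("Isotherm at %g K", x$T), ...)
  invisible(x)
}

#' @export
as.data.frame.isotherm <- function(x, ...) {
  data.frame(c_mol_per_L = x$c, q_ug_per_cm2 = x$q)
}

#' Read and write isotherm files
#'
#' Plain-text dialect: `#`-prefixed metadata header lines (`# T_K=...`,
#' `# provenance=...`) followed by a CSV body with columns
#' `c_mol_per_L,q_ug_per_cm2`.
#'
#' @param x An `isotherm`.
#' @param path File path.
#' @return `read_isotherm()` returns an `isotherm`; `write_isotherm()` returns
#'   `path` invisibly.
#' @export
write_isotherm <- function(x, path) {
  stopifnot(inherits(x, "isotherm"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# T_K=%.10g", x$T), con)
  if (nzchar(x$provenance))
    writeLines(paste0("# provenance=", x$provenance), con)
  writeLines("c_mol_per_L,q_ug_per_cm2", con)
  writeLines(sprintf("%.12g,%.12g", x$c, x$q), con)
  invisible(path)
}

#' @rdname write_isotherm
#' @export
read_isotherm <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  T <- get_meta("T_K")
  if (is.null(T)) stop("isotherm file lacks a '# T_K=' header: ", path)
  prov <- get_meta("provenance")
  body <- read.csv(text = lines[!grepl("^#", lines)])
  need <- c("c_mol_per_L", "q_ug_per_cm2")
  if (!all(need %in% names(body)))
    stop("isotherm file must have columns ", paste(need, collapse = ", "))
  isotherm(body$c_mol_per_L, body$q_ug_per_cm2, T = as.numeric(T),
           provenance = if (is.null(prov)) basename(path) else prov)
}
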