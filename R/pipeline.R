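#' Run the full isotherm-analysis pipeline
#'
#' Chains every stage on a set of isotherms (or QCM traces): model selection
#' per temperature, adoption of the majority-selected model, a
#' parameters-by-temperature fit table, adsorption energies (when a
#' solubility `S` is supplied), entropy and free-enthalpy curves, and a
#' temperature-trend classification. When `out_dir` is given, all artifacts
#' are written there as delimited text with the configuration echoed into
#' `report.txt`; re-running with the same inputs and seed reproduces them
#' exactly.
#'
#' Adsorption energies depend on the adsorbate solubility through
#' `|E| = R T ln(S / c_x)`; no default is provided and the energy table is
#' emitted only when `S` is passed.
#'
#' @param input A directory of isotherm / injection-log files, a character
#'   vector of file paths, or a list of [isotherm] objects. Injection logs
#'   (recognised by their `delta_f_Hz` column) require `qcm`.
#' @param out_dir Optional output directory (created if missing).
#' @param candidates Candidate model ids for selection.
#' @param qcm Optional [qcm_config()], needed to reduce injection logs.
#' @param S Optional adsorbate solubility, mol/L, for the energy table.
#' @param z_tr Translational partition reference for the thermodynamics.
#' @param n_starts,seed Multi-start fitting options (see [isofit()]).
#' @param mode A [units_mode()].
#' @param fixed Optional named vector of fixed parameters passed to the fits.
#' @return An object of class `iso_report`: list with `selections` (per
#'   temperature), `adopted` (model id), `grid` (the [fit_temperatures()]
#'   result), `energies` (data frame or `NULL`), `thermo` (per-temperature
#'   `thermo_curve`s), `trend`, `config`, `failures`.
#' @export
run_pipeline <- function(input, out_dir = NULL, candidates = iso_models(),
                         qcm = NULL, S = NULL, z_tr = 1,
                         n_starts = 5, seed = 1, mode = units_mode(),
                         fixed = NULL) {
  curves <- load_pipeline_input(input, qcm)
  if (!length(curves)) stop("no isotherms found in input")
  Ts <- vapply(curves, `[[`, 0, "T")
  curves <- curves[order(Ts)]; Ts <- sort(Ts)
  failures <- character(0)

  selections <- list()
  for (i in seq_along(curves)) {
    s <- try(select_model(curves[[i]], candidates, n_starts = n_starts,
                          seed = seed, fixed = fixed, mode = mode),
             silent = TRUE)
    if (inherits(s, "try-error")) {
      failures <- c(failures, sprintf("selection at T=%g: %s", Ts[i],
                                      conditionMessage(attr(s, "condition"))))
      selections[i] <- list(NULL)
    } else selections[[i]] <- s
  }
  chosen <- vapply(selections, function(s)
    if (is.null(s)) NA_character_ else s$chosen, "")
  if (all(is.na(chosen))) stop("model selection failed at every temperature")
  tab <- table(chosen[!is.na(chosen)])
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {       # tie across temperatures: lowest mean AIC
    mean_aic <- vapply(top, function(m) mean(vapply(
      selections[!vapply(selections, is.null, TRUE)],
      function(s) s$fits[[m]]$aic, 0)), 0)
    top <- top[which.min(mean_aic)]
  }
  adopted <- top[1]

  grid <- NULL
  if (length(curves) >= 2) {
    grid <- try(fit_temperatures(curves, adopted, n_starts = n_starts,
                                 seed = seed, fixed = fixed, mode = mode),
                silent = TRUE)
    if (inherits(grid, "try-error")) {
      failures <- c(failures, paste("temperature grid:",
                                    conditionMessage(attr(grid, "condition"))))
      grid <- NULL
    }
  }

  energies <- NULL
  if (!is.null(S) && !is.null(grid)) {
    enames <- setdiff(param_names(adopted), c("n", "P_M", "a", "b"))
    energies <- do.call(rbind, lapply(seq_along(grid$temperatures), function(i) {
      Tk <- grid$temperatures[i]
      cx <- as.numeric(grid$table[enames, i])
      data.frame(T_K = Tk, parameter = enames, c_x = cx,
                 E_kJ_per_mol = adsorption_energy(cx, S, Tk))
    }))
  }

  thermo <- list()
  if (!is.null(grid) && adopted != "double_real") {
    for (i in seq_along(grid$fits)) {
      f <- grid$fits[[i]]
      if (is.null(f)) next
      tc <- try(thermo_curves(f$params, z_tr = z_tr, T = f$T, mode = mode),
                silent = TRUE)
      if (inherits(tc, "try-error"))
        failures <- c(failures, sprintf("thermo at T=%g", f$T))
      else thermo[[sprintf("T_%g", f$T)]] <- tc
    }
  }

  trend <- NULL
  if (!is.null(grid) && length(grid$temperatures) >= 3) {
    trend <- try(trend_report(grid), silent = TRUE)
    if (inherits(trend, "try-error")) {
      failures <- c(failures, "trend report failed")
      trend <- NULL
    }
  }

  config <- list(candidates = candidates, adopted = adopted, S = S,
                 z_tr = z_tr, n_starts = n_starts, seed = seed,
                 beta_convention = mode$convention,
                 fixed = fixed, temperatures = Ts,
                 version = as.character(utils::packageVersion("isophys")))
  report <- structure(list(selections = selections, adopted = adopted,
                           grid = grid, energies = energies, thermo = thermo,
                           trend = trend, config = config,
                           failures = failures, curves = curves),
                      class = "iso_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

load_pipeline_input <- function(input, qcm) {
  if (is.list(input) && all(vapply(input, inherits, TRUE, what = "isotherm")))
    return(input)
  paths <- if (is.character(input) && length(input) == 1 && dir.exists(input))
    list.files(input, pattern = "\\.(csv|txt)$", full.names = TRUE)
  else if (is.character(input)) input
  else stop("input must be isotherm objects, file paths or a directory")
  lapply(paths, function(p) {
    head <- readLines(p, n = 20)
    if (any(grepl("delta_f_Hz", head))) {
      if (is.null(qcm))
        stop("injection log ", basename(p), " requires a qcm_config")
      Tline <- grep("^#\\s*T_K=", head, value = TRUE)
      T <- if (length(Tline)) as.numeric(sub("^#\\s*T_K=", "", Tline[1])) else 298.15
      reduce_trace(read_injection_log(p), qcm, T = T)
    } else read_isotherm(p)
  })
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sel_rows <- do.call(rbind, lapply(report$selections, function(s) {
    if (is.null(s)) return(NULL)
    cbind(T_K = s$T, s$criteria,
          chosen = s$criteria$model == s$chosen,
          gap_ok = s$gap_ok)
  }))
  if (!is.null(sel_rows))
    write.csv(sel_rows, file.path(out_dir, "selection.csv"),
              row.names = FALSE, quote = FALSE)
  if (!is.null(report$grid)) {
    tab <- cbind(parameter = rownames(report$grid$table), report$grid$table)
    write.csv(tab, file.path(out_dir, "params.csv"),
              row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$energies))
    write.csv(report$energies, file.path(out_dir, "energies.csv"),
              row.names = FALSE, quote = FALSE)
  for (nm in names(report$thermo))
    write_thermo_curve(report$thermo[[nm]],
                       file.path(out_dir, paste0("thermo_", nm, ".csv")))
  lines <- c(
    "isophys analysis report",
    sprintf("version: %s", report$config$version),
    sprintf("beta convention: %s", report$config$beta_convention),
    sprintf("seed: %d | starts: %d", report$config$seed, report$config$n_starts),
    sprintf("candidates: %s", paste(report$config$candidates, collapse = ", ")),
    sprintf("temperatures [K]: %s", paste(report$config$temperatures, collapse = ", ")),
    sprintf("adopted model: %s", report$adopted),
    sprintf("z_tr [mol/L]: %g", report$config$z_tr),
    if (is.null(report$config$S))
      "solubility S: not supplied (no energy table; energies require S)"
    else sprintf("solubility S [mol/L]: %g", report$config$S),
    if (!is.null(report$trend))
      sprintf("thermal character: %s", report$trend$thermal_character),
    if (length(report$failures))
      c("failures:", paste(" -", report$failures)) else "failures: none"
  )
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.iso_report <- function(x, ...) {
  cat(sprintf("<iso_report> %d temperature(s); adopted model: %s\n",
              length(x$curves), x$adopted))
  if (!is.null(x$trend))
    cat("  thermal character:", x$trend$thermal_character, "\n")
  if (!is.null(x$grid)) print(x$grid)
  if (length(x$failures)) cat("  failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}
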