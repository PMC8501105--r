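#' QCM sensor configuration
#'
#' Holds the quartz crystal microbalance constants needed to reduce an
#' injection/frequency log to an isotherm. The frequency budget assumes the
#' temperature (`delta_f_T`), roughness (`delta_f_r`), viscosity/density
#' (`delta_f_eta_rho`) and pressure (`delta_f_p`) contributions are
#' negligible after baseline stabilisation, so the measured shift is the mass
#' term alone; these assumption flags are carried on the object.
#'
#' @param C Sauerbrey sensitivity factor, Hz cm^2/ug, > 0. There is no
#'   default: `C` depends on the crystal and must be calibrated.
#' @param V_s Measuring-cell volume, mL (default 150).
#' @param f0 Fundamental resonance frequency, Hz (default 5 MHz).
#' @param area_upper,area_lower Electrode areas, cm^2.
#' @return An object of class `qcm_config`.
#' @examples
#' qcm_config(C = 56.6)
#' @export
qcm_config <- function(C, V_s = 150, f0 = 5e6,
                       area_upper = 1.37, area_lower = 0.4) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("sensitivity factor C must be a positive scalar [Hz cm^2/ug]")
  if (!is.numeric(V_s) || V_s <= 0) stop("cell volume V_s must be > 0 [mL]")
  structure(list(C = C, V_s = V_s, f0 = f0,
                 area_upper = area_upper, area_lower = area_lower,
                 neglected = c("delta_f_T", "delta_f_r",
                               "delta_f_eta_rho", "delta_f_p")),
            class = "qcm_config")
}

#' @export
print.qcm_config <- function(x, ...) {
  cat(sprintf("<qcm_config> C = %g Hz cm^2/ug, V_s = %g mL, f0 = %g Hz\n",
              x$C, x$V_s, x$f0))
  cat("  neglected frequency terms:", paste(x$neglected, collapse = ", "), "\n")
  invisible(x)
}

#' Sauerbrey frequency-to-mass conversion
#'
#' Inverts the Sauerbrey relation `delta_f_m = -C * delta_m`: a negative
#' frequency shift corresponds to a positive areal mass uptake.
#'
#' @param delta_f Frequency shift(s) from the stabilised baseline, Hz.
#' @param C Sensitivity factor, Hz cm^2/ug, > 0.
#' @return Areal mass change(s), ug/cm^2.
#' @examples
#' sauerbrey_mass(-113.2, C = 56.6)   # 2 ug/cm^2
#' @export
sauerbrey_mass <- function(delta_f, C) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("sensitivity factor C must be a positive scalar")
  -delta_f / C
}

#' Injection volume from matter conservation
#'
#' Volume of stock solution (concentration `c0`) to inject into a cell of
#' volume `V_s` to reach the target concentration `c_f`, neglecting the added
#' volume itself: `V_ad = c_f * V_s / c0`.
#'
#' @param c_f Target concentration after equilibration, mol/L, >= 0.
#' @param V_s Cell volume, mL.
#' @param c0 Stock concentration, mol/L, > 0; must be >= `c_f`.
#' @return Injection volume(s), mL.
#' @examples
#' injection_volume(1e-3, V_s = 150, c0 = 0.1)   # 1.5 mL
#' @export
injection_volume <- function(c_f, V_s, c0) {
  if (any(!is.finite(c0)) || any(c0 <= 0)) stop("stock concentration c0 must be > 0")
  if (any(!is.finite(c_f)) || any(c_f < 0)) stop("c_f must be >= 0")
  if (any(c_f > c0)) stop("target concentration exceeds the stock concentration")
  c_f * V_s / c0
}

#' Injection records
#'
#' One QCM titration step: stock concentration `c0`, either the injected
#' volume `v_injected` (mL) or the post-equilibration target concentration
#' `c_target` (mol/L, exactly one of the two), and the cumulative frequency
#' shift `delta_f` (Hz) from the stabilised baseline.
#'
#' @param c0 Stock concentration(s), mol/L, > 0.
#' @param delta_f Cumulative frequency shift(s), Hz.
#' @param v_injected Injected volume(s), mL, or `NA`.
#' @param c_target Target concentration(s), mol/L, or `NA`.
#' @return A data frame of class `injection_log` with columns `step`,
#'   `c0_mol_per_L`, `v_injected_mL`, `c_target_mol_per_L`, `delta_f_Hz`.
#' @export
injection_records <- function(c0, delta_f, v_injected = NA_real_,
                              c_target = NA_real_) {
  k <- max(length(c0), length(delta_f), length(v_injected), length(c_target))
  rec <- data.frame(step = seq_len(k),
                    c0_mol_per_L = rep_len(as.numeric(c0), k),
                    v_injected_mL = rep_len(as.numeric(v_injected), k),
                    c_target_mol_per_L = rep_len(as.numeric(c_target), k),
                    delta_f_Hz = rep_len(as.numeric(delta_f), k))
  validate_injection_log(rec)
}

validate_injection_log <- function(rec) {
  if (any(!is.finite(rec$c0_mol_per_L)) || any(rec$c0_mol_per_L <= 0))
    stop("every record needs a positive stock concentration c0")
  has_v <- !is.na(rec$v_injected_mL)
  has_c <- !is.na(rec$c_target_mol_per_L)
  if (any(has_v & has_c))
    stop("records must carry either v_injected or c_target, not both")
  if (any(!has_v & !has_c))
    stop("records must carry one of v_injected or c_target")
  if (any(!is.finite(rec$delta_f_Hz)))
    stop("delta_f must be finite")
  class(rec) <- c("injection_log", "data.frame")
  rec
}

#' Reduce a QCM injection trace to an isotherm
#'
#' Converts an ordered injection/frequency log into an [isotherm]:
#' concentrations accumulate by matter conservation
#' (`c_i = c_{i-1} + c0_i * v_i / V_s`, or `c_target` where given) and
#' adsorbed quantities follow the Sauerbrey relation `q_i = -delta_f_i / C`.
#' `delta_f` is the cumulative shift from the stabilised baseline, so `q` is
#' the total adsorbed quantity at each step, not an increment.
#'
#' By default the injected volumes are not subtracted from the cell volume
#' (they are small against `V_s`); set `account_added_volume = TRUE` to track
#' the exact dilution for sensitivity analysis.
#'
#' @param records An `injection_log` (see [injection_records()]) or a data
#'   frame with the same columns.
#' @param cfg A [qcm_config()].
#' @param T Temperature, K.
#' @param account_added_volume If `TRUE`, dilute by the running cell volume
#'   `V_s + sum(v)` instead of the constant-volume approximation.
#' @return An [isotherm].
#' @export
reduce_trace <- function(records, cfg, T, account_added_volume = FALSE) {
  stopifnot(inherits(cfg, "qcm_config"))
  rec <- validate_injection_log(as.data.frame(records))
  k <- nrow(rec)
  conc <- numeric(k)
  moles <- 0            # mmol when V_s in mL and c in mol/L
  vol <- cfg$V_s
  c_prev <- 0
  for (i in seq_len(k)) {
    if (!is.na(rec$c_target_mol_per_L[i])) {
      ci <- rec$c_target_mol_per_L[i]
      v <- (ci - c_prev) * vol / rec$c0_mol_per_L[i]
      if (v < 0) stop("non-monotone concentrations in trace at step ", i)
    } else {
      v <- rec$v_injected_mL[i]
      if (v < 0) stop("negative injected volume at step ", i)
    }
    moles <- moles + rec$c0_mol_per_L[i] * v
    if (account_added_volume) vol <- vol + v
    ci <- moles / vol
    conc[i] <- ci
    c_prev <- ci
  }
  if (any(diff(conc) <= 0)) stop("non-monotone concentrations in trace")
  q <- sauerbrey_mass(rec$delta_f_Hz, cfg$C)
  isotherm(conc, q, T = T, provenance = "reduced QCM trace")
}

#' Read and write injection logs
#'
#' CSV dialect with header
#' `step,c0_mol_per_L,v_injected_mL,c_target_mol_per_L,delta_f_Hz`;
#' an empty field marks an absent optional value.
#'
#' @param records An `injection_log`.
#' @param path File path.
#' @export
write_injection_log <- function(records, path) {
  rec <- validate_injection_log(as.data.frame(records))
  write.csv(rec, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_injection_log
#' @export
read_injection_log <- function(path) {
  rec <- read.csv(path, na.strings = c("", "NA"), comment.char = "#")
  need <- c("step", "c0_mol_per_L", "v_injected_mL",
            "c_target_mol_per_L", "delta_f_Hz")
  if (!all(need %in% names(rec)))
    stop("injection log must have columns ", paste(need, collapse = ", "))
  validate_injection_log(rec[need])
}

#' Read a key:value configuration file
#'
#' Parses a plain-text `key: value` file mirroring the [qcm_config()] fields
#' (`C`, `V_s`, `f0`, `area_upper`, `area_lower`); unknown keys are ignored
#' with a warning.
#'
#' @param path File path.
#' @return A [qcm_config()].
#' @export
read_qcm_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, function(x)
    paste(x[-1], collapse = ":"), ""))))
  known <- c("C", "V_s", "f0", "area_upper", "area_lower")
  if (any(!keys %in% known))
    warning("ignoring unknown config keys: ",
            paste(setdiff(keys, known), collapse = ", "))
  args <- as.list(vals[keys %in% known])
  names(args) <- keys[keys %in% known]
  do.call(qcm_config, args)
}
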