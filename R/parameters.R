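# Population-invariant physiological constants and closure defaults.
# These complete the subject/population fields (normal flow, pressures,
# haemoglobin, CCO pool) to a full model parameterisation.
.nh_shared_defaults <- list(
  SaO2_n  = 0.96,  # normal arterial O2 saturation (fraction)
  PaCO2_n = 40,    # normal arterial CO2 partial pressure (mmHg)
  f_art   = 0.25,  # arterial fraction of cerebral blood volume
  r_n     = 1,     # normal arterial radius (arbitrary units; not rescaled
                   # for the neonate: baseline vessel geometry kept adult)
  tau_mu  = 5,     # vascular tone time constant (s)
  R_P     = 3,     # autoregulatory pressure gain (adult; preterm preset: 10)
  R_C     = 1,     # CO2 reactivity gain
  R_O     = 1,     # tissue-O2 reactivity gain
  R_u     = 1.5,   # demand -> vascular tone gain (functional hyperemia)
  k_r     = 0.12,  # maximal fractional radius excursion from tone
  k_m     = 0.15,  # demand -> CMRO2 coupling gain (soft metabolic coupling)
  K_mO2   = 0.005, # Michaelis constant for O2 limitation of CMRO2 (mM)
  O2t_n   = 0.024, # normal tissue O2 concentration (mM)
  k_CuA   = 0.5,   # CuA redox relaxation rate (1/s)
  tau_O2  = 2      # tissue O2 pool time constant (s), sets kappa at calibration
)

# Table-anchored population values used to validate the shipped presets.
.nh_table_values <- list(
  adult   = list(CBF_n = 49,   CCO_tis = 5.5, CuA_frac_n = 0.8,
                 CMRO2_n = 155, P_a_n = 100, Hbtot = 9.1,
                 V_blood_n = 0.04,   P_ic_n = 9.5),
  preterm = list(CBF_n = 19.8, CCO_tis = 2.2, CuA_frac_n = 0.67,
                 CMRO2_n = 40.865, P_a_n = 30, Hbtot = 9.75,
                 V_blood_n = 0.0233, P_ic_n = 5.1)
)

.nh_subject_fields <- c("CBF_n", "CCO_tis", "CuA_frac_n", "CMRO2_n",
                        "P_a_n", "Hbtot", "V_blood_n", "P_ic_n")

#' Construct a physiological parameter set
#'
#' Bundles the subject/population constants of the cerebral haemodynamics
#' model (normal flow, metabolic rate, pressures, haemoglobin and
#' cytochrome-c-oxidase pools) with the shared closure constants (vascular
#' gains, time constants, oxygen-transport constants). The result is
#' uncalibrated: pass it through [calibrate()] before simulating.
#'
#' @param CBF_n normal cerebral blood flow, ml 100g^-1 min^-1.
#' @param CCO_tis total tissue cytochrome-c-oxidase concentration, uM.
#' @param CuA_frac_n normal oxidised CuA fraction, in (0, 1).
#' @param CMRO2_n normal cerebral metabolic rate of O2, umol 100g^-1 min^-1.
#' @param P_a_n normal mean arterial pressure, mmHg.
#' @param Hbtot total haemoglobin in blood, mM in haem units (1 O2 binding
#'   site per haem; see the methods vignette for why haem units are used).
#' @param V_blood_n normal brain blood volume fraction.
#' @param P_ic_n intracranial pressure, mmHg; the effective downstream
#'   pressure of the vascular bed.
#' @param ... overrides for any shared constant (`SaO2_n`, `PaCO2_n`,
#'   `f_art`, `r_n`, `tau_mu`, `R_P`, `R_C`, `R_O`, `R_u`, `k_r`, `k_m`,
#'   `K_mO2`, `O2t_n`, `k_CuA`, `tau_O2`).
#' @return An object of class `nh_params` (uncalibrated).
#' @seealso [calibrate()], [load_preset()], [subject_overrides()]
#' @export
parameter_set <- function(CBF_n, CCO_tis, CuA_frac_n, CMRO2_n,
                          P_a_n, Hbtot, V_blood_n, P_ic_n, ...) {
  p <- .nh_shared_defaults
  extra <- list(...)
  unknown <- setdiff(names(extra), names(.nh_shared_defaults))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  p[names(extra)] <- extra
  p <- c(list(CBF_n = CBF_n, CCO_tis = CCO_tis, CuA_frac_n = CuA_frac_n,
              CMRO2_n = CMRO2_n, P_a_n = P_a_n, Hbtot = Hbtot,
              V_blood_n = V_blood_n, P_ic_n = P_ic_n), p)
  obj <- structure(p, class = "nh_params", calibrated = FALSE)
  validate_params(obj)
  obj
}

validate_params <- function(p) {
  num <- p[vapply(p, is.numeric, logical(1))]
  bad <- names(num)[!vapply(num, function(x) is.finite(x) && length(x) == 1,
                            logical(1))]
  if (length(bad)) stop("non-finite or non-scalar parameter(s): ",
                        paste(bad, collapse = ", "))
  pos <- c("CBF_n", "CCO_tis", "CuA_frac_n", "CMRO2_n", "P_a_n", "Hbtot",
           "V_blood_n", "P_ic_n", "SaO2_n", "PaCO2_n", "f_art", "r_n",
           "tau_mu", "k_r", "k_m", "K_mO2", "O2t_n", "k_CuA", "tau_O2")
  neg <- pos[vapply(pos, function(f) p[[f]] <= 0, logical(1))]
  if (length(neg)) stop("parameter(s) must be strictly positive: ",
                        paste(neg, collapse = ", "))
  fr <- c("CuA_frac_n", "V_blood_n", "SaO2_n", "f_art")
  over <- fr[vapply(fr, function(f) p[[f]] > 1, logical(1))]
  if (length(over)) stop("fraction(s) exceed 1: ", paste(over, collapse = ", "))
  if (p$CuA_frac_n >= 1) stop("CuA_frac_n must lie in (0, 1)")
  if (p$k_r >= 1) stop("k_r must lie in (0, 1)")
  if (p$P_a_n <= p$P_ic_n) {
    stop("P_a_n must exceed P_ic_n (no perfusion pressure otherwise)")
  }
  oef <- p$CMRO2_n / (p$CBF_n * p$Hbtot * p$SaO2_n)
  if (oef <= 0 || oef >= 1) {
    stop(sprintf(
      "baseline oxygen extraction fraction %.3f outside (0, 1); CMRO2_n, CBF_n and Hbtot are inconsistent",
      oef))
  }
  invisible(p)
}

#' @export
print.nh_params <- function(x, ...) {
  cat(sprintf("<nh_params>%s\n",
              if (isTRUE(attr(x, "calibrated"))) " (calibrated)" else ""))
  cat(sprintf("  CBF_n = %g ml/100g/min, CMRO2_n = %g umol/100g/min\n",
              x$CBF_n, x$CMRO2_n))
  cat(sprintf("  P_a_n = %g mmHg, P_ic_n = %g mmHg, Hbtot = %g mM (haem)\n",
              x$P_a_n, x$P_ic_n, x$Hbtot))
  cat(sprintf("  V_blood_n = %g, CCO_tis = %g uM, CuA_frac_n = %g\n",
              x$V_blood_n, x$CCO_tis, x$CuA_frac_n))
  if (isTRUE(attr(x, "calibrated"))) {
    cat(sprintf("  closure: K_flow = %.6g, D_O2 = %.6g, k_red_ratio = %.6g\n",
                x$K_flow, x$D_O2, x$k_red_ratio))
  }
  invisible(x)
}

is_calibrated <- function(p) isTRUE(attr(p, "calibrated"))

#' Solve the closure constants so the normal state is an exact fixed point
#'
#' Computes `K_flow` (vascular conductance), the oxygen-transport constants
#' `D_O2`, `sigma_O2` and `kappa_O2`, and the CuA reduction ratio
#' `k_red_ratio` such that the baseline state (zero tone, normal tissue O2,
#' normal oxidised CuA fraction) under baseline inputs is an exact
#' equilibrium with `CBF = CBF_n` and `CMRO2 = CMRO2_n`.
#'
#' @param params an `nh_params` object.
#' @return The same object with closure constants filled in and the
#'   `calibrated` attribute set.
#' @export
calibrate <- function(params) {
  if (!inherits(params, "nh_params")) stop("params must be an nh_params object")
  validate_params(params)
  p <- params
  p$K_flow <- p$CBF_n / (p$r_n^4 * (p$P_a_n - p$P_ic_n))
  SvO2_n <- p$SaO2_n - p$CMRO2_n / (p$CBF_n * p$Hbtot)
  if (SvO2_n <= 0) {
    stop(sprintf(
      "calibration infeasible: baseline venous saturation %.3f <= 0 (extraction exceeds delivery)",
      SvO2_n))
  }
  Sc_n <- (p$SaO2_n + SvO2_n) / 2
  # Tissue-side back-pressure set to half the capillary drive at baseline;
  # the remaining half is the diffusion gradient that sustains CMRO2_n.
  p$sigma_O2 <- Sc_n * p$Hbtot / (2 * p$O2t_n)
  p$D_O2 <- p$CMRO2_n / (Sc_n * p$Hbtot - p$sigma_O2 * p$O2t_n)
  # kappa converts the (per-minute, per-100g) O2 balance into mM/s and sets
  # the linearised tissue O2 pool time constant to tau_O2 seconds.
  p$kappa_O2 <- 1 / (p$tau_O2 * p$D_O2 * p$sigma_O2)
  p$k_red_ratio <- (1 - p$CuA_frac_n) / p$CuA_frac_n
  p$g_n <- p$O2t_n / (p$O2t_n + p$K_mO2)
  p$SvO2_n <- SvO2_n
  attr(p, "calibrated") <- TRUE
  p
}

#' Baseline model state for a parameter set
#'
#' @param params calibrated or uncalibrated `nh_params`.
#' @return Named numeric vector `c(mu, O2t, a)`: zero vascular tone, normal
#'   tissue O2, normal oxidised CuA fraction.
#' @export
baseline_state <- function(params) {
  c(mu = 0, O2t = params$O2t_n, a = params$CuA_frac_n)
}

#' Baseline instantaneous inputs for a parameter set
#'
#' @param params `nh_params`.
#' @param cbf_clamped logical; clamp cerebral blood flow at its normal value.
#' @return Named list with `P_a`, `SaO2`, `PaCO2`, `u`, `m`, `cbf_clamped`.
#' @export
baseline_inputs <- function(params, cbf_clamped = FALSE) {
  list(P_a = params$P_a_n, SaO2 = params$SaO2_n, PaCO2 = params$PaCO2_n,
       u = 1, m = 1, cbf_clamped = isTRUE(cbf_clamped))
}

#' Load a shipped parameter preset
#'
#' Presets live as JSON under `inst/extdata/presets/`: `adult` and `preterm`
#' are the two population parameterisations (the loader checks their
#' anchor values against the built-in table and refuses a tampered file);
#' `neonate1` and `neonate2` are the preterm preset with subject-specific
#' haemoglobin and baseline SpO2.
#'
#' @param name one of `"adult"`, `"preterm"`, `"neonate1"`, `"neonate2"`,
#'   or a path to a JSON file with the same fields.
#' @param calibrated solve the closure constants before returning
#'   (default `TRUE`).
#' @return An `nh_params` object.
#' @export
load_preset <- function(name, calibrated = TRUE) {
  file <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".json"),
                package = "neohaem")
  if (!nzchar(file) || !file.exists(file)) {
    stop("unknown preset '", name, "'; shipped presets: adult, preterm, ",
         "neonate1, neonate2")
  }
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  subject <- raw[.nh_subject_fields]
  missing <- .nh_subject_fields[vapply(subject, is.null, logical(1))]
  if (length(missing)) {
    stop("preset file lacks field(s): ", paste(missing, collapse = ", "))
  }
  extra <- raw[intersect(names(raw), names(.nh_shared_defaults))]
  p <- do.call(parameter_set, c(subject, extra))
  id <- sub("\\.json$", "", basename(file))
  if (id %in% names(.nh_table_values)) {
    ref <- .nh_table_values[[id]]
    for (f in names(ref)) {
      if (!isTRUE(all.equal(p[[f]], ref[[f]], tolerance = 1e-12))) {
        stop(sprintf("preset '%s' field %s = %g does not match the reference value %g",
                     id, f, p[[f]], ref[[f]]))
      }
    }
  }
  if (calibrated) p <- calibrate(p)
  p
}

#' Apply subject-specific overrides to a parameter set
#'
#' Replaces total haemoglobin (given clinically in g/dL, converted to mM in
#' haem units: `g/dL * 10 / 64500 * 4 * 1000`) and baseline arterial
#' saturation, then recalibrates.
#'
#' @param base `nh_params` to start from (typically the preterm preset).
#' @param haemoglobin_g_dL blood haemoglobin, g/dL; `NULL` keeps the base value.
#' @param baseline_SpO2 baseline pulse-oximetry saturation, fraction in
#'   (0, 1]; `NULL` keeps the base value.
#' @return A recalibrated `nh_params`.
#' @export
subject_overrides <- function(base, haemoglobin_g_dL = NULL,
                              baseline_SpO2 = NULL) {
  if (!inherits(base, "nh_params")) stop("base must be an nh_params object")
  p <- base
  if (!is.null(haemoglobin_g_dL)) {
    if (!is.finite(haemoglobin_g_dL) || haemoglobin_g_dL <= 0) {
      stop("haemoglobin_g_dL must be a positive number")
    }
    p$Hbtot <- haemoglobin_g_dL * 10 / 64500 * 4 * 1000
  }
  if (!is.null(baseline_SpO2)) {
    if (!is.finite(baseline_SpO2) || baseline_SpO2 <= 0 || baseline_SpO2 > 1) {
      stop("baseline_SpO2 must lie in (0, 1]")
    }
    p$SaO2_n <- baseline_SpO2
  }
  if (is.null(haemoglobin_g_dL) && is.null(baseline_SpO2)) return(base)
  attr(p, "calibrated") <- FALSE
  calibrate(p)
}
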