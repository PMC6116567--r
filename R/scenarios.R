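# Registry of the stimulus-evoked simulation scenarios and the
# steady-state autoregulation experiment.

#' Define a simulation scenario
#'
#' @param name scenario identifier.
#' @param preset parameter preset id (see [load_preset()]).
#' @param amps [stimulus_amplitudes()].
#' @param hrf [hrf_spec()].
#' @param clamp_cbf clamp cerebral blood flow at its normal value.
#' @param duration total simulated time, s.
#' @param dt output grid spacing, s.
#' @return Object of class `nh_scenario`.
#' @export
scenario <- function(name, preset, amps, hrf = hrf_spec(),
                     clamp_cbf = FALSE, duration = 60, dt = 0.1) {
  stopifnot(is.character(name), length(name) == 1,
            inherits(amps, "nh_amplitudes"), inherits(hrf, "nh_hrf_spec"),
            duration > 0, dt > 0)
  structure(list(name = name, preset = preset, amps = amps, hrf = hrf,
                 clamp_cbf = isTRUE(clamp_cbf), duration = duration,
                 dt = dt),
            class = "nh_scenario")
}

#' The built-in scenario registry
#'
#' Six stimulus-evoked simulations with their published peak amplitudes:
#'
#' * `kozberg_bp_rise` - somatosensory activation in newborn-equivalent
#'   rats with a blood-pressure rise: `alpha = 2` demand, 1.5 mmHg pressure
#'   rise (encoded `beta = -1.5`; the pressure-amplitude sign convention is
#'   a dip for positive `beta`, and this group's pressure rose).
#' * `kozberg_no_hyperemia` - the group without hyperemia: no demand
#'   increase, 1 % radius constriction (`gamma = 0.01`) and a small
#'   pressure dip (`beta = 0.18`).
#' * `roche_labarbe` - somatosensory activation in preterm neonates:
#'   `alpha = 0.5`.
#' * `usz_neonate1` - visual activation, subject 1 parameters:
#'   `alpha = 0.7`.
#' * `usz_neonate2` - visual activation, subject 2: `alpha = 0.7` with
#'   cerebral blood flow clamped at its normal value.
#' * `usz_neonate2_bp` - as `usz_neonate2` plus a 7 mmHg pressure dip
#'   (`beta = 7`).
#'
#' Rat scenarios run on the generic preterm human preset (the animals are
#' age-equivalent to human newborns and the model is a human-neonate
#' model); the visual-activation scenarios use the subject presets.
#' Stimulus blocks: onset 10 s; duration 10 s (somatosensory) or 20 s
#' (visual); 60 s total.
#'
#' @return Named list of `nh_scenario` objects.
#' @export
scenario_registry <- function() {
  som <- hrf_spec(stimulus_onset = 10, stimulus_duration = 10)
  vis <- hrf_spec(stimulus_onset = 10, stimulus_duration = 20)
  sc <- list(
    scenario("kozberg_bp_rise", "preterm",
             stimulus_amplitudes(alpha = 2, beta = -1.5), som),
    scenario("kozberg_no_hyperemia", "preterm",
             stimulus_amplitudes(alpha = 0, beta = 0.18, gamma = 0.01), som),
    scenario("roche_labarbe", "preterm",
             stimulus_amplitudes(alpha = 0.5), som),
    scenario("usz_neonate1", "neonate1",
             stimulus_amplitudes(alpha = 0.7), vis),
    scenario("usz_neonate2", "neonate2",
             stimulus_amplitudes(alpha = 0.7), vis, clamp_cbf = TRUE),
    scenario("usz_neonate2_bp", "neonate2",
             stimulus_amplitudes(alpha = 0.7, beta = 7), vis,
             clamp_cbf = TRUE))
  stats::setNames(sc, vapply(sc, `[[`, character(1), "name"))
}

#' Look up a scenario by name
#'
#' @param name registry name.
#' @return The `nh_scenario`; unknown names raise an error listing the
#'   valid ones.
#' @export
get_scenario <- function(name) {
  reg <- scenario_registry()
  if (inherits(name, "nh_scenario")) return(name)
  if (!name %in% names(reg)) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Run a registry scenario
#'
#' Loads and calibrates the scenario's parameter preset, builds its input
#' timeline and integrates the model.
#'
#' @param name scenario name or `nh_scenario` object.
#' @param params optional calibrated `nh_params` overriding the scenario's
#'   preset.
#' @param ... passed to [run_simulation()].
#' @return An `nh_trajectory` with a `scenario` attribute.
#' @export
run_scenario <- function(name, params = NULL, ...) {
  sc <- get_scenario(name)
  p <- if (is.null(params)) load_preset(sc$preset) else
    .nh_require_calibrated(params)
  grid <- seq(0, sc$duration, by = sc$dt)
  tl <- build_timeline(sc$amps, sc$hrf, p, clamp_cbf = sc$clamp_cbf,
                       time_grid = grid)
  traj <- run_simulation(p, tl, ...)
  attr(traj, "scenario") <- sc$name
  traj
}

#' Steady-state autoregulation curve
#'
#' Cerebral blood flow at equilibrium as a function of arterial pressure,
#' with all other inputs at their normal values.
#'
#' @param params calibrated `nh_params`.
#' @param P_range strictly increasing pressure grid, mmHg; must stay above
#'   the intracranial pressure and at or below 200 mmHg. The default spans
#'   0.4 to 2 times the normal pressure. Very low pressures where even the
#'   fully dilated bed cannot supply the oxygen demand raise the
#'   oxygen-supply-exhausted error (the model has no equilibrium there).
#' @return Data frame of class `nh_autoreg` with `P_a` and `CBF`.
#' @export
autoregulation_curve <- function(params, P_range = NULL) {
  p <- .nh_require_calibrated(params)
  if (is.null(P_range)) {
    P_range <- seq(0.4 * p$P_a_n, min(200, 2 * p$P_a_n), by = 0.5)
  }
  if (any(diff(P_range) <= 0)) stop("P_range must be strictly increasing")
  if (min(P_range) <= p$P_ic_n || max(P_range) > 200) {
    stop(sprintf("P_range must lie within (%g, 200] mmHg", p$P_ic_n))
  }
  cbf <- vapply(P_range, function(P) {
    inp <- baseline_inputs(p)
    inp$P_a <- P
    st <- tryCatch(steady_state(p, inp), error = function(e) {
      stop(sprintf("autoregulation curve failed at P_a = %g mmHg: %s",
                   P, conditionMessage(e)), call. = FALSE)
    })
    derived_quantities(st, inp, p)$CBF
  }, numeric(1))
  structure(data.frame(P_a = P_range, CBF = cbf),
            class = c("nh_autoreg", "data.frame"))
}

#' Autoregulation plateau width
#'
#' Width of the contiguous pressure interval around the normal pressure on
#' which the normalised curve slope `d(CBF/CBF_n)/dP_a` stays below a
#' threshold in magnitude. Zero when the slope already exceeds the
#' threshold at the normal pressure itself.
#'
#' @param curve an `nh_autoreg` data frame.
#' @param params the `nh_params` the curve was computed from (provides
#'   `P_a_n` and `CBF_n`).
#' @param threshold slope threshold, per mmHg (default 0.01).
#' @return Plateau width in mmHg.
#' @export
plateau_width <- function(curve, params, threshold = 0.01) {
  stopifnot(inherits(curve, "nh_autoreg"))
  P <- curve$P_a
  rel <- curve$CBF / params$CBF_n
  n <- length(P)
  slope <- numeric(n)
  slope[2:(n - 1)] <- (rel[3:n] - rel[1:(n - 2)]) / (P[3:n] - P[1:(n - 2)])
  slope[1] <- (rel[2] - rel[1]) / (P[2] - P[1])
  slope[n] <- (rel[n] - rel[n - 1]) / (P[n] - P[n - 1])
  flat <- abs(slope) < threshold
  i0 <- which.min(abs(P - params$P_a_n))
  if (!flat[i0]) return(0)
  lo <- i0
  while (lo > 1 && flat[lo - 1]) lo <- lo - 1
  hi <- i0
  while (hi < n && flat[hi + 1]) hi <- hi + 1
  P[hi] - P[lo]
}
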