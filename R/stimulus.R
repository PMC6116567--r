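# Stimulus design: canonical double-gamma haemodynamic response function
# (HRF) convolved with the stimulus block, and the input timelines that
# drive the model (demand, arterial pressure, radius modulation).

#' Specify a haemodynamic response function
#'
#' The kernel is the classical difference of two gamma densities (unit
#' rate): a positive lobe whose mode sits at `peak_time` and a negative
#' lobe (weight `undershoot_ratio`) with mode at `undershoot_time`. The
#' kernel is convolved with a boxcar covering the stimulus block and the
#' result is renormalised to unit peak, so stimulus amplitudes always
#' denote peak excursions.
#'
#' @param peak_time time-to-peak of the positive lobe, s.
#' @param undershoot_time mode of the undershoot lobe, s.
#' @param undershoot_ratio weight of the undershoot lobe (>= 0).
#' @param stimulus_onset stimulus start, s.
#' @param stimulus_duration stimulus block length, s.
#' @return Object of class `nh_hrf_spec`.
#' @export
hrf_spec <- function(peak_time = 5, undershoot_time = 15,
                     undershoot_ratio = 0.35, stimulus_onset = 10,
                     stimulus_duration = 10) {
  if (!(peak_time > 0) || !(stimulus_duration > 0) || !(stimulus_onset >= 0)) {
    stop("peak_time and stimulus_duration must be positive, stimulus_onset >= 0")
  }
  if (!(peak_time < undershoot_time)) {
    stop("peak_time must be smaller than undershoot_time")
  }
  if (undershoot_ratio < 0 || undershoot_ratio >= 1) {
    stop("undershoot_ratio must lie in [0, 1)")
  }
  structure(list(peak_time = peak_time, undershoot_time = undershoot_time,
                 undershoot_ratio = undershoot_ratio,
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration),
            class = "nh_hrf_spec")
}

# Double-gamma kernel (unit rate; mode of gamma(shape, 1) is shape - 1).
.nh_hrf_kernel <- function(x, spec) {
  stats::dgamma(x, shape = spec$peak_time + 1, rate = 1) -
    spec$undershoot_ratio *
      stats::dgamma(x, shape = spec$undershoot_time + 1, rate = 1)
}

# Running integral of the kernel; the boxcar convolution is a difference of
# two evaluations, so no numerical quadrature is needed.
.nh_hrf_kernel_integral <- function(x, spec) {
  stats::pgamma(x, shape = spec$peak_time + 1, rate = 1) -
    spec$undershoot_ratio *
      stats::pgamma(x, shape = spec$undershoot_time + 1, rate = 1)
}

#' Evaluate the peak-normalised HRF on a time grid
#'
#' @param spec an [hrf_spec()].
#' @param time_grid strictly increasing times, s. Spacing must resolve the
#'   peak (at most `peak_time / 4`).
#' @return Numeric vector of HRF values; zero before stimulus onset, unit
#'   maximum over the grid.
#' @export
make_hrf <- function(spec, time_grid) {
  stopifnot(inherits(spec, "nh_hrf_spec"))
  if (length(time_grid) < 2 || any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing with at least 2 points")
  }
  if (max(diff(time_grid)) > spec$peak_time / 4) {
    stop(sprintf(
      "time grid too coarse to resolve the HRF peak: spacing %.3g s exceeds peak_time/4 = %.3g s",
      max(diff(time_grid)), spec$peak_time / 4))
  }
  raw <- .nh_hrf_kernel_integral(time_grid - spec$stimulus_onset, spec) -
    .nh_hrf_kernel_integral(time_grid - spec$stimulus_onset -
                              spec$stimulus_duration, spec)
  peak <- max(raw)
  if (!(peak > 0)) stop("degenerate HRF: non-positive peak on this grid")
  raw / peak
}

#' Stimulus amplitudes
#'
#' `alpha` scales demand (`u = 1 + alpha * HRF`), `beta` scales arterial
#' pressure with the printed sign convention (`P_a = P_a_n - beta * HRF`;
#' positive `beta` is a pressure dip, a pressure rise takes negative
#' `beta`), and `gamma` imposes direct radius modulation
#' (`m = 1 - gamma * HRF`, e.g. `gamma = 0.01` is a 1 % constriction).
#'
#' @param alpha demand amplitude, dimensionless.
#' @param beta pressure amplitude, mmHg (peak excursion).
#' @param gamma radius-modulation amplitude, dimensionless.
#' @return Object of class `nh_amplitudes`.
#' @export
stimulus_amplitudes <- function(alpha = 0, beta = 0, gamma = 0) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma))
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "nh_amplitudes")
}

#' Build the model input timeline for a stimulus
#'
#' Demand, arterial pressure and radius modulation follow the HRF with
#' their respective amplitudes; arterial saturation and CO2 tension are
#' held at their normal values throughout.
#'
#' @param amps [stimulus_amplitudes()].
#' @param spec [hrf_spec()].
#' @param params `nh_params` providing the baseline values.
#' @param clamp_cbf clamp cerebral blood flow at `CBF_n` in the oxygen
#'   transport (vascular tone and volume still evolve).
#' @param time_grid strictly increasing times, s.
#' @return Data frame of class `nh_timeline` with columns `time`, `P_a`,
#'   `SaO2`, `PaCO2`, `u`, `m`, `cbf_clamped`; the HRF is kept as an
#'   attribute.
#' @export
build_timeline <- function(amps, spec, params, clamp_cbf = FALSE,
                           time_grid = seq(0, 60, by = 0.1)) {
  stopifnot(inherits(amps, "nh_amplitudes"), inherits(spec, "nh_hrf_spec"),
            inherits(params, "nh_params"))
  hrf <- make_hrf(spec, time_grid)
  u <- 1 + amps$alpha * hrf
  m <- 1 - amps$gamma * hrf
  if (any(u <= 0)) {
    stop(sprintf("amplitude error: alpha = %g drives demand u <= 0", amps$alpha))
  }
  if (any(m <= 0)) {
    stop(sprintf("amplitude error: gamma = %g drives radius modulation m <= 0",
                 amps$gamma))
  }
  tl <- data.frame(time = time_grid,
                   P_a = params$P_a_n - amps$beta * hrf,
                   SaO2 = params$SaO2_n,
                   PaCO2 = params$PaCO2_n,
                   u = u, m = m,
                   cbf_clamped = isTRUE(clamp_cbf))
  attr(tl, "hrf") <- hrf
  attr(tl, "amplitudes") <- amps
  attr(tl, "hrf_spec") <- spec
  class(tl) <- c("nh_timeline", "data.frame")
  tl
}
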