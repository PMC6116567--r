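# Forward simulation: integrate the closure over an input timeline and
# post-process the state trajectory into fNIRS-style observables.

#' Run a forward simulation
#'
#' Integrates the model with an adaptive Dormand-Prince 5(4) scheme
#' (compiled) from the steady state of the timeline's first sample, then
#' derives the observables at every grid time. Change signals (`dHbO2`,
#' `dHHb`, `dHbT`, `dOxCCO`, in uM) are referenced to the mean over the
#' pre-stimulus baseline window; `rCBF`, `rCMRO2`, `rCBV` are ratios to
#' that baseline.
#'
#' @param params calibrated `nh_params`.
#' @param timeline an `nh_timeline` from [build_timeline()]; must start
#'   with at least 10 s of baseline inputs.
#' @param rtol,atol integrator tolerances (defaults 1e-8 / 1e-10).
#' @param baseline_window length of the initial window used to zero the
#'   change signals, s.
#' @return Data frame of class `nh_trajectory`: `time`, the state columns
#'   (`mu`, `O2t`, `a`), the derived columns (`r`, `CBF`, `CMRO2`, `SvO2`,
#'   `V_blood`, `HbO2_tis`, `HHb_tis`, `HbT_tis`, `oxCCO_tis`), the change
#'   signals and ratios, and the driving `Pa` and `u`.
#' @export
run_simulation <- function(params, timeline, rtol = 1e-8, atol = 1e-10,
                           baseline_window = 10) {
  p <- .nh_require_calibrated(params)
  if (!inherits(timeline, "nh_timeline")) {
    stop("timeline must be built with build_timeline()")
  }
  tt <- timeline$time
  if (tt[1] != 0) stop("timeline must start at t = 0")
  pre <- tt < baseline_window
  if (sum(pre) < 2 || max(tt) <= baseline_window) {
    stop("timeline must start with at least ", baseline_window,
         " s of baseline inputs")
  }
  base_ok <- all(abs(timeline$u[pre] - 1) < 1e-9) &&
    all(abs(timeline$m[pre] - 1) < 1e-9) &&
    all(abs(timeline$P_a[pre] - p$P_a_n) < 1e-6) &&
    all(abs(timeline$SaO2[pre] - p$SaO2_n) < 1e-9) &&
    all(abs(timeline$PaCO2[pre] - p$PaCO2_n) < 1e-9)
  if (!base_ok) {
    stop("timeline does not hold baseline inputs over the first ",
         baseline_window, " s")
  }
  clamp <- unique(timeline$cbf_clamped)
  if (length(clamp) != 1) {
    stop("cbf_clamped must be constant over the timeline")
  }
  inp0 <- list(P_a = timeline$P_a[1], SaO2 = timeline$SaO2[1],
               PaCO2 = timeline$PaCO2[1], u = timeline$u[1],
               m = timeline$m[1], cbf_clamped = clamp)
  y0 <- steady_state(p, inp0)
  res <- .nh_integrate_cpp(tt, timeline$P_a, timeline$SaO2, timeline$PaCO2,
                           timeline$u, timeline$m, clamp, unclass(p),
                           unname(y0), rtol, atol)
  if (!isTRUE(res$success)) {
    stop(sprintf("simulation failed at t = %.4g s: %s", res$t_fail,
                 res$message))
  }
  st <- res$states
  d <- .nh_derived_core(st[, 1], st[, 2], st[, 3], timeline$P_a,
                        timeline$SaO2, timeline$u, timeline$m, clamp, p,
                        time = tt)
  traj <- data.frame(time = tt, mu = st[, 1], O2t = st[, 2], a = st[, 3],
                     r = d$r, CBF = d$CBF, CMRO2 = d$CMRO2, SvO2 = d$SvO2,
                     V_blood = d$V_blood, HbO2_tis = d$HbO2_tis,
                     HHb_tis = d$HHb_tis, HbT_tis = d$HbT_tis,
                     oxCCO_tis = d$oxCCO_tis)
  base <- function(x) mean(x[pre])
  traj$dHbO2 <- traj$HbO2_tis - base(traj$HbO2_tis)
  traj$dHHb <- traj$HHb_tis - base(traj$HHb_tis)
  traj$dHbT <- traj$dHbO2 + traj$dHHb
  traj$dOxCCO <- traj$oxCCO_tis - base(traj$oxCCO_tis)
  traj$rCBF <- traj$CBF / base(traj$CBF)
  traj$rCMRO2 <- traj$CMRO2 / base(traj$CMRO2)
  traj$rCBV <- traj$V_blood / base(traj$V_blood)
  traj$Pa <- timeline$P_a
  traj$u <- timeline$u
  attr(traj, "baseline_window") <- baseline_window
  attr(traj, "cbf_clamped") <- clamp
  attr(traj, "amplitudes") <- attr(timeline, "amplitudes")
  attr(traj, "hrf_spec") <- attr(timeline, "hrf_spec")
  attr(traj, "params") <- p
  class(traj) <- c("nh_trajectory", "data.frame")
  traj
}

#' @export
print.nh_trajectory <- function(x, ...) {
  cat(sprintf("<nh_trajectory> %d samples over %.4g s%s\n", nrow(x),
              max(x$time), if (isTRUE(attr(x, "cbf_clamped")))
                " (CBF clamped)" else ""))
  cat(sprintf("  peak dHbO2 = %+.4g uM, extreme dHHb = [%+.4g, %+.4g] uM, peak dHbT = %+.4g uM\n",
              max(x$dHbO2), min(x$dHHb), max(x$dHHb), max(x$dHbT)))
  cat(sprintf("  peak rCBF = %.4g, peak rCMRO2 = %.4g\n",
              max(x$rCBF), max(x$rCMRO2)))
  invisible(x)
}

.nh_delta_cols <- c("dHbO2", "dHHb", "dHbT", "dOxCCO")

#' Block-average a set of trajectories or traces
#'
#' Sample-wise mean of the change signals across repetitions on identical
#' time grids, re-zeroed on the pre-stimulus baseline window; the standard
#' presentation of block-averaged stimulus-evoked fNIRS data.
#'
#' @param trajectories list of `nh_trajectory` / `nh_traces` /
#'   data frames sharing a `time` column and at least one of `dHbO2`,
#'   `dHHb`, `dHbT`, `dOxCCO`.
#' @param baseline_window baseline length used for re-zeroing, s.
#' @return Data frame with `time` and the averaged change columns common
#'   to all inputs.
#' @export
block_average <- function(trajectories, baseline_window = 10) {
  if (inherits(trajectories, "data.frame")) trajectories <- list(trajectories)
  if (!length(trajectories)) stop("no trajectories supplied")
  tt <- trajectories[[1]]$time
  for (tr in trajectories) {
    if (length(tr$time) != length(tt) ||
        !isTRUE(all.equal(tr$time, tt, tolerance = 1e-10))) {
      stop("alignment error: trajectories are not on identical time grids")
    }
  }
  cols <- Reduce(intersect, lapply(trajectories, names))
  cols <- intersect(.nh_delta_cols, cols)
  if (!length(cols)) stop("no change-signal columns shared by all inputs")
  out <- data.frame(time = tt)
  pre <- tt < baseline_window
  if (!any(pre)) pre <- seq_along(tt) == 1
  for (cl in cols) {
    avg <- rowMeans(vapply(trajectories, function(tr) tr[[cl]],
                           numeric(length(tt))))
    out[[cl]] <- avg - mean(avg[pre])
  }
  class(out) <- c("nh_block_average", "data.frame")
  out
}

#' Write a trajectory to delimited text
#'
#' @param traj `nh_trajectory`.
#' @param file output CSV path (header
#'   `time,dHbO2,dHHb,dHbT,dOxCCO,rCBF,rCMRO2,rCBV,Pa,u`).
#' @param meta_file optional JSON sidecar with scenario metadata and a
#'   parameter hash.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file, meta_file = NULL) {
  stopifnot(inherits(traj, "nh_trajectory"))
  cols <- c("time", "dHbO2", "dHHb", "dHbT", "dOxCCO", "rCBF", "rCMRO2",
            "rCBV", "Pa", "u")
  utils::write.csv(as.data.frame(traj)[, cols], file, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(meta_file)) {
    p <- attr(traj, "params")
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(unclass(p), tmp, auto_unbox = TRUE, digits = NA)
    amps <- attr(traj, "amplitudes")
    meta <- list(
      scenario = attr(traj, "scenario"),
      cbf_clamped = isTRUE(attr(traj, "cbf_clamped")),
      amplitudes = if (!is.null(amps)) unclass(amps),
      hrf_spec = if (!is.null(attr(traj, "hrf_spec")))
        unclass(attr(traj, "hrf_spec")),
      parameters = unclass(p),
      parameter_hash = unname(tools::md5sum(tmp)))
    jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(file)
}
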