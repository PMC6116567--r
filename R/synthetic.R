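# Synthetic block-averaged fNIRS traces: forward simulation resampled to a
# measurement rate with additive, channel-independent Gaussian noise.
# Stands in for instrument data in every fitting and averaging test.

#' Specify the synthetic-noise model
#'
#' @param noise_fraction Gaussian noise standard deviation as a fraction of
#'   the scenario's peak absolute `dHbO2` (so the level is
#'   scenario-invariant).
#' @param sampling_rate measurement sampling rate, Hz (default 1 Hz, the
#'   typical block-averaged presentation).
#' @param seed integer RNG seed; mandatory, no hidden global state.
#' @return Object of class `nh_noise_spec`.
#' @export
noise_spec <- function(noise_fraction, sampling_rate = 1, seed) {
  stopifnot(is.finite(noise_fraction), noise_fraction >= 0,
            is.finite(sampling_rate), sampling_rate > 0,
            is.finite(seed))
  structure(list(noise_fraction = noise_fraction,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "nh_noise_spec")
}

# run `code` under a temporary RNG seed, restoring global RNG state after
.nh_with_seed <- function(seed, code) {
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

.nh_fixture_from_trajectory <- function(traj, noise) {
  tgrid <- seq(0, max(traj$time), by = 1 / noise$sampling_rate)
  res <- function(ch) stats::approx(traj$time, traj[[ch]], xout = tgrid)$y
  clean <- list(dHbO2 = res("dHbO2"), dHHb = res("dHHb"), dHbT = res("dHbT"))
  sigma <- noise$noise_fraction * max(abs(traj$dHbO2))
  noisy <- .nh_with_seed(noise$seed, {
    lapply(clean, function(x) x + stats::rnorm(length(x), sd = sigma))
  })
  out <- measured_traces(tgrid, dHbO2 = noisy$dHbO2, dHHb = noisy$dHHb,
                         dHbT = noisy$dHbT)
  attr(out, "sigma") <- sigma
  attr(out, "noise") <- unclass(noise)
  out
}

#' Generate a synthetic measured-trace fixture
#'
#' Forward-simulates a scenario, resamples the change signals to the
#' measurement rate and adds independent Gaussian noise per channel with
#' standard deviation `noise_fraction * max(|dHbO2|)`. Reproducible given
#' the seed in `noise`.
#'
#' @param scenario_name registry name or `nh_scenario`.
#' @param noise a [noise_spec()].
#' @return An `nh_traces` data frame with `sigma` and `noise` attributes.
#' @export
make_fixture <- function(scenario_name, noise) {
  stopifnot(inherits(noise, "nh_noise_spec"))
  sc <- get_scenario(scenario_name)
  out <- .nh_fixture_from_trajectory(run_scenario(sc), noise)
  attr(out, "scenario") <- sc$name
  out
}

#' Generate a parameter-recovery fixture suite
#'
#' Writes one fixture CSV per combination of demand amplitude, pressure
#' amplitude, noise level and seed (all simulated from a common scenario
#' template with the amplitudes substituted) plus a JSON manifest recording
#' the generation settings, enabling seeded recovery experiments.
#'
#' @param dir output directory (created if needed).
#' @param alphas,betas demand / pressure amplitude grids.
#' @param noise_fractions noise levels (fractions of peak `|dHbO2|`).
#' @param seeds integer seeds.
#' @param template scenario providing preset, HRF and clamp flag (default
#'   `"roche_labarbe"`).
#' @param sampling_rate fixture sampling rate, Hz.
#' @return The manifest, invisibly (list with `template`, `sampling_rate`
#'   and one `entries` record per fixture: file, alpha, beta,
#'   noise_fraction, seed, sigma).
#' @export
make_recovery_suite <- function(dir, alphas, betas, noise_fractions, seeds,
                                template = "roche_labarbe",
                                sampling_rate = 1) {
  sc <- get_scenario(template)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- load_preset(sc$preset)
  grid <- expand.grid(alpha = alphas, beta = betas,
                      noise_fraction = noise_fractions, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  entries <- vector("list", nrow(grid))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    key <- sprintf("a%g_b%g", g$alpha, g$beta)
    if (is.null(cache[[key]])) {
      sci <- sc
      sci$amps <- stimulus_amplitudes(alpha = g$alpha, beta = g$beta,
                                      gamma = sc$amps$gamma)
      cache[[key]] <- run_scenario(sci, params = params)
    }
    ns <- noise_spec(g$noise_fraction, sampling_rate, g$seed)
    fx <- .nh_fixture_from_trajectory(cache[[key]], ns)
    file <- sprintf("fixture_a%g_b%g_n%g_s%d.csv", g$alpha, g$beta,
                    g$noise_fraction, as.integer(g$seed))
    utils::write.csv(as.data.frame(fx), file.path(dir, file),
                     row.names = FALSE, quote = FALSE)
    entries[[i]] <- list(file = file, alpha = g$alpha, beta = g$beta,
                         noise_fraction = g$noise_fraction,
                         seed = as.integer(g$seed),
                         sigma = attr(fx, "sigma"))
  }
  manifest <- list(template = sc$name, sampling_rate = sampling_rate,
                   entries = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a recovery-suite manifest
#'
#' @param dir suite directory.
#' @return The manifest list as written by [make_recovery_suite()].
#' @export
read_recovery_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = FALSE)
}
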