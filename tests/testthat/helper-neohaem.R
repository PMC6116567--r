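# Shared fixtures: presets are calibrated once per test run.
nh_preset <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (is.null(cache[[name]])) cache[[name]] <- load_preset(name)
    cache[[name]]
  }
})

nh_registry_trajectories <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$trajs)) {
      cache$trajs <- lapply(scenario_registry(), run_scenario)
    }
    cache$trajs
  }
})

# sign of each change signal at its largest absolute excursion
nh_sign_pattern <- function(traj) {
  vapply(c("dHbO2", "dHHb", "dHbT", "dOxCCO"), function(ch) {
    x <- traj[[ch]]
    sign(x[which.max(abs(x))])
  }, numeric(1))
}
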