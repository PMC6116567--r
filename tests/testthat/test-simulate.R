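test_that("a null stimulus preserves the equilibrium", {
  p <- nh_preset("preterm")
  tl <- build_timeline(stimulus_amplitudes(), hrf_spec(), p,
                       time_grid = seq(0, 60, by = 0.1))
  tr <- run_simulation(p, tl)
  for (ch in c("dHbO2", "dHHb", "dHbT", "dOxCCO")) {
    expect_lt(max(abs(tr[[ch]])), 1e-6)
  }
  expect_lt(max(abs(tr$rCBF - 1)), 1e-8)
  expect_lt(max(abs(tr$CBF - p$CBF_n)), 1e-6)
})

test_that("trajectories satisfy the change-signal invariants", {
  for (tr in nh_registry_trajectories()) {
    expect_identical(tr$dHbT, tr$dHbO2 + tr$dHHb)
    expect_lt(max(abs(tr[1, c("dHbO2", "dHHb", "dHbT", "dOxCCO")])), 1e-9)
    expect_equal(tr$rCBV[1], 1, tolerance = 1e-9)
  }
})

test_that("demand-driven activation yields functional hyperemia", {
  tr <- nh_registry_trajectories()[["roche_labarbe"]]
  expect_gt(max(tr$rCBF), 1)
  expect_gt(max(tr$rCMRO2), 1)
  expect_lt(min(tr$dHHb), 0)
})

test_that("a CBF clamp inverts the deoxy-haemoglobin response", {
  tr <- nh_registry_trajectories()[["usz_neonate2"]]
  expect_gt(max(tr$dHHb), 0)
  expect_true(all(tr$CBF == tr$CBF[1]))  # clamp pins reported flow
})

test_that("vasodilation vs vasoconstriction flips the response sign", {
  p <- nh_preset("preterm")
  grid <- seq(0, 60, by = 0.1)
  dilate <- run_simulation(p, build_timeline(stimulus_amplitudes(alpha = 0.5),
                                             hrf_spec(), p, time_grid = grid))
  expect_lt(min(dilate$dHHb), 0)
  constrict <- run_simulation(p, build_timeline(
    stimulus_amplitudes(gamma = 0.01), hrf_spec(), p, time_grid = grid))
  expect_gt(max(constrict$dHHb), 0)
})

test_that("halving integrator tolerances leaves peaks unchanged", {
  reg <- scenario_registry()
  for (nm in names(reg)) {
    a <- nh_registry_trajectories()[[nm]]
    b <- run_scenario(nm, rtol = 5e-9, atol = 5e-11)
    pk_a <- max(abs(a$dHbO2)); pk_b <- max(abs(b$dHbO2))
    expect_lt(abs(pk_a - pk_b) / pk_a, 1e-3, label = paste("peak", nm))
  }
})

test_that("Fick consistency holds along unclamped trajectories", {
  tr <- nh_registry_trajectories()[["roche_labarbe"]]
  p <- attr(tr, "params")
  fick <- tr$CBF * p$Hbtot * (0.96 - tr$SvO2)
  expect_equal(fick, tr$CMRO2, tolerance = 1e-8)
})

test_that("baseline haemoglobin does not alter the response pattern", {
  base <- load_preset("preterm", calibrated = FALSE)
  reg <- scenario_registry()
  reg <- reg[vapply(reg, function(s) s$preset == "preterm", logical(1))]
  ref <- lapply(names(reg), function(nm) nh_registry_trajectories()[[nm]])
  names(ref) <- names(reg)
  for (s in c(0.9, 1.1)) {
    p <- base; p$Hbtot <- base$Hbtot * s
    pc <- calibrate(p)
    for (nm in names(reg)) {
      tr <- run_scenario(nm, params = pc)
      expect_identical(nh_sign_pattern(tr), nh_sign_pattern(ref[[nm]]),
                       label = sprintf("sign pattern %s x%g", nm, s))
      tp <- tr$time[which.max(abs(tr$dHbO2))]
      tp_ref <- ref[[nm]]$time[which.max(abs(ref[[nm]]$dHbO2))]
      expect_lt(abs(tp - tp_ref) / tp_ref, 0.05)
    }
  }
})

test_that("block averaging combines repetitions correctly", {
  p <- nh_preset("preterm")
  tr <- nh_registry_trajectories()[["roche_labarbe"]]

  same <- block_average(list(tr, tr))
  expect_equal(same$dHbO2, tr$dHbO2, tolerance = 1e-12)

  flip <- as.data.frame(tr)[c("time", "dHbO2", "dHHb", "dHbT", "dOxCCO")]
  for (ch in c("dHbO2", "dHHb", "dHbT", "dOxCCO")) flip[[ch]] <- -flip[[ch]]
  zero <- block_average(list(tr, flip))
  expect_lt(max(abs(zero$dHbO2)), 1e-12)

  short <- tr[1:100, ]
  expect_error(block_average(list(tr, short)), "alignment error")
})

test_that("block averaging reduces fixture noise by sqrt(n)", {
  clean <- make_fixture("roche_labarbe", noise_spec(0, 1, seed = 1))
  fxs <- lapply(1:10, function(s)
    make_fixture("roche_labarbe", noise_spec(0.05, 1, seed = s)))
  avg <- block_average(fxs, baseline_window = 10)
  resid_one <- unlist(lapply(c("dHbO2", "dHHb", "dHbT"),
                             function(ch) fxs[[1]][[ch]] - clean[[ch]]))
  resid_avg <- unlist(lapply(c("dHbO2", "dHHb", "dHbT"),
                             function(ch) avg[[ch]] - clean[[ch]]))
  ratio <- sd(resid_avg) / sd(resid_one)
  expect_lt(abs(ratio - 1 / sqrt(10)), 0.2 / sqrt(10))
})

test_that("simulation guards its preconditions", {
  p <- nh_preset("preterm")
  # stimulus inside the baseline window
  tl <- build_timeline(stimulus_amplitudes(alpha = 0.5),
                       hrf_spec(stimulus_onset = 2), p,
                       time_grid = seq(0, 60, by = 0.1))
  expect_error(run_simulation(p, tl), "baseline inputs")
  # pressure collapse below the intracranial pressure
  tl <- build_timeline(stimulus_amplitudes(beta = 26), hrf_spec(), p,
                       time_grid = seq(0, 60, by = 0.1))
  expect_error(run_simulation(p, tl), "oxygen supply exhausted|failed")
})

test_that("trajectory writer emits the documented table and sidecar", {
  tr <- nh_registry_trajectories()[["roche_labarbe"]]
  csv <- tempfile(fileext = ".csv"); meta <- tempfile(fileext = ".json")
  write_trajectory(tr, csv, meta_file = meta)
  got <- utils::read.csv(csv)
  expect_identical(names(got),
                   c("time", "dHbO2", "dHHb", "dHbT", "dOxCCO", "rCBF",
                     "rCMRO2", "rCBV", "Pa", "u"))
  expect_equal(nrow(got), 601)
  side <- jsonlite::read_json(meta)
  expect_identical(side$scenario, "roche_labarbe")
  expect_true(nzchar(side$parameter_hash))
  unlink(c(csv, meta))
})
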