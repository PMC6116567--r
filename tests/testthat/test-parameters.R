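test_that("shipped population presets carry the reference values", {
  pt <- nh_preset("preterm")
  expect_equal(pt$CBF_n, 19.8)
  expect_equal(pt$CCO_tis, 2.2)
  expect_equal(pt$CuA_frac_n, 0.67)
  expect_equal(pt$CMRO2_n, 40.865)
  expect_equal(pt$P_a_n, 30)
  expect_equal(pt$Hbtot, 9.75)
  expect_equal(pt$V_blood_n, 0.0233)
  expect_equal(pt$P_ic_n, 5.1)

  ad <- nh_preset("adult")
  expect_equal(unlist(ad[c("CBF_n", "CCO_tis", "CuA_frac_n", "CMRO2_n",
                           "P_a_n", "Hbtot", "V_blood_n", "P_ic_n")]),
               c(CBF_n = 49, CCO_tis = 5.5, CuA_frac_n = 0.8, CMRO2_n = 155,
                 P_a_n = 100, Hbtot = 9.1, V_blood_n = 0.04, P_ic_n = 9.5))

  # baseline oxygen extraction fraction must be a proper fraction
  for (p in list(pt, ad)) {
    oef <- p$CMRO2_n / (p$CBF_n * p$Hbtot * p$SaO2_n)
    expect_gt(oef, 0)
    expect_lt(oef, 1)
  }
  expect_error(load_preset("nonexistent"), "unknown preset")
})

test_that("calibration makes the baseline an exact fixed point", {
  for (name in c("preterm", "adult", "neonate1", "neonate2")) {
    p <- nh_preset(name)
    rhs <- model_rhs(baseline_state(p), baseline_inputs(p), p)
    expect_lt(max(abs(rhs)), 1e-10, label = paste0("rhs(", name, ")"))
    d <- derived_quantities(baseline_state(p), baseline_inputs(p), p)
    expect_equal(d$CBF, p$CBF_n)
    expect_equal(d$CMRO2, p$CMRO2_n)
  }
})

test_that("fixed-point property holds across perturbed parameter sets", {
  set.seed(42)
  base <- load_preset("preterm", calibrated = FALSE)
  for (i in 1:12) {
    p <- base
    for (f in c("CBF_n", "Hbtot", "CMRO2_n", "P_a_n", "V_blood_n")) {
      p[[f]] <- p[[f]] * runif(1, 0.9, 1.1)
    }
    pc <- calibrate(p)
    rhs <- model_rhs(baseline_state(pc), baseline_inputs(pc), pc)
    expect_lt(max(abs(rhs)), 1e-10)
    d <- derived_quantities(baseline_state(pc), baseline_inputs(pc), pc)
    expect_equal(d$CBF, pc$CBF_n, tolerance = 1e-12)
    expect_equal(d$CMRO2, pc$CMRO2_n, tolerance = 1e-12)
  }
})

test_that("calibration absorbs a haemoglobin change", {
  p <- load_preset("preterm", calibrated = FALSE)
  p$Hbtot <- p$Hbtot * 1.1
  pc <- calibrate(p)
  expect_lt(max(abs(model_rhs(baseline_state(pc), baseline_inputs(pc), pc))),
            1e-10)
})

test_that("invalid parameter combinations are rejected with diagnostics", {
  p <- load_preset("preterm", calibrated = FALSE)
  bad <- p; bad$CMRO2_n <- 1e4
  expect_error(calibrate(bad), "extraction fraction")
  bad <- p; bad$P_a_n <- 4   # below P_ic_n
  expect_error(calibrate(bad), "P_ic_n")
  expect_error(parameter_set(CBF_n = -1, CCO_tis = 2.2, CuA_frac_n = 0.67,
                             CMRO2_n = 40.865, P_a_n = 30, Hbtot = 9.75,
                             V_blood_n = 0.0233, P_ic_n = 5.1),
               "strictly positive")
  expect_error(parameter_set(CBF_n = 19.8, CCO_tis = 2.2, CuA_frac_n = 0.67,
                             CMRO2_n = 40.865, P_a_n = 30, Hbtot = 9.75,
                             V_blood_n = 0.0233, P_ic_n = 5.1, bogus = 1),
               "unknown parameter")
})

test_that("subject overrides convert haemoglobin and recalibrate", {
  base <- nh_preset("preterm")
  n1 <- subject_overrides(base, haemoglobin_g_dL = 17.08, baseline_SpO2 = 0.95)
  expect_equal(n1$Hbtot, 10.59, tolerance = 1e-3)
  expect_equal(n1$SaO2_n, 0.95)
  n2 <- subject_overrides(base, haemoglobin_g_dL = 9.70)
  expect_equal(n2$Hbtot, 6.02, tolerance = 1e-3)
  for (p in list(n1, n2)) {
    expect_lt(max(abs(model_rhs(baseline_state(p), baseline_inputs(p), p))),
              1e-10)
  }
  # identity when no overrides requested
  expect_identical(subject_overrides(base), base)
  expect_error(subject_overrides(base, haemoglobin_g_dL = -2), "positive")
  expect_error(subject_overrides(base, baseline_SpO2 = 1.2), "0, 1")

  # shipped subject presets equal the override construction
  expect_equal(nh_preset("neonate1")$Hbtot, n1$Hbtot)
  expect_equal(nh_preset("neonate2")$Hbtot, n2$Hbtot)
})
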