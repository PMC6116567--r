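test_that("rhs responds to demand and pressure with the stated signs", {
  p <- nh_preset("preterm")
  st <- baseline_state(p)

  inp <- baseline_inputs(p); inp$u <- 1.5
  d <- model_rhs(st, inp, p)
  expect_lt(d[["a"]], 0)      # demand reduces oxidised CuA before flow responds
  expect_lt(d[["mu"]], 0)     # and dilates the vasculature

  inp <- baseline_inputs(p); inp$P_a <- p$P_a_n + 10
  expect_gt(model_rhs(st, inp, p)[["mu"]], 0)  # pressure rise constricts

  inp <- baseline_inputs(p); inp$PaCO2 <- p$PaCO2_n + 5
  expect_lt(model_rhs(st, inp, p)[["mu"]], 0)  # hypercapnia dilates
})

test_that("rhs validates calibration and state bounds", {
  p_raw <- load_preset("preterm", calibrated = FALSE)
  expect_error(model_rhs(baseline_state(p_raw), baseline_inputs(p_raw), p_raw),
               "not calibrated")
  p <- nh_preset("preterm")
  expect_error(model_rhs(c(mu = 1.5, O2t = 0.024, a = 0.67),
                         baseline_inputs(p), p), "mu in \\[-1, 1\\]")
  expect_error(model_rhs(c(mu = 0, O2t = -0.01, a = 0.67),
                         baseline_inputs(p), p), "O2t >= 0")
  expect_error(model_rhs(c(mu = 0, O2t = 0.024, a = 1.2),
                         baseline_inputs(p), p), "a in \\[0, 1\\]")
  inp <- baseline_inputs(p); inp$u <- 0
  expect_error(model_rhs(baseline_state(p), inp, p), "u must be")
})

test_that("flow follows the quartic radius law", {
  p <- nh_preset("preterm")
  # low tissue O2 keeps CMRO2 below the delivery of the half-radius bed so
  # the oxygen-supply guard stays silent over the whole radius range
  st <- c(mu = 0, O2t = 0.001, a = p$CuA_frac_n)
  base_inp <- baseline_inputs(p)
  cbf <- vapply(c(0.5, 1, 2), function(m) {
    inp <- base_inp; inp$m <- m
    derived_quantities(st, inp, p)$CBF
  }, numeric(1))
  # with tone frozen at baseline, m multiplies r directly
  expect_equal(cbf[1] / cbf[2], 0.5^4, tolerance = 1e-12)
  expect_equal(cbf[3] / cbf[2], 2^4, tolerance = 1e-12)
  expect_equal(cbf[3], 16 * p$CBF_n, tolerance = 1e-12)
})

test_that("the CBF clamp pins flow at its normal value", {
  p <- nh_preset("preterm")
  st <- baseline_state(p)
  for (P in c(20, 30, 45)) {
    inp <- baseline_inputs(p, cbf_clamped = TRUE); inp$P_a <- P
    expect_equal(derived_quantities(st, inp, p)$CBF, p$CBF_n)
  }
})

test_that("observables satisfy their structural invariants", {
  p <- nh_preset("preterm")
  set.seed(7)
  for (i in 1:20) {
    st <- c(mu = runif(1, -0.9, 0.9), O2t = runif(1, 0.005, 0.05),
            a = runif(1, 0.1, 0.95))
    inp <- baseline_inputs(p)
    inp$P_a <- runif(1, 20, 60); inp$u <- runif(1, 0.8, 1.5)
    inp$m <- runif(1, 0.95, 1.05); inp$SaO2 <- runif(1, 0.85, 1)
    d <- derived_quantities(st, inp, p)
    expect_identical(d$HbT_tis, d$HbO2_tis + d$HHb_tis)
    expect_gte(d$SvO2, 0)
    expect_lte(d$SvO2, inp$SaO2)
    expect_gt(d$V_blood, 0)
  }
})

test_that("exhausted oxygen supply raises an error instead of clipping", {
  p <- nh_preset("preterm")
  inp <- baseline_inputs(p)
  inp$SaO2 <- 0.2  # extraction demand exceeds arterial content
  expect_error(derived_quantities(baseline_state(p), inp, p),
               "oxygen supply exhausted")
})

test_that("steady_state returns the baseline fixed point and obeys Fick", {
  for (name in c("preterm", "adult")) {
    p <- nh_preset(name)
    ss <- steady_state(p)
    expect_equal(unname(ss), unname(baseline_state(p)), tolerance = 1e-9)
  }
  # Fick consistency at non-baseline steady states
  p <- nh_preset("preterm")
  for (mod in list(list(P_a = 40), list(u = 1.2), list(SaO2 = 0.9))) {
    inp <- utils::modifyList(baseline_inputs(p), mod)
    st <- steady_state(p, inp)
    d <- derived_quantities(st, inp, p)
    fick <- d$CBF * p$Hbtot * (inp$SaO2 - d$SvO2)
    expect_equal(fick, d$CMRO2, tolerance = 1e-6)
  }
})

test_that("steady states above the plateau and under demand match the flow oracle", {
  p <- nh_preset("preterm")

  inp <- baseline_inputs(p); inp$P_a <- 60
  ss <- steady_state(p, inp)
  expect_gt(derived_quantities(ss, inp, p)$CBF, p$CBF_n)  # pressure-passive
  li <- neohaem:::.nh_integrate_constant(p, inp)
  expect_lt(max(abs(ss - li)), 1e-6)

  inp <- baseline_inputs(p); inp$u <- 1.2
  ss <- steady_state(p, inp)
  expect_gt(derived_quantities(ss, inp, p)$CMRO2, p$CMRO2_n)
  li <- neohaem:::.nh_integrate_constant(p, inp)
  expect_lt(max(abs(ss - li)), 1e-6)
})

test_that("steady venous saturation is monotone in metabolic rate and flow", {
  base <- load_preset("preterm", calibrated = FALSE)
  scl <- c(0.8, 1, 1.2)
  sv <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    p <- base
    p$CMRO2_n <- base$CMRO2_n * scl[i]
    p$CBF_n <- base$CBF_n * scl[j]
    pc <- calibrate(p)
    st <- steady_state(pc)
    sv[i, j] <- derived_quantities(st, baseline_inputs(pc), pc)$SvO2
  }
  for (j in 1:3) expect_true(all(diff(sv[, j]) < 0))  # decreasing in CMRO2_n
  for (i in 1:3) expect_true(all(diff(sv[i, ]) > 0))  # increasing in CBF_n
})
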