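test_that("integration reproduces closed-form trajectories with both methods", {
  # single compartment, net rate r: C(t) = C0 exp(r t)
  sys <- toy_system(kappa = c(HSC = 0.6), rho = c(HSC = 0.85))
  r <- (2 * 0.85 - 1) * 0.6
  init <- toy_state(HSC = 250)
  times <- c(0, 1.5, 3, 6)
  for (m in c("expm", "lsoda")) {
    tr <- integrate_model(sys, initial = init, times = times, method = m)
    expect_equal(tr$HSC, 250 * exp(r * times), tolerance = 1e-6)
  }

  # all-zero rates: constant trajectory
  tr0 <- integrate_model(toy_system(), initial = toy_state(MPP = 42, dead = 7),
                         times = c(0, 3, 6))
  expect_equal(tr0$MPP, rep(42, 3))
  expect_equal(tr0$totalDeadCells, rep(7, 3))

  # terminal decay: live falls exponentially, dead accrues the complement
  sysd <- toy_system(delta = 0.5)
  trd <- integrate_model(sysd, initial = toy_state(Mono = 400), times = c(0, 2, 6))
  expect_equal(trd$Mono, 400 * exp(-0.5 * c(0, 2, 6)), tolerance = 1e-6)
  expect_equal(trd$totalDeadCells, 400 - trd$Mono, tolerance = 1e-6)
})

test_that("trajectories report consistent derived readouts", {
  sys <- default_system_parameters()
  tr <- integrate_model(sys, initial = default_initial_state(),
                        times = c(0, 2, 4, 6))
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(as.matrix(tr[, readout_names()]) >= 0))
  expect_equal(tr$totalViableCells,
               unname(rowSums(tr[, cell_type_ids()])))
  # the neutrophil readout folds in the quiescent pool
  states <- attr(tr, "states")
  expect_equal(tr$Neut, states[, "Neut"] + states[, "NeutQ"])
})

test_that("control kinetics restrict the full trajectory and echo day 0", {
  sys <- default_system_parameters()
  init <- default_initial_state()
  single <- simulate_control_kinetics(sys, init, days = 0)
  expect_equal(unlist(single[1, cell_type_ids()]),
               init[cell_type_ids()])
  full <- simulate_control_kinetics(sys, init)
  sub <- integrate_model(sys, initial = init, times = c(2, 3, 4, 5, 6))
  expect_equal(unname(as.matrix(full[full$time >= 2, readout_names()])),
               unname(as.matrix(sub[, readout_names()])), tolerance = 1e-9)

  # doubling toy: one self-renewing type at kappa = ln 2 reaches 6400 on day 6
  sys2 <- toy_system(kappa = c(HSC = log(2)), rho = c(HSC = 1))
  tr <- simulate_control_kinetics(sys2, toy_state(HSC = 100))
  expect_equal(tr$HSC[tr$time == 6], 6400, tolerance = 1e-8)
})

test_that("dose-response normalization behaves as vehicle ratio", {
  sys <- default_system_parameters()
  init <- default_initial_state()
  # inert drug: every entry 1
  dr <- simulate_dose_response(sys, inert_drug(), initial = init)
  expect_equal(unname(dr$normalized), matrix(1, 7, 14), tolerance = 1e-9)
  # dose 0 row normalizes to itself
  dr0 <- simulate_dose_response(sys, sparse_drug("HSC", 0.9, 25),
                                doses = c(0, 25, 2500), initial = init)
  expect_equal(unname(dr0$normalized[1, ]), rep(1, 14))
  # live readouts monotone non-increasing in dose under a single Hill
  drd <- simulate_dose_response(sys, reference_drug_params("docetaxel"),
                                initial = init)
  for (id in cell_type_ids())
    expect_true(all(diff(drd$normalized[, id]) <= 1e-10))
})

test_that("dead-cell normalized readout rises with dose only via killing", {
  # delta = 0 isolates the killing flux contribution to the dead pool
  sys <- default_system_parameters()
  sys$delta <- 0
  init <- default_initial_state()
  killer <- sparse_drug("MPP", 2.0, 25)
  dr <- simulate_dose_response(sys, killer, initial = init)
  expect_true(all(diff(dr$normalized[, "totalDeadCells"]) >= -1e-10))
  expect_gt(dr$normalized[7, "totalDeadCells"], 1)
  # purely anti-proliferative: dead readout pinned at 1 across doses
  ap <- sparse_drug("MPP", 1.0, 25)
  dra <- simulate_dose_response(sys, ap, initial = init)
  expect_equal(unname(dra$normalized[, "totalDeadCells"]), rep(1, 7),
               tolerance = 1e-9)
})

test_that("two-compartment dose-response ratio matches the analytic Hill attenuation", {
  # HSC self-renewing (rho = 1): treated/vehicle = exp((k_eff - k) * day)
  sys <- toy_system(kappa = c(HSC = 1), rho = c(HSC = 1))
  drug <- sparse_drug("HSC", 0.5, 25)
  init <- toy_state(HSC = 100, dead = 10)
  doses <- dose_grid()
  dr <- simulate_dose_response(sys, drug, doses = doses, initial = init)
  k_eff <- effective_division_rate(1, 0.5, doses, 25)
  expect_equal(unname(dr$normalized[, "HSC"]), exp((k_eff - 1) * 6),
               tolerance = 1e-6)
})

test_that("halving integrator tolerances barely moves day-6 readouts", {
  sys <- default_system_parameters()
  init <- default_initial_state()
  a <- integrate_model(sys, initial = init, times = c(0, 6), method = "lsoda",
                       rtol = 1e-8, atol = 1e-8)
  b <- integrate_model(sys, initial = init, times = c(0, 6), method = "lsoda",
                       rtol = 5e-9, atol = 5e-9)
  rel <- abs(as.matrix(a[2, readout_names()]) - as.matrix(b[2, readout_names()])) /
    (abs(as.matrix(a[2, readout_names()])) + 1)
  expect_lt(max(rel), 1e-4)
})
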