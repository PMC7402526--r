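# small noiseless dataset shared across calibration tests
calib_data <- local({
  generate_kinetic_dataset(default_system_parameters(),
                           default_initial_state(),
                           noise_model(donor_count = 3, cv = 0))
})

test_that("kinetic objective is zero at truth and quadratic in the residuals", {
  sys <- default_system_parameters()
  init <- default_initial_state()
  initials <- c(init[cell_type_ids()], totalDeadCells = init[["totalDeadCells"]])
  names(initials) <- readout_names()
  expect_equal(kinetic_objective(sys, initials, calib_data), 0, tolerance = 1e-14)

  # frozen-rate toy: the simulation is constant, residuals are hand-computable
  sys0 <- toy_system()
  obs <- calib_data
  initials0 <- stats::setNames(rep(100, 14), readout_names())
  days <- c(2, 3)
  donors <- expand.grid(donor_id = "d1", day = days,
                        readout = readout_names(),
                        stringsAsFactors = FALSE)
  donors$cells_per_ml <- ifelse(donors$readout == "HSC",
                                ifelse(donors$day == 2, 110, 90), 100)
  toy_data <- kinetic_dataset(donors)
  # raw scaling: residuals are (100-110) and (100-90) on HSC only
  expect_equal(kinetic_objective(sys0, initials0, toy_data, scaling = "raw"),
               (-10)^2 + 10^2)
  # scaled: each divided by the HSC mean level 100
  expect_equal(kinetic_objective(sys0, initials0, toy_data, scaling = "scaled"),
               2 * (10 / 100)^2)
  # doubling all residuals quadruples the quadratic form
  donors2 <- donors
  donors2$cells_per_ml <- ifelse(donors2$readout == "HSC",
                                 ifelse(donors2$day == 2, 120, 80), 100)
  toy_data2 <- kinetic_dataset(donors2)
  expect_equal(kinetic_objective(sys0, initials0, toy_data2, scaling = "raw"),
               4 * kinetic_objective(sys0, initials0, toy_data, scaling = "raw"))
})

test_that("objective consumes the donor mean and ignores donor ordering", {
  d <- calib_data$donors
  shuffled <- kinetic_dataset(d[rev(seq_len(nrow(d))), ])
  sys <- default_system_parameters()
  initials <- stats::setNames(
    c(default_initial_state()[cell_type_ids()],
      default_initial_state()[["totalDeadCells"]]), readout_names())
  expect_equal(kinetic_objective(sys, initials, shuffled),
               kinetic_objective(sys, initials, calib_data))
})

test_that("system fits respect bounds and are seed-deterministic", {
  settings <- fit_settings(max_generations = 2, population_size = 12,
                           seed = 11, local_search = FALSE)
  f1 <- fit_system(calib_data, settings)
  f2 <- fit_system(calib_data, settings)
  expect_identical(f1$system, f2$system)
  expect_identical(f1$objective, f2$objective)
  expect_gte(f1$system$rho[["HSC"]], 0.5)
  expect_true(all(f1$system$rho[-1] <= 0.5))
  expect_true(all(f1$system$kappa >= 0 & f1$system$kappa <= 4 / log(2)))
  expect_equal(sum(f1$system$beta[1:4]), 1, tolerance = 1e-9)
  expect_equal(sum(f1$system$beta[5:6]), 1, tolerance = 1e-9)
  b <- f1$bounds
  expect_true(all(f1$initials >= b$lower[paste0("init_", readout_names())] - 1e-9))
  expect_true(all(f1$initials <= b$upper[paste0("init_", readout_names())] + 1e-9))
})

test_that("profile likelihood bounds the unconstrained optimum and flags flatness", {
  # an empty culture constrains nothing: every profile is exactly flat
  empty <- generate_kinetic_dataset(toy_system(), toy_state(),
                                    noise_model(donor_count = 2, cv = 0))
  settings <- fit_settings(max_generations = 3, population_size = 30,
                           seed = 3, scaling = "log", n_polish = 1L,
                           n_hops = 2L)
  prof <- profile_likelihood("kappa_Gran", grid = c(0.5, 2, 4), data = empty,
                             settings = settings)
  expect_true(attr(prof, "flat"))
  expect_equal(prof$objective, rep(0, 3), tolerance = 1e-12)

  # a two-compartment culture pins kappa_HSC: profiling at the generating
  # value recovers the optimum, profiling far away forces a worse fit
  sys <- toy_system(kappa = c(HSC = 0.7, MPP = 0.5),
                    rho = c(HSC = 0.9, MPP = 0.4))
  init <- toy_state(HSC = 1000, MPP = 500, dead = 50)
  data <- generate_kinetic_dataset(sys, init, noise_model(donor_count = 2, cv = 0))
  base <- fit_system(data, settings)
  prof2 <- profile_likelihood("kappa_HSC", grid = c(0.7, 3.5), data = data,
                              settings = settings, start = base)
  expect_false(attr(prof2, "flat"))
  expect_gt(prof2$objective[2], prof2$objective[1] + 1)
  # constrained refits cannot beat the unconstrained optimum beyond
  # optimizer noise, and at the optimum they coincide with it
  expect_true(all(prof2$objective >= base$objective - 0.1 * (1 + base$objective)))
  expect_equal(prof2$objective[1], base$objective, tolerance = 0.1)
})

test_that("linearized identifiability flags unconstrained parameters", {
  sys <- default_system_parameters()
  init <- default_initial_state()
  initials <- stats::setNames(
    c(init[cell_type_ids()], init[["totalDeadCells"]]), readout_names())
  # at the assay-noise scale only the stiffest parameters clear the cutoff
  ident <- assess_identifiability(sys, initials, calib_data)
  expect_true(all(c("parameter", "rel_se", "identifiable") %in% names(ident)))
  expect_true(ident$identifiable[ident$parameter == "rho_HSC"])
  # judged at the residual tolerance of a noiseless fit, the bulk of the
  # kinetic parameters are pinned down
  ident0 <- assess_identifiability(sys, initials, calib_data, sigma = 0.005)
  kap <- ident0[grepl("^kappa_", ident0$parameter), ]
  expect_gt(mean(kap$identifiable), 0.5)
})
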