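test_that("total drug mass is conserved with zero clearance", {
  mod <- build_model(reference_adult(), inert_drug())
  prof <- simulate_model(mod, single_dose("iv_bolus", 2, duration = 100))
  mb <- prof$mass_balance
  expect_lt(max(abs(mb$rel_error)), 1e-6)
  # essentially nothing eliminated
  expect_lt(max(prof$eliminated$renal + prof$eliminated$biliary), 1e-6)
})

test_that("mass balance closes at every output time with elimination", {
  mod <- ref_model()
  for (reg in list(single_dose("iv_bolus", 2, duration = 72),
                   single_dose("oral", 80, duration = 72))) {
    prof <- simulate_model(mod, reg)
    expect_lt(max(abs(prof$mass_balance$rel_error)), 1e-6)
  }
})

test_that("with unit partitioning and no clearance all tissues equilibrate", {
  mod <- build_model(reference_adult(), inert_drug(unit_kp = TRUE))
  prof <- simulate_model(mod, single_dose("iv_bolus", 10, duration = 300),
                         keep_states = TRUE)
  st <- prof$states
  last <- st[nrow(st), ]
  org <- reference_adult()$organs
  conc <- vapply(org$organ[org$organ != "lung"], function(o) {
    vol <- org$volume_L[org$organ == o]
    nm <- switch(o, venous_blood = "venous", arterial_blood = "arterial", o)
    last[[nm]] / vol
  }, 0)
  conc <- c(conc, lung = last[["lung"]] / org$volume_L[org$organ == "lung"])
  expect_lt(diff(range(conc)) / mean(conc), 1e-4)
})

test_that("IV AUC0-inf equals Dose/CL_T independent of the Kp set", {
  target <- 2 / (219 * 0.06) * 1000  # ng.h/mL
  base <- nadolol_parameters()
  perturbed <- nadolol_parameters()
  tab <- organ_reference_table()
  perturbed$kp_overrides <- stats::setNames(
    (tab$water + 10^0.81 * tab$lipid + (1 / 0.7 - 1) * tab$protein) *
      c(2, 0.5)[1 + seq_len(nrow(tab)) %% 2],
    tab$organ
  )
  for (drug in list(base, perturbed)) {
    prof <- simulate_model(build_model(reference_adult(), drug),
                           single_dose("iv_bolus", 2, duration = 120))
    nc <- run_nca(prof, dose = 2, route = "iv_bolus")
    expect_lt(abs(nc$auc_0_inf - target) / target, 0.01)
  }
})

test_that("kinetics are linear in dose", {
  mod <- ref_model()
  p1 <- simulate_model(mod, single_dose("iv_bolus", 1, duration = 48))
  p2 <- simulate_model(mod, single_dose("iv_bolus", 2, duration = 48))
  nz <- p2$conc > 1e-9
  expect_lt(max(abs(2 * p1$conc[nz] - p2$conc[nz]) / p2$conc[nz]), 1e-4)
})

test_that("once-daily oral dosing reaches superposition steady state", {
  mod <- ref_model()
  single <- simulate_model(mod, single_dose("oral", 80, duration = 500),
                           simulation_settings(grid_step = 0.25))
  auc_inf <- run_nca(single, dose = 80, route = "oral")$auc_0_inf

  ss <- simulate_model(mod, repeated_dose("oral", 80, interval = 24,
                                          n_doses = 10, duration = 240),
                       simulation_settings(grid_step = 0.25))
  sel <- ss$times >= 216
  auc_tau <- trapz_for_test(ss$times[sel], ss$conc[sel])
  expect_lt(abs(auc_tau - auc_inf) / auc_inf, 0.02)
})

test_that("exposure is monotone non-increasing in GFR", {
  drug <- nadolol_parameters()
  auc <- vapply(c(18, 45, 90, 120), function(g) {
    prof <- simulate_model(build_model(adult_with_gfr(g), drug),
                           single_dose("iv_bolus", 2, duration = 120))
    run_nca(prof, dose = 2, route = "iv_bolus")$auc_0_inf
  }, 0)
  expect_true(all(diff(auc) < 0))
})

test_that("severe renal failure raises population mean exposure", {
  drug <- nadolol_parameters()
  reg <- single_dose("oral", 80, duration = 72)
  healthy <- sample_population(population_spec(8, c(18, 74), seed = 3))
  rf <- sample_population(population_spec(8, c(18, 74),
                                          health_state = "severe_rf",
                                          seed = 3))
  auc_h <- mean(vapply(simulate_population(healthy, drug, reg),
                       function(p) trapz_for_test(p$times, p$conc), 0))
  auc_rf <- mean(vapply(simulate_population(rf, drug, reg),
                        function(p) trapz_for_test(p$times, p$conc), 0))
  expect_gt(auc_rf, auc_h)
})

test_that("halving the output step leaves NCA results essentially unchanged", {
  mod <- ref_model()
  reg <- single_dose("oral", 80, duration = 96)
  nc1 <- run_nca(simulate_model(mod, reg, simulation_settings(grid_step = 0.2)),
                 dose = 80, route = "oral")
  nc2 <- run_nca(simulate_model(mod, reg, simulation_settings(grid_step = 0.1)),
                 dose = 80, route = "oral")
  expect_lt(abs(nc1$auc_0_t - nc2$auc_0_t) / nc2$auc_0_t, 0.005)
  expect_lt(abs(nc1$cmax - nc2$cmax) / nc2$cmax, 0.005)
})

test_that("per-kg doses resolve against body weight", {
  mod <- ref_model()  # 70 kg reference
  abs_prof <- simulate_model(mod, single_dose("iv_bolus", 70, duration = 24))
  kg_prof <- simulate_model(mod, single_dose("iv_bolus", 1, duration = 24,
                                             per_kg = TRUE))
  expect_equal(kg_prof$conc, abs_prof$conc, tolerance = 1e-9)
})

test_that("population simulation is order-stable and reports subject failures", {
  pop <- sample_population(population_spec(4, c(20, 30), seed = 5))
  drug <- nadolol_parameters()
  reg <- single_dose("iv_bolus", 2, duration = 24)
  profs <- simulate_population(pop, drug, reg)
  expect_length(profs, 4)
  expect_equal(vapply(profs, `[[`, 0L, "subject_id"), 1:4)

  # identical individuals give identical profiles
  same <- list(pop[[1]], pop[[1]])
  profs2 <- simulate_population(same, drug, reg)
  expect_equal(profs2[[1]]$conc, profs2[[2]]$conc)

  expect_error(simulate_population(list(), drug, reg))
})

test_that("regimens and settings reject malformed inputs", {
  expect_error(dose_event("iv_bolus", -1))
  expect_error(dose_event("oral", 80, time = -2))
  expect_error(regimen(list(dose_event("oral", 80, 0),
                            dose_event("oral", 80, 0))))
  expect_error(simulation_settings(rtol = 0))
  expect_error(simulation_settings(output_grid = c(2, 1)))
  ref <- reference_adult()
  ref$organs <- ref$organs[ref$organs$organ != "kidney", ]
  # flow balance broken too, but the missing organ must be detected
  expect_error(build_model(ref, nadolol_parameters()))
})
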