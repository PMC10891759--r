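make_iv_spec <- function(...) {
  synthetic_study_spec(cl = 219, v_central = 150, dose_mg = 2,
                       route = "iv_bolus",
                       times = c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 16, 24,
                                 30, 36), ...)
}

test_that("the closed-form profile satisfies its analytic identities", {
  spec <- make_iv_spec()
  # C(0+) = Dose / V for a one-compartment IV bolus
  spec0 <- spec; spec0$times <- c(0, 1, 2)
  prof0 <- closed_form_profile(spec0)
  expect_equal(prof0$conc[1], 2 / 150 * 1000, tolerance = 1e-12)

  # dense trapezoid AUC equals F*Dose/CL to 0.1%
  dense <- spec
  dense$times <- c(seq(0, 10, by = 0.01), seq(10.1, 400, by = 0.1))
  pd <- closed_form_profile(dense)
  auc <- trapz_for_test(pd$time, pd$conc)
  expect_lt(abs(auc - 2 / (219 * 0.06) * 1000) / (2 / (219 * 0.06) * 1000),
            0.001)
})

test_that("the two-compartment curve collapses to one compartment as Q -> 0", {
  t <- seq(0.1, 72, by = 0.1)
  one <- synthetic_study_spec(cl = 219, v_central = 150, dose_mg = 2,
                              route = "iv_bolus", times = t)
  two <- synthetic_study_spec(cl = 219, v_central = 150, v_peripheral = 50,
                              q_inter = 1e-9, dose_mg = 2,
                              route = "iv_bolus", times = t)
  c1 <- closed_form_profile(one)$conc
  c2 <- closed_form_profile(two)$conc
  expect_lt(max(abs(c1 - c2) / pmax(c1, 1e-9)), 1e-4)
})

test_that("oral closed form handles the degenerate ka = k limit", {
  k <- 219 * 0.06 / 150
  sp <- synthetic_study_spec(cl = 219, v_central = 150, ka = k,
                             f_oral = 0.34, dose_mg = 80, route = "oral",
                             times = seq(0.5, 96, by = 0.5))
  prof <- closed_form_profile(sp)
  expect_true(all(is.finite(prof$conc)))
  # limit form: C = F D k t exp(-k t) / V
  expected <- 0.34 * 80 * k * prof$time * exp(-k * prof$time) / 150 * 1000
  expect_equal(prof$conc, expected, tolerance = 1e-6)
})

test_that("noise-free generation recovers the generating clearance", {
  spec <- make_iv_spec(prop_cv = 0, add_floor = 0, iiv_cv = 0,
                       n_subjects = 1, seed = 4)
  spec$times <- seq(0.1, 200, by = 0.1)
  study <- generate_observed_study(spec)
  nc <- run_nca(study$profiles[[1]], dose = 2, route = "iv_bolus")
  expect_lt(abs(nc$cl - 219) / 219, 0.01)
  expect_lt(abs(nc$auc_0_inf - 152.2) / 152.2, 0.01)
})

test_that("generation is reproducible from the seed", {
  spec <- make_iv_spec(n_subjects = 10, seed = 99)
  s1 <- generate_observed_study(spec)
  s2 <- generate_observed_study(spec)
  expect_identical(s1, s2)
  spec2 <- make_iv_spec(n_subjects = 10, seed = 100)
  expect_false(identical(generate_observed_study(spec2), s1))
})

test_that("NCA recovers clearance across a noisy synthetic population", {
  spec <- make_iv_spec(n_subjects = 200, seed = 17,
                       prop_cv = 0.10, add_floor = 0.1, iiv_cv = 0.20)
  study <- generate_observed_study(spec)
  cls <- vapply(study$profiles, function(p) {
    run_nca(p, dose = 2, route = "iv_bolus")$cl
  }, 0)
  geo <- exp(mean(log(cls)))
  expect_lt(abs(geo - 219) / 219, 0.05)
})

test_that("engine predictions validate against matched synthetic observations", {
  # predicted arm: the PBPK engine; observed arm: the synthetic generator
  # built from the same clearance -- AFE of the AUC/CL ratios must be
  # close to unity
  times <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 16, 24, 30, 36)
  prof <- simulate_model(ref_model(), single_dose("iv_bolus", 2,
                                                  duration = 36))
  on_grid <- data.frame(
    time = times,
    conc = approx(prof$times, prof$conc, times)$y
  )
  pred <- run_nca(on_grid, dose = 2, route = "iv_bolus")

  spec <- make_iv_spec(n_subjects = 40, seed = 23)
  study <- generate_observed_study(spec)
  obs_nca <- lapply(study$profiles, run_nca, dose = 2, route = "iv_bolus")
  obs_auc <- exp(mean(log(vapply(obs_nca, `[[`, 0, "auc_0_inf"))))
  obs_cl <- exp(mean(log(vapply(obs_nca, `[[`, 0, "cl"))))

  ratios <- c(pred_obs_ratio(pred$auc_0_inf, obs_auc),
              pred_obs_ratio(pred$cl, obs_cl))
  a <- afe(ratios)
  expect_gt(a, 0.9)
  expect_lt(a, 1.1)
})

test_that("synthetic studies export in the tidy profile format", {
  spec <- make_iv_spec(n_subjects = 3, seed = 1)
  study <- generate_observed_study(spec)
  path <- tempfile(fileext = ".csv")
  write_synthetic_study(study, path)
  df <- read.csv(path)
  expect_named(df, c("subject_id", "time_h", "conc_ng_per_mL"))
  expect_equal(nrow(df), 3 * length(spec$times))
  unlink(path)
})
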