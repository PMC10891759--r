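test_that("reference adult is deterministic and satisfies its invariants", {
  a <- reference_adult()
  b <- reference_adult()
  expect_identical(a, b)
  expect_silent(validate_physiology(a))
  expect_equal(a$gfr, 120)
  expect_equal(a$hematocrit, 0.45)
  expect_equal(a$gastric_emptying_min, 15)
  expect_gt(a$hematocrit, 0)
  expect_lt(a$hematocrit, 1)
  sys <- a$organs[!(a$organs$organ %in%
                      c("venous_blood", "arterial_blood", "lung")), ]
  expect_equal(sum(sys$flow_L_per_h), a$cardiac_output_L_h,
               tolerance = 1e-9)
})

test_that("renal-failure scaling sets exactly the three disease fields", {
  ref <- reference_adult()
  mod <- apply_renal_failure(ref, "moderate")
  sev <- apply_renal_failure(ref, "severe")

  expect_equal(mod$gfr, 45)
  expect_equal(mod$hematocrit, 0.42)
  expect_equal(mod$gastric_emptying_min, 20.4)
  expect_equal(sev$gfr, 18)
  expect_equal(sev$hematocrit, 0.39)
  expect_equal(sev$gastric_emptying_min, 24.6)

  # everything else untouched; input not mutated
  expect_identical(mod$organs, ref$organs)
  expect_identical(mod$body_weight, ref$body_weight)
  expect_equal(ref$gfr, 120)

  # idempotent per severity
  expect_equal(apply_renal_failure(mod, "moderate")$gfr, mod$gfr)

  # unknown severity is a named error
  expect_error(apply_renal_failure(ref, "mild"),
               class = "nadpbpk_severity_error")
})

test_that("GFR maturation saturates at the adult value and is monotone", {
  at18 <- scale_to_age(18, body_weight = 70, height = 170)
  expect_lt(abs(at18$gfr - 120) / 120, 0.02)

  ages <- c(0.25, 0.5, 1, 2, 4, 6, 9, 12, 15, 18)
  gfr <- vapply(ages, function(a) scale_to_age(a)$gfr, 0)
  expect_true(all(diff(gfr) >= 0))
  expect_lt(scale_to_age(0.25, body_weight = 6.4)$gfr, 120)

  expect_error(scale_to_age(0))
  expect_error(scale_to_age(25))
  expect_error(scale_to_age(5, body_weight = -1))
})

test_that("the maturation sigmoid evaluates to its documented closed form", {
  # independent arithmetic: Hill sigmoid of postmenstrual age with
  # TM50 47.7 weeks, coefficient 3.4, allometric weight scaling
  age <- 10; wt <- 32
  pma <- age * 52.1775 + 40
  frac <- pma^3.4 / (47.7^3.4 + pma^3.4)
  expected <- 120 * (wt / 70)^0.75 * frac
  expect_equal(scale_to_age(age, body_weight = wt)$gfr, expected,
               tolerance = 1e-10)
  expect_equal(gfr_maturation_fraction(pma), frac, tolerance = 1e-12)
})

test_that("flow balance holds for reference, disease and pediatric states", {
  states <- list(
    reference_adult(),
    apply_renal_failure(reference_adult(), "moderate"),
    apply_renal_failure(reference_adult(), "severe"),
    scale_to_age(0.25), scale_to_age(2), scale_to_age(10), scale_to_age(17)
  )
  for (st in states) {
    sys <- st$organs[!(st$organs$organ %in%
                         c("venous_blood", "arterial_blood", "lung")), ]
    expect_lt(abs(sum(sys$flow_L_per_h) - st$cardiac_output_L_h) /
                st$cardiac_output_L_h, 1e-6)
  }
})

test_that("population sampling is seeded, bounded and demographically faithful", {
  spec <- population_spec(100, c(18, 74), female_fraction = 0.25, seed = 42)
  pop1 <- sample_population(spec)
  pop2 <- sample_population(spec)
  expect_equal(length(pop1), 100)
  expect_identical(pop1, pop2)

  pop3 <- sample_population(population_spec(100, c(18, 74),
                                            female_fraction = 0.25,
                                            seed = 43))
  expect_false(identical(pop1, pop3))

  ages <- vapply(pop1, `[[`, 0, "age")
  expect_true(all(ages >= 18 & ages <= 74))

  n_female <- sum(vapply(pop1, `[[`, "", "sex") == "female")
  expect_gte(n_female, qbinom(0.005, 100, 0.25))
  expect_lte(n_female, qbinom(0.995, 100, 0.25))
})

test_that("zero-variance sampling returns the deterministic template", {
  spec <- population_spec(1, c(30, 30), weight_range = c(70, 70),
                          female_fraction = 0, seed = 9, cv = 0)
  ind <- sample_population(spec)[[1]]
  ref <- reference_adult()
  expect_equal(ind$organs$volume_L, ref$organs$volume_L, tolerance = 1e-12)
  expect_equal(ind$organs$flow_L_per_h, ref$organs$flow_L_per_h,
               tolerance = 1e-12)
  expect_equal(ind$gfr, 120, tolerance = 1e-12)
})

test_that("sampled individuals keep flow balance after variability", {
  for (hs in c("healthy", "severe_rf", "pediatric")) {
    ar <- if (hs == "pediatric") c(0.5, 16) else c(18, 74)
    pop <- sample_population(population_spec(8, ar, health_state = hs,
                                             seed = 11))
    for (st in pop) expect_silent(validate_physiology(st))
  }
})

test_that("population spec rejects invalid inputs", {
  expect_error(population_spec(0, c(18, 74)))
  expect_error(population_spec(10, c(18, 74), female_fraction = 1.5))
  expect_error(population_spec(10, c(-5, 10)))
  expect_error(population_spec(10, c(18, 74), weight_range = c(-1, 50)))
})
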