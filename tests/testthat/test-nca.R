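test_that("trapezoid AUC, Cmax and Tmax follow from the grid", {
  tri <- data.frame(time = c(0, 1, 2), conc = c(0, 10, 0))
  nc <- run_nca(tri, dose = 1, route = "iv_bolus")
  expect_equal(nc$auc_0_t, 10)
  expect_equal(nc$cmax, 10)
  expect_equal(nc$tmax, 1)
})

test_that("trapezoid AUC is additive and collinear-point invariant", {
  set.seed(31)
  t <- sort(runif(20, 0, 24))
  c <- exp(-0.1 * t) * 100
  full <- run_nca(data.frame(time = t, conc = c), dose = 1)$auc_0_t
  k <- 10
  left <- trapz_for_test(t[1:k], c[1:k])
  right <- trapz_for_test(t[k:20], c[k:20])
  expect_equal(full, left + right, tolerance = 1e-12)

  # inserting a collinear midpoint does not change the area
  tm <- (t[5] + t[6]) / 2
  cm <- c[5] + (c[6] - c[5]) * (tm - t[5]) / (t[6] - t[5])
  t2 <- append(t, tm, after = 5); c2 <- append(c, cm, after = 5)
  expect_equal(run_nca(data.frame(time = t2, conc = c2), dose = 1)$auc_0_t,
               full, tolerance = 1e-12)
})

test_that("a mono-exponential profile recovers its generating clearance", {
  cl <- 219; v <- 150                   # mL/min, L
  k <- cl * 0.06 / v                    # 1/h
  t <- seq(0, 96, by = 0.25)
  conc <- 2 / v * exp(-k * t) * 1000    # ng/mL for a 2 mg dose
  nc <- run_nca(data.frame(time = t, conc = conc), dose = 2,
                route = "iv_bolus")
  expect_lt(abs(nc$cl - cl) / cl, 0.01)
  expect_lt(abs(nc$t_half - log(2) / k) / (log(2) / k), 0.01)
})

test_that("degenerate profiles are handled explicitly", {
  z <- data.frame(time = 0:10, conc = rep(0, 11))
  nc <- run_nca(z, dose = 1)
  expect_equal(nc$auc_0_t, 0)
  expect_true(is.na(nc$cl))
  expect_true(is.na(nc$auc_0_inf))

  # rising profile: no negative terminal slope
  up <- data.frame(time = 0:10, conc = 1:11)
  nc2 <- run_nca(up, dose = 1)
  expect_true(is.na(nc2$auc_0_inf))
  expect_equal(nc2$auc_0_t, trapz_for_test(0:10, 1:11))

  expect_error(run_nca(data.frame(time = 0:1, conc = c(1, 2)), dose = 1))
  expect_error(run_nca(data.frame(time = 0:3, conc = c(1, -1, 1, 1))))
})

test_that("VPC envelopes respect their ordering invariants", {
  set.seed(7)
  profs <- lapply(1:25, function(i) {
    data.frame(time = 0:10, conc = exp(-0.2 * (0:10)) * rlnorm(1, 0, 0.3) * 100)
  })
  v <- vpc_summary(profs)
  expect_true(all(v$minimum <= v$p5 + 1e-12))
  expect_true(all(v$p5 <= v$p95 + 1e-12))
  expect_true(all(v$p95 <= v$maximum + 1e-12))
  expect_true(all(v$minimum <= v$mean & v$mean <= v$maximum))

  # identical profiles: all five curves coincide
  same <- lapply(1:5, function(i) data.frame(time = 0:5, conc = 6:11))
  vs <- vpc_summary(same)
  expect_equal(vs$minimum, vs$maximum)
  expect_equal(vs$p5, vs$mean)

  # permutation invariance over subjects
  expect_equal(vpc_summary(profs[sample(25)]), v)

  # mismatched grids rejected
  bad <- c(profs[1:3], list(data.frame(time = c(0, 2, 4), conc = c(1, 1, 1))))
  expect_error(vpc_summary(bad))
})

test_that("VPC percentiles match analytic log-normal quantiles", {
  set.seed(12)
  mu <- log(50); sdl <- 0.4
  profs <- lapply(rlnorm(400, mu, sdl), function(x) {
    data.frame(time = c(0, 1, 2), conc = rep(x, 3))
  })
  v <- vpc_summary(profs)
  expect_lt(abs(v$p5[1] - qlnorm(0.05, mu, sdl)) / qlnorm(0.05, mu, sdl), 0.1)
  expect_lt(abs(v$p95[1] - qlnorm(0.95, mu, sdl)) / qlnorm(0.95, mu, sdl), 0.1)
})

test_that("box summaries use interpolated quartiles with min/max whiskers", {
  b <- box_summary(1:9)
  expect_equal(b$median, 5)
  expect_equal(b$q25, 3)
  expect_equal(b$q75, 7)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 9)

  cst <- box_summary(rep(4.2, 10))
  expect_true(all(unlist(cst) == 4.2))

  # brute-force order-statistic oracle (type-7 interpolation)
  set.seed(2)
  x <- rnorm(37)
  s <- sort(x)
  q7 <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  b2 <- box_summary(x)
  expect_equal(b2$median, q7(0.5), tolerance = 1e-12)
  expect_equal(b2$q25, q7(0.25), tolerance = 1e-12)
  expect_equal(b2$q75, q7(0.75), tolerance = 1e-12)

  expect_error(box_summary(numeric(0)))
})

test_that("NCA on the simulated reference adult recovers total clearance", {
  prof <- simulate_model(ref_model(), single_dose("iv_bolus", 2,
                                                  duration = 120))
  nc <- run_nca(prof, dose = 2, route = "iv_bolus")
  expect_lt(abs(nc$cl - 219) / 219, 0.02)
})
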