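# Non-compartmental analysis and population summary envelopes.

profile_xy <- function(profile) {
  if (inherits(profile, "concentration_profile")) {
    list(t = profile$times, c = profile$conc)
  } else if (is.data.frame(profile)) {
    cn <- names(profile)
    tcol <- intersect(c("time", "time_h", "times"), cn)[1]
    ccol <- intersect(c("conc", "conc_ng_per_mL", "concentration"), cn)[1]
    if (is.na(tcol) || is.na(ccol)) {
      nad_stop("profile data frame needs time and concentration columns")
    }
    list(t = profile[[tcol]], c = profile[[ccol]])
  } else {
    nad_stop("profile must be a concentration_profile or a data frame")
  }
}

# Terminal slope: log-linear least squares on the last max(5, points in the
# last 20% of the time span) positive concentrations after Tmax.
terminal_lambda_z <- function(t, c) {
  i_max <- which.max(c)
  span <- max(t) - min(t)
  in_tail <- which(t >= max(t) - 0.2 * span & c > 0 & seq_along(t) > i_max)
  pos_after <- which(c > 0 & seq_along(t) > i_max)
  n_take <- max(5, length(in_tail))
  idx <- utils::tail(pos_after, n_take)
  if (length(idx) < 3) return(NA_real_)
  x <- t[idx]; y <- log(c[idx])
  slope <- stats::cov(x, y) / stats::var(x)
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  -slope
}

#' Non-compartmental analysis of one profile
#'
#' Cmax/Tmax are read off the sampling grid; AUC_0-t uses the linear
#' trapezoid; AUC_0-inf adds `C_last / lambda_z`, with the terminal slope
#' `lambda_z` from log-linear regression over the last 5 points or the
#' points in the last 20 percent of the time span, whichever set is
#' larger. Clearance is `Dose / AUC_0-inf` (apparent CL/F for oral data),
#' converted to mL/min; the half-life is `ln 2 / lambda_z`. When no
#' negative terminal slope can be estimated, AUC_0-inf, CL and t1/2 are
#' returned as `NA` while AUC_0-t is still reported.
#'
#' @param profile A `concentration_profile` or a data frame with time and
#'   concentration columns (h, ng/mL).
#' @param dose Administered dose in mg; defaults to the profile's
#'   regimen total.
#' @param route `"iv_bolus"` or `"oral"` (recorded; oral clearance is the
#'   apparent CL/F).
#' @return A `pk_parameters` list: `cmax` (ng/mL), `tmax` (h), `auc_0_t`,
#'   `auc_0_inf` (ng.h/mL), `cl` (mL/min), `t_half` (h), `lambda_z` (1/h).
#' @examples
#' run_nca(data.frame(time = 0:2, conc = c(0, 10, 0)))$auc_0_t  # 10
#' @export
run_nca <- function(profile, dose = NULL, route = NULL) {
  xy <- profile_xy(profile)
  t <- xy$t; c <- xy$c
  if (length(t) < 3) nad_stop("NCA needs at least 3 time points")
  if (any(c < 0)) nad_stop("concentrations must be non-negative")
  if (is.unsorted(t, strictly = TRUE)) nad_stop("times must be strictly increasing")
  if (is.null(dose) && inherits(profile, "concentration_profile")) {
    dose <- profile$dose_total
  }
  if (is.null(route) && inherits(profile, "concentration_profile")) {
    route <- profile$regimen$events[[1]]$route
  }

  cmax <- max(c)
  tmax <- t[which.max(c)]
  auc_t <- trapz(t, c)

  lambda_z <- if (all(c == 0)) NA_real_ else terminal_lambda_z(t, c)
  c_last <- c[length(c)]
  if (is.na(lambda_z)) {
    auc_inf <- NA_real_
    t_half <- NA_real_
  } else {
    auc_inf <- auc_t + c_last / lambda_z
    t_half <- log(2) / lambda_z
  }
  cl <- if (!is.null(dose) && is.finite(auc_inf) && auc_inf > 0) {
    dose / auc_inf * 1e6 / 60   # mg per ng.h/mL -> mL/min
  } else {
    NA_real_
  }

  structure(
    list(cmax = cmax, tmax = tmax, auc_0_t = auc_t, auc_0_inf = auc_inf,
         cl = cl, t_half = t_half, lambda_z = lambda_z,
         dose = dose, route = route),
    class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf(
    "<pk_parameters> Cmax %.3g ng/mL at %.2g h | AUC0-t %.4g, AUC0-inf %.4g ng.h/mL\n",
    x$cmax, x$tmax, x$auc_0_t, x$auc_0_inf
  ))
  cat(sprintf("  CL %.4g mL/min | t1/2 %.3g h\n", x$cl, x$t_half))
  invisible(x)
}

profiles_matrix <- function(profiles) {
  if (length(profiles) < 2) nad_stop("need at least 2 profiles")
  ts <- lapply(profiles, function(p) profile_xy(p)$t)
  t0 <- ts[[1]]
  same <- vapply(ts, function(t) {
    length(t) == length(t0) && max(abs(t - t0)) <= 1e-9
  }, TRUE)
  if (!all(same)) nad_stop("profiles are not on a common time grid")
  list(t = t0,
       m = vapply(profiles, function(p) profile_xy(p)$c,
                  numeric(length(t0))))
}

#' Visual-predictive-check envelope summary
#'
#' Per output time: arithmetic mean, minimum, maximum, and the 5th and
#' 95th percentiles across subjects (percentiles by linear interpolation
#' between order statistics, `stats::quantile` type 7).
#'
#' @param profiles List of profiles on a common time grid.
#' @return Data frame with columns `time`, `mean`, `minimum`, `maximum`,
#'   `p5`, `p95`.
#' @export
vpc_summary <- function(profiles) {
  pm <- profiles_matrix(profiles)
  q <- t(apply(pm$m, 1, stats::quantile, probs = c(0.05, 0.95),
               type = 7, names = FALSE))
  data.frame(
    time = pm$t,
    mean = rowMeans(pm$m),
    minimum = apply(pm$m, 1, min),
    maximum = apply(pm$m, 1, max),
    p5 = q[, 1],
    p95 = q[, 2]
  )
}

#' Box-plot summary statistics
#'
#' Median and quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7); whiskers are the minimum and maximum of
#' the data, matching the convention of the exposure box plots.
#'
#' @param values Non-empty numeric vector.
#' @return A one-row data frame: `median`, `q25`, `q75`, `whisker_low`,
#'   `whisker_high`.
#' @examples
#' box_summary(1:9)  # median 5, quartiles 3 and 7
#' @export
box_summary <- function(values) {
  if (!length(values) || !is.numeric(values)) {
    nad_stop("values must be a non-empty numeric vector")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(median = q[2], q25 = q[1], q75 = q[3],
             whisker_low = min(values), whisker_high = max(values))
}

#' Mean profile across subjects
#'
#' @param profiles List of profiles on a common grid.
#' @return Data frame with `time` and `conc` (arithmetic mean, ng/mL).
#' @export
mean_profile <- function(profiles) {
  pm <- profiles_matrix(profiles)
  data.frame(time = pm$t, conc = rowMeans(pm$m))
}
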