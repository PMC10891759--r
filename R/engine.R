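# Simulation engine: whole-body perfusion-limited ODE system with IV and
# oral dosing, single and repeated administration.
#
# Topology: venous and arterial blood pools, lung in series, and parallel
# systemic organs. Gut and spleen drain through the portal vein into the
# liver; every other organ returns directly to the venous pool. Oral doses
# pass stomach lumen -> intestinal lumen -> gut tissue (first-order), with
# a competing first-order intestinal transit loss. Renal elimination acts
# on the kidney inflow (arterial) plasma concentration, biliary
# elimination on the liver inflow (portal + arterial mixed) plasma
# concentration; with a conservative lung this makes the IV plasma
# AUC_0-inf equal Dose/CL_T by mass balance, independent of the Kp set.

HCT_REF_FOR_BP <- 0.45

#' A single dose event
#'
#' @param route `"iv_bolus"` or `"oral"`.
#' @param amount Dose in mg, or in mg/kg when `per_kg = TRUE` (resolved
#'   against the simulated individual's body weight).
#' @param time Administration time, h (>= 0).
#' @param per_kg Interpret `amount` as mg/kg.
#' @return A `dose_event`.
#' @export
dose_event <- function(route = c("iv_bolus", "oral"), amount, time = 0,
                       per_kg = FALSE) {
  route <- match.arg(route)
  if (!is.numeric(amount) || amount <= 0) nad_stop("dose amount must be positive")
  if (time < 0) nad_stop("dose time must be non-negative")
  structure(list(route = route, amount = amount, time = time,
                 per_kg = isTRUE(per_kg)),
            class = "dose_event")
}

#' A dosing regimen
#'
#' @param events List of [dose_event()]s with strictly increasing times.
#' @param duration Simulation duration, h; defaults to the last dose time
#'   plus 96 h.
#' @param interval Dosing interval, h, recorded for repeated regimens
#'   (used when summarizing the final dosing interval).
#' @return A `regimen`.
#' @export
regimen <- function(events, duration = NULL, interval = NULL) {
  if (inherits(events, "dose_event")) events <- list(events)
  if (!length(events)) nad_stop("a regimen needs at least one dose event")
  if (!all(vapply(events, inherits, TRUE, "dose_event"))) {
    nad_stop("events must be dose_event objects")
  }
  times <- vapply(events, `[[`, 0, "time")
  if (is.unsorted(times, strictly = TRUE)) {
    nad_stop("dose times must be strictly increasing")
  }
  duration <- duration %||% (max(times) + 96)
  if (duration <= max(times)) nad_stop("duration must extend past the last dose")
  structure(list(events = events, duration = duration, interval = interval),
            class = "regimen")
}

#' Single-dose regimen helper
#' @param route,amount,per_kg Passed to [dose_event()].
#' @param duration Simulation duration, h.
#' @return A `regimen`.
#' @export
single_dose <- function(route, amount, duration = 96, per_kg = FALSE) {
  regimen(list(dose_event(route, amount, 0, per_kg)), duration = duration)
}

#' Repeated-dose regimen helper
#' @param route,amount,per_kg Passed to [dose_event()].
#' @param interval Dosing interval, h.
#' @param n_doses Number of doses.
#' @param duration Simulation duration, h; default runs one full interval
#'   past the last dose.
#' @return A `regimen`.
#' @export
repeated_dose <- function(route, amount, interval = 24, n_doses = 7,
                          duration = NULL, per_kg = FALSE) {
  times <- (seq_len(n_doses) - 1) * interval
  ev <- lapply(times, function(t) dose_event(route, amount, t, per_kg))
  regimen(ev, duration = duration %||% (n_doses * interval),
          interval = interval)
}

#' Simulation settings
#'
#' @param output_grid Optional full output time grid, h (strictly
#'   increasing, starting at 0). When omitted, a grid with step
#'   `grid_step` plus refinement points just after each dose (to resolve
#'   the IV mixing transient for trapezoid integration) is generated.
#' @param grid_step Default grid step, h.
#' @param rtol,atol Solver tolerances.
#' @param seed Optional integer seed recorded with the settings.
#' @return A `simulation_settings` object.
#' @export
simulation_settings <- function(output_grid = NULL, grid_step = 0.1,
                                rtol = 1e-6, atol = 1e-8, seed = NULL) {
  if (rtol <= 0 || atol <= 0) nad_stop("solver tolerances must be positive")
  if (!is.null(output_grid)) {
    if (is.unsorted(output_grid, strictly = TRUE)) {
      nad_stop("output grid must be strictly increasing")
    }
  }
  structure(list(output_grid = output_grid, grid_step = grid_step,
                 rtol = rtol, atol = atol, seed = seed),
            class = "simulation_settings")
}

#' Default output grid for a regimen
#'
#' Uniform grid at `step` over the regimen duration, with geometric
#' refinement points inserted shortly after every dose time so that the
#' fast venous mixing transient after an IV bolus is resolved by
#' trapezoid integration.
#'
#' @param reg A `regimen`.
#' @param step Grid step, h.
#' @return Numeric vector of output times.
#' @export
default_output_grid <- function(reg, step = 0.1) {
  base <- seq(0, reg$duration, by = step)
  refine <- c(0.002, 0.005, 0.01, 0.02, 0.05)
  dose_times <- vapply(reg$events, `[[`, 0, "time")
  extra <- as.vector(outer(refine, dose_times, `+`))
  grid <- sort(unique(c(base, dose_times, extra, reg$duration)))
  grid[grid <= reg$duration]
}

blood_plasma_ratio_at_hct <- function(bp_ref, hct) {
  k_ery <- (bp_ref - (1 - HCT_REF_FOR_BP)) / HCT_REF_FOR_BP
  (1 - hct) + hct * k_ery
}

#' Build the whole-body PBPK model for one individual
#'
#' Assembles the perfusion-limited state vector (stomach and intestinal
#' lumen, venous and arterial blood, lung, and the systemic organs) with
#' the individual's volumes, flows, GFR-scaled renal clearance,
#' allometrically scaled biliary clearance, gastric emptying rate and
#' effective absorption rate.
#'
#' @param individual A `physiology_state`.
#' @param drug A `drug_parameters` object.
#' @return A `pbpk_model`.
#' @export
build_model <- function(individual, drug) {
  validate_physiology(individual)
  org <- individual$organs
  sys <- systemic_organs(org)
  need <- c("gut", "spleen", "kidney", "liver")
  if (!all(need %in% sys$organ)) {
    nad_stop("physiology is missing organs required by the model topology: ",
             paste(setdiff(need, sys$organ), collapse = ", "))
  }
  kp <- partition_coefficients(drug, org)
  bp <- blood_plasma_ratio_at_hct(drug$blood_plasma_ratio,
                                  individual$hematocrit)

  j_gut <- match("gut", sys$organ)
  j_spl <- match("spleen", sys$organ)
  j_kid <- match("kidney", sys$organ)
  j_liv <- match("liver", sys$organ)

  wt_scale <- (individual$body_weight / WT_REF_KG)^ALLOMETRIC_EXP
  cls <- split_clearance(drug)
  clr <- scale_renal_clearance(cls$renal, individual$gfr) * 0.06   # L/h
  clb <- cls$biliary * 0.06 * wt_scale                             # L/h

  ka <- absorption_rate(drug$peff, drug$intestinal_radius) * drug$sa_multiplier

  n_sys <- nrow(sys)
  p <- list(
    n_sys = n_sys,
    i_st = 1L, i_int = 2L, i_ven = 3L, i_art = 4L, i_lung = 5L,
    i_sys = 5L + seq_len(n_sys),
    j_gut = j_gut, j_spl = j_spl, j_kid = j_kid, j_liv = j_liv,
    j_ven_drain = setdiff(seq_len(n_sys), c(j_gut, j_spl, j_liv)),
    V_sys = sys$volume_L,
    Q_sys = sys$flow_L_per_h,
    KpB_sys = unname(kp[sys$organ]) / bp,
    V_ven = org$volume_L[org$organ == "venous_blood"],
    V_art = org$volume_L[org$organ == "arterial_blood"],
    V_lung = org$volume_L[org$organ == "lung"],
    KpB_lung = unname(kp["lung"]) / bp,
    CO = individual$cardiac_output_L_h,
    Q_ha = sys$flow_L_per_h[j_liv],
    Q_gut = sys$flow_L_per_h[j_gut],
    Q_spl = sys$flow_L_per_h[j_spl],
    CLr = clr, CLb = clb, BP = bp,
    kge = log(2) / (individual$gastric_emptying_min / 60),
    ka = ka,
    kloss = log(2) / drug$transit_half_life,
    body_weight = individual$body_weight
  )
  p$Q_liv_tot <- p$Q_ha + p$Q_gut + p$Q_spl

  state_names <- c("stomach", "intestine", "venous", "arterial", "lung",
                   sys$organ, "elim_renal", "elim_biliary", "lumen_loss")
  structure(list(params = p, state_names = state_names,
                 individual = individual, drug = drug),
            class = "pbpk_model")
}

pbpk_deriv <- function(t, y, p) {
  C_sys_out <- y[p$i_sys] / p$V_sys / p$KpB_sys
  C_ven <- y[p$i_ven] / p$V_ven
  C_art <- y[p$i_art] / p$V_art
  C_lung_out <- y[p$i_lung] / p$V_lung / p$KpB_lung

  renal <- p$CLr * C_art / p$BP
  C_liv_in <- (p$Q_ha * C_art + p$Q_gut * C_sys_out[p$j_gut] +
                 p$Q_spl * C_sys_out[p$j_spl]) / p$Q_liv_tot
  bil <- p$CLb * C_liv_in / p$BP
  absorbed <- p$ka * y[p$i_int]

  d_sys <- p$Q_sys * (C_art - C_sys_out)
  d_sys[p$j_kid] <- d_sys[p$j_kid] - renal
  d_sys[p$j_liv] <- p$Q_ha * C_art + p$Q_gut * C_sys_out[p$j_gut] +
    p$Q_spl * C_sys_out[p$j_spl] - p$Q_liv_tot * C_sys_out[p$j_liv] - bil
  d_sys[p$j_gut] <- d_sys[p$j_gut] + absorbed

  d_st <- -p$kge * y[p$i_st]
  d_int <- p$kge * y[p$i_st] - (p$ka + p$kloss) * y[p$i_int]

  ven_in <- sum(p$Q_sys[p$j_ven_drain] * C_sys_out[p$j_ven_drain]) +
    p$Q_liv_tot * C_sys_out[p$j_liv]

  list(c(d_st, d_int,
         ven_in - p$CO * C_ven,
         p$CO * (C_lung_out - C_art),
         p$CO * (C_ven - C_lung_out),
         d_sys,
         renal, bil, p$kloss * y[p$i_int]))
}

resolve_events <- function(reg, body_weight) {
  data.frame(
    var = vapply(reg$events, function(e) {
      if (e$route == "iv_bolus") "venous" else "stomach"
    }, ""),
    time = vapply(reg$events, `[[`, 0, "time"),
    value = vapply(reg$events, function(e) {
      if (e$per_kg) e$amount * body_weight else e$amount
    }, 0),
    method = "add",
    stringsAsFactors = FALSE
  )
}

#' Simulate a concentration-time profile
#'
#' Integrates the whole-body system with `deSolve::lsoda` (stiff-capable)
#' over the requested output grid, applying doses as instantaneous events
#' (IV bolus into the venous pool, oral into the stomach lumen). The
#' reported quantity is the venous plasma concentration in ng/mL (blood
#' concentration divided by the hematocrit-dependent blood-to-plasma
#' ratio).
#'
#' @param model A `pbpk_model` from [build_model()].
#' @param reg A `regimen`.
#' @param settings A `simulation_settings` object.
#' @param keep_states Also return the full compartment amount matrix
#'   (element `states`).
#' @return A `concentration_profile`: list with `times` (h), `conc`
#'   (ng/mL), the regimen, the administered total dose (mg), a mass
#'   balance data frame and compartment bookkeeping.
#' @examples
#' \donttest{
#' mod <- build_model(reference_adult(), nadolol_parameters())
#' prof <- simulate_model(mod, single_dose("iv_bolus", 2))
#' max(prof$conc)
#' }
#' @export
simulate_model <- function(model, reg, settings = simulation_settings(),
                           keep_states = FALSE) {
  stopifnot(inherits(model, "pbpk_model"), inherits(reg, "regimen"))
  p <- model$params
  ev <- resolve_events(reg, p$body_weight)
  grid <- settings$output_grid %||% default_output_grid(reg, settings$grid_step)
  times <- sort(unique(c(grid, ev$time)))
  y0 <- stats::setNames(numeric(length(model$state_names)),
                        model$state_names)
  sol <- try(deSolve::lsoda(
    y = y0, times = times, func = pbpk_deriv, parms = p,
    events = list(data = ev), rtol = settings$rtol, atol = settings$atol,
    maxsteps = 50000
  ), silent = TRUE)
  if (inherits(sol, "try-error") ||
      nrow(sol) < length(times) || any(!is.finite(sol[, "venous"]))) {
    nad_stop("ODE solver failed for subject ",
             model$individual$subject_id %||% "(template)",
             ": ", if (inherits(sol, "try-error")) attr(sol, "condition")$message
                   else "incomplete or non-finite solution",
             class = "nadpbpk_solver_error")
  }
  sol <- as.data.frame(sol)
  keep <- sol$time %in% grid
  sol <- sol[keep, , drop = FALSE]

  conc <- sol$venous / p$V_ven / p$BP * 1000  # mg/L -> ng/mL
  body_cols <- setdiff(model$state_names,
                       c("elim_renal", "elim_biliary", "lumen_loss"))
  total <- rowSums(sol[, body_cols, drop = FALSE]) +
    sol$elim_renal + sol$elim_biliary + sol$lumen_loss
  administered <- vapply(sol$time, function(t) {
    sum(ev$value[ev$time < t - 1e-12])
  }, 0)
  # at (and before) a dose instant the event is not yet in the state
  rel_err <- ifelse(administered > 0,
                    (total - administered) / administered, 0)

  structure(
    list(times = sol$time, conc = pmax(conc, 0), regimen = reg,
         subject_id = model$individual$subject_id %||% NA_integer_,
         dose_total = sum(ev$value),
         mass_balance = data.frame(time = sol$time, in_system = total,
                                   administered = administered,
                                   rel_error = rel_err),
         eliminated = data.frame(time = sol$time,
                                 renal = sol$elim_renal,
                                 biliary = sol$elim_biliary,
                                 lumen_loss = sol$lumen_loss),
         lumen = data.frame(time = sol$time, stomach = sol$stomach,
                            intestine = sol$intestine),
         states = if (keep_states) sol else NULL),
    class = "concentration_profile"
  )
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, time_h = x$times,
             conc_ng_per_mL = x$conc)
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf(
    "<concentration_profile> subject %s: %d points over %.1f h, Cmax %.3g ng/mL\n",
    as.character(x$subject_id), length(x$times), max(x$times), max(x$conc)
  ))
  invisible(x)
}

#' Simulate a virtual population
#'
#' One profile per individual, in input order; results are independent of
#' execution order. Per-subject solver failures are reported with the
#' subject id.
#'
#' @param individuals List of `physiology_state` objects (e.g. from
#'   [sample_population()]).
#' @param drug A `drug_parameters` object.
#' @param reg A `regimen`.
#' @param settings A `simulation_settings` object.
#' @return List of `concentration_profile`s.
#' @export
simulate_population <- function(individuals, drug, reg,
                                settings = simulation_settings()) {
  if (!length(individuals)) nad_stop("population is empty")
  lapply(seq_along(individuals), function(i) {
    ind <- individuals[[i]]
    if (is.null(ind$subject_id)) ind$subject_id <- i
    tryCatch(
      simulate_model(build_model(ind, drug), reg, settings),
      error = function(e) {
        nad_stop("simulation failed for subject ", ind$subject_id, ": ",
                 conditionMessage(e), class = "nadpbpk_solver_error")
      }
    )
  })
}

#' Tidy profile table for a set of subjects
#'
#' @param profiles List of `concentration_profile`s.
#' @return Data frame with `subject_id`, `time_h`, `conc_ng_per_mL`.
#' @export
profiles_to_data_frame <- function(profiles) {
  do.call(rbind, lapply(profiles, as.data.frame))
}
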