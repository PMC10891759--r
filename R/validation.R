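# Model-qualification statistics and the packaged in-study observed data:
# predicted/observed ratios, average fold error (AFE), twofold criterion,
# and the simulation pipeline that re-predicts every published study arm.

#' Packaged observed/predicted PK parameter table
#'
#' The printed predicted and observed Cmax (ng/mL), AUC_0-t (ng.h/mL) and
#' CL cells per study arm in the healthy IV, healthy oral, pediatric IV
#' and pediatric oral blocks, together with the demographics needed to
#' re-simulate each arm (participants, female fraction, age and weight
#' ranges, fixed pediatric age). Observed CL is carried as printed,
#' without unit conversion (the oral-block CL unit convention is
#' inconsistent and is treated as opaque).
#'
#' @param table1_only Keep only arms with printed predicted/observed
#'   cells (drops the extra study arms carried for scenario listing).
#' @return A data frame.
#' @export
observed_pk_table <- function(table1_only = TRUE) {
  tab <- read_extdata_csv("observed_pk_table.csv")
  if (table1_only) tab <- tab[tab$in_table1 == 1, , drop = FALSE]
  tab
}

#' Packaged AFE reference table
#'
#' Printed average-fold-error values per parameter and population block.
#'
#' @return A data frame with `group`, `parameter`, `afe`.
#' @export
afe_reference_table <- function() {
  read_extdata_csv("afe_reference.csv")
}

#' Predicted-to-observed ratio
#'
#' `R = predicted / observed`; full precision is retained (table output
#' rounds to two decimals).
#'
#' @param predicted,observed Positive numerics (vectorized).
#' @return The ratio(s).
#' @examples
#' round(pred_obs_ratio(104, 81), 2)  # 1.28
#' @export
pred_obs_ratio <- function(predicted, observed) {
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    nad_stop("observed values must be positive")
  }
  predicted / observed
}

#' Average fold error
#'
#' `AFE = 10^(mean(log10(R)))` over predicted/observed ratios -- the
#' geometric mean of the ratios; 1.0 indicates no average bias and the
#' statistic is reciprocal-symmetric (a 2x over- and a 2x under-prediction
#' cancel).
#'
#' @param ratios Positive ratios.
#' @return The AFE.
#' @examples
#' round(afe(c(0.99, 0.94, 1.04, 0.96)), 2)  # 0.98
#' @export
afe <- function(ratios) {
  if (!length(ratios)) nad_stop("afe needs at least one ratio")
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    nad_stop("ratios must be positive and finite")
  }
  10^mean(log10(ratios))
}

#' Twofold acceptance check
#'
#' Flags each ratio against the twofold criterion (0.5 <= R <= 2, closed
#' interval) and reports the symmetric fold error `max(R, 1/R)` plus the
#' aggregate pass fraction.
#'
#' @param ratios Positive ratios.
#' @return List with `table` (ratio, fold_error, within_twofold),
#'   `pass_fraction` and `max_fold_error`.
#' @examples
#' twofold_check(c(1.28, 0.14))$pass_fraction  # 0.5
#' @export
twofold_check <- function(ratios) {
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    nad_stop("ratios must be positive and finite")
  }
  fe <- pmax(ratios, 1 / ratios)
  ok <- ratios >= 0.5 & ratios <= 2
  list(
    table = data.frame(ratio = ratios, fold_error = fe, within_twofold = ok),
    pass_fraction = mean(ok),
    max_fold_error = max(fe)
  )
}

#' Qualification report from predicted and observed tables
#'
#' Joins predicted and observed values on (block, row, parameter), emits
#' the per-cell ratio table with twofold flags, and the AFE per
#' population block and parameter. Unmatched keys raise an error naming
#' them rather than being dropped silently.
#'
#' @param predicted Data frame with `block`, `row`, `parameter`,
#'   `predicted`.
#' @param observed Data frame with `block`, `row`, `parameter`,
#'   `observed`.
#' @return A `qualification_report`: list with `ratio_table` and
#'   `afe_table`.
#' @export
qualification_report <- function(predicted, observed) {
  need_p <- c("block", "row", "parameter", "predicted")
  need_o <- c("block", "row", "parameter", "observed")
  if (!all(need_p %in% names(predicted)) || !all(need_o %in% names(observed))) {
    nad_stop("predicted/observed tables lack the required key columns")
  }
  key <- function(d) paste(d$block, d$row, d$parameter, sep = "/")
  kp <- key(predicted); ko <- key(observed)
  if (!length(intersect(kp, ko))) {
    nad_stop("no matching keys between predicted and observed tables; ",
             "predicted keys: ", paste(utils::head(kp, 5), collapse = ", "),
             " ... observed keys: ", paste(utils::head(ko, 5), collapse = ", "))
  }
  miss_p <- setdiff(ko, kp); miss_o <- setdiff(kp, ko)
  if (length(miss_p) || length(miss_o)) {
    nad_stop("unmatched keys -- missing predictions: ",
             paste(miss_p, collapse = ", "),
             "; missing observations: ",
             paste(miss_o, collapse = ", "))
  }
  m <- merge(predicted[need_p], observed[need_o],
             by = c("block", "row", "parameter"))
  m <- m[order(m$block, m$row, m$parameter), , drop = FALSE]
  m$ratio <- pred_obs_ratio(m$predicted, m$observed)
  m$within_twofold <- m$ratio >= 0.5 & m$ratio <= 2

  groups <- split(m, list(m$block, m$parameter), drop = TRUE)
  afe_table <- do.call(rbind, lapply(groups, function(g) {
    data.frame(block = g$block[1], parameter = g$parameter[1],
               n = nrow(g), afe = afe(g$ratio),
               pass_fraction = mean(g$within_twofold))
  }))
  rownames(afe_table) <- NULL
  structure(list(ratio_table = m, afe_table = afe_table),
            class = "qualification_report")
}

#' @export
print.qualification_report <- function(x, ...) {
  cat("<qualification_report>\n")
  cat(sprintf("  %d cells, %.0f%% within twofold\n",
              nrow(x$ratio_table), 100 * mean(x$ratio_table$within_twofold)))
  print(x$afe_table, digits = 3)
  invisible(x)
}

#' Recompute the printed ratio arithmetic
#'
#' Recomputes R = predicted/observed from the packaged printed cells and
#' compares against the printed ratios, flagging cells whose printed
#' value differs from the recomputed one by more than 0.01 (several
#' printed cells are truncated rather than rounded).
#'
#' @return Data frame with one row per (arm, parameter) cell.
#' @export
table_ratio_check <- function() {
  tab <- observed_pk_table()
  cells <- lapply(c("cmax", "auc", "cl"), function(par) {
    data.frame(
      block = tab$block, row = tab$row, parameter = par,
      predicted = tab[[paste0("pred_", par)]],
      observed = tab[[paste0("obs_", par)]],
      printed_ratio = tab[[paste0("r_", par)]]
    )
  })
  out <- do.call(rbind, cells)
  out$recomputed <- pred_obs_ratio(out$predicted, out$observed)
  # a printed cell "agrees" when either rounding or truncation of the
  # recomputed ratio to two decimals reproduces it
  rounded <- round(out$recomputed, 2)
  truncated <- trunc(out$recomputed * 100 + 1e-9) / 100
  out$discrepant <- abs(rounded - out$printed_ratio) > 1e-9 &
    abs(truncated - out$printed_ratio) > 1e-9
  out
}

# ---- simulation-based qualification -------------------------------------

# Fixed per-route sampling schedules standing in for the unpublished
# digitized study designs.
sampling_schedule <- function(block, steady_state = FALSE) {
  sched <- switch(block,
    iv_healthy = c(0.033, 0.083, 0.167, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8,
                   12, 16, 24, 36, 48),
    oral_healthy = c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48, 72),
    iv_pediatric = c(0.033, 0.083, 0.167, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 12,
                     24, 36, 48),
    oral_pediatric = c(0.5, 1, 2, 3, 4, 6, 8, 12, 24, 36, 48),
    ckd = c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48, 72, 96),
    nad_stop("unknown study block: ", block)
  )
  if (steady_state) sched <- sched[sched <= 24]
  sched
}

arm_population_spec <- function(arm, n, seed) {
  if (!is.na(arm$sim_age_months)) {
    age <- arm$sim_age_months / 12
    population_spec(
      n = n, age_range = c(age, age),
      female_fraction = arm$female_frac,
      health_state = "pediatric", seed = seed
    )
  } else {
    health <- if (identical(arm$block, "ckd")) "moderate_rf" else "healthy"
    wr <- if (is.na(arm$wt_lo)) NULL else c(arm$wt_lo, arm$wt_hi)
    population_spec(
      n = n, age_range = c(arm$age_lo, arm$age_hi), weight_range = wr,
      female_fraction = arm$female_frac, health_state = health, seed = seed
    )
  }
}

#' Re-predict one published study arm
#'
#' Samples a virtual population matching the arm's demographics, simulates
#' the arm's regimen (single dose, or seven once-daily doses for the
#' steady-state arm, analyzed over the final interval), and runs NCA on
#' the arithmetic mean profile evaluated at the arm's sampling schedule.
#'
#' @param arm One row of [observed_pk_table()].
#' @param drug Drug parameters (default nadolol).
#' @param n Virtual population size (default 100).
#' @param seed Integer seed.
#' @return List with the predicted `pk_parameters`, the per-subject AUCs,
#'   and the mean profile.
#' @export
simulate_study_arm <- function(arm, drug = nadolol_parameters(), n = 100,
                               seed = 1) {
  if (is.data.frame(arm)) arm <- as.list(arm[1, ])
  route <- if (startsWith(arm$block, "iv")) "iv_bolus" else "oral"
  ss <- isTRUE(arm$steady_state == 1)
  sched <- sampling_schedule(arm$block, ss)
  per_kg <- isTRUE(arm$per_kg == 1)

  if (ss) {
    n_doses <- 7
    reg <- repeated_dose(route, arm$dose_mg, interval = 24,
                         n_doses = n_doses, per_kg = per_kg,
                         duration = n_doses * 24)
    offset <- (n_doses - 1) * 24
  } else {
    reg <- regimen(list(dose_event(route, arm$dose_mg, 0, per_kg)),
                   duration = max(sched))
    offset <- 0
  }
  grid <- sort(unique(c(default_output_grid(reg), offset + sched)))
  settings <- simulation_settings(output_grid = grid)

  pop <- sample_population(arm_population_spec(arm, n, seed))
  profiles <- simulate_population(pop, drug, reg, settings)

  mp <- mean_profile(profiles)
  sel <- mp$time %in% (offset + sched)
  obs_grid <- data.frame(time = mp$time[sel] - offset, conc = mp$conc[sel])

  mean_wt <- mean(vapply(pop, `[[`, 0, "body_weight"))
  dose_abs <- if (per_kg) arm$dose_mg * mean_wt else arm$dose_mg
  nca <- run_nca(obs_grid, dose = dose_abs, route = route)

  subject_auc <- vapply(profiles, function(p) {
    sel_i <- p$times %in% (offset + sched)
    trapz(p$times[sel_i], p$conc[sel_i])
  }, 0)

  list(nca = nca, mean_profile = obs_grid, subject_auc = subject_auc,
       schedule = sched, dose_mg = dose_abs, route = route)
}

#' Simulation-based model qualification against the published arms
#'
#' Re-predicts every packaged study arm with virtual populations and
#' compares predicted Cmax and AUC_0-t (and, for the IV blocks, CL)
#' against the printed observed values via the ratio / AFE / twofold
#' statistics. Oral CL is excluded from the numeric comparison because
#' the printed oral CL units are not internally consistent.
#'
#' @param drug Drug parameters (default nadolol).
#' @param n Virtual population size per arm (default 100).
#' @param seed Integer seed.
#' @param blocks Blocks to include (default all four printed blocks).
#' @return A `qualification_report` with the per-arm predictions attached
#'   as attribute `predictions`.
#' @export
qualify_model <- function(drug = nadolol_parameters(), n = 100, seed = 1,
                          blocks = c("iv_healthy", "oral_healthy",
                                     "iv_pediatric", "oral_pediatric")) {
  tab <- observed_pk_table()
  tab <- tab[tab$block %in% blocks, , drop = FALSE]
  preds <- vector("list", nrow(tab))
  rows <- vector("list", nrow(tab))
  obs_rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    arm <- as.list(tab[i, ])
    sim <- simulate_study_arm(arm, drug = drug, n = n, seed = seed + i)
    preds[[i]] <- sim
    iv <- startsWith(arm$block, "iv")
    pars <- c("cmax", "auc", if (iv) "cl")
    pred_vals <- c(cmax = sim$nca$cmax, auc = sim$nca$auc_0_t,
                   cl = if (iv) sim$nca$cl * 0.06 else NA)  # CL in L/h
    obs_vals <- c(cmax = arm$obs_cmax, auc = arm$obs_auc,
                  cl = if (iv) arm$obs_cl else NA)
    rows[[i]] <- data.frame(block = arm$block, row = arm$row,
                            parameter = pars,
                            predicted = unname(pred_vals[pars]))
    obs_rows[[i]] <- data.frame(block = arm$block, row = arm$row,
                                parameter = pars,
                                observed = unname(obs_vals[pars]))
  }
  predicted <- do.call(rbind, rows)
  observed <- do.call(rbind, obs_rows)
  rep <- qualification_report(predicted, observed)
  attr(rep, "predictions") <- preds
  rep
}

#' Write a qualification report to CSV files
#'
#' @param report A `qualification_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_qualification_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$ratio_table,
                   file.path(dir, "ratio_table.csv"), row.names = FALSE)
  utils::write.csv(report$afe_table,
                   file.path(dir, "afe_table.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pass_fraction = mean(report$ratio_table$within_twofold),
         n_cells = nrow(report$ratio_table)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
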