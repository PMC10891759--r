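# Scenario runner: end-to-end workflows (population -> simulation -> NCA /
# VPC / box statistics / qualification) driven by JSON configuration
# documents, reproducing the study designs from config alone.

SCENARIO_OUTPUTS <- c("profiles", "nca", "vpc", "box", "qualification")

scenario_dir <- function() {
  system.file("scenarios", package = "nadpbpk")
}

#' List packaged scenarios
#'
#' Enumerates the packaged JSON scenario configurations plus one scenario
#' per packaged published study arm (re-simulation of that arm's regimen
#' and demographics).
#'
#' @return Data frame with `name` and `source` (`"config"` or
#'   `"study_arm"`).
#' @export
list_scenarios <- function() {
  files <- list.files(scenario_dir(), pattern = "\\.json$")
  cfg <- data.frame(name = sub("\\.json$", "", files), source = "config")
  tab <- read_extdata_csv("observed_pk_table.csv")
  arms <- data.frame(
    name = sprintf("study_%s_%d_%s", tab$block, tab$row, tab$ref),
    source = "study_arm"
  )
  rbind(cfg, arms)
}

check_field <- function(doc, path, type, errors, optional = FALSE,
                        choices = NULL) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  val <- doc
  for (p in parts) {
    val <- if (is.list(val) && !is.null(names(val))) val[[p]] else NULL
    if (is.null(val)) break
  }
  # JSON parsed without simplification yields scalars/arrays as lists
  if (!is.null(val) && is.list(val) && type != "list") val <- unlist(val)
  if (is.null(val)) {
    if (!optional) errors <- c(errors, paste0(path, ": missing"))
    return(errors)
  }
  ok <- switch(type,
               character = is.character(val),
               numeric = is.numeric(val),
               list = is.list(val),
               logical = is.logical(val))
  if (!ok) {
    errors <- c(errors, paste0(path, ": expected ", type))
  } else if (!is.null(choices) && !all(val %in% choices)) {
    errors <- c(errors, paste0(path, ": must be one of ",
                               paste(choices, collapse = ", ")))
  }
  errors
}

#' Validate a scenario configuration
#'
#' Dry-run schema validation (no simulation): checks required fields and
#' types, reporting violations with their field paths.
#'
#' @param doc A scenario config (list, JSON string, or file path).
#' @return List with `valid` (logical) and `errors` (character vector of
#'   field-path messages).
#' @export
validate_config <- function(doc) {
  if (is.character(doc)) {
    doc <- if (file.exists(doc)) {
      jsonlite::read_json(doc, simplifyVector = FALSE)
    } else {
      jsonlite::fromJSON(doc, simplifyVector = FALSE)
    }
  }
  errors <- character()
  errors <- check_field(doc, "name", "character", errors)
  errors <- check_field(doc, "seed", "numeric", errors, optional = TRUE)
  errors <- check_field(doc, "outputs", "character", errors,
                        choices = SCENARIO_OUTPUTS)
  if (is.null(doc$groups) || !length(doc$groups)) {
    errors <- c(errors, "groups: missing or empty")
  } else {
    for (i in seq_along(doc$groups)) {
      g <- doc$groups[[i]]
      pre <- sprintf("groups[%d].", i)
      e2 <- character()
      e2 <- check_field(g, "label", "character", e2)
      e2 <- check_field(g, "population", "list", e2)
      e2 <- check_field(g, "regimen", "list", e2)
      if (!is.null(g$population)) {
        e2 <- check_field(g$population, "n", "numeric", e2)
        e2 <- check_field(g$population, "health_state", "character", e2,
                          choices = c("healthy", "moderate_rf",
                                      "severe_rf", "pediatric"))
        e2 <- check_field(g$population, "age_range", "numeric", e2)
        e2 <- check_field(g$population, "female_fraction", "numeric", e2,
                          optional = TRUE)
        e2 <- check_field(g$population, "weight_range", "numeric", e2,
                          optional = TRUE)
      }
      if (!is.null(g$regimen)) {
        e2 <- check_field(g$regimen, "route", "character", e2,
                          choices = c("iv_bolus", "oral"))
        e2 <- check_field(g$regimen, "amount_mg", "numeric", e2)
        e2 <- check_field(g$regimen, "interval_h", "numeric", e2,
                          optional = TRUE)
        e2 <- check_field(g$regimen, "n_doses", "numeric", e2,
                          optional = TRUE)
        e2 <- check_field(g$regimen, "duration_h", "numeric", e2,
                          optional = TRUE)
      }
      errors <- c(errors, if (length(e2)) paste0(pre, e2))
    }
  }
  list(valid = !length(errors), errors = errors)
}

group_regimen <- function(rg) {
  per_kg <- isTRUE(rg$per_kg)
  n_doses <- rg$n_doses %||% 1
  if (n_doses > 1) {
    repeated_dose(rg$route, rg$amount_mg, interval = rg$interval_h %||% 24,
                  n_doses = n_doses, per_kg = per_kg,
                  duration = rg$duration_h %||% NULL)
  } else {
    single_dose(rg$route, rg$amount_mg,
                duration = rg$duration_h %||% 96, per_kg = per_kg)
  }
}

group_population <- function(pg, seed, n_override = NULL) {
  population_spec(
    n = n_override %||% pg$n,
    age_range = unlist(pg$age_range),
    weight_range = if (is.null(pg$weight_range)) NULL
                   else unlist(pg$weight_range),
    female_fraction = pg$female_fraction %||% 0,
    health_state = pg$health_state %||% "healthy",
    seed = seed,
    cv = pg$cv %||% 0.16
  )
}

resolve_scenario <- function(name_or_doc) {
  if (is.list(name_or_doc)) return(name_or_doc)
  if (file.exists(name_or_doc)) {
    return(jsonlite::read_json(name_or_doc, simplifyVector = FALSE))
  }
  packaged <- file.path(scenario_dir(), paste0(name_or_doc, ".json"))
  if (file.exists(packaged)) {
    return(jsonlite::read_json(packaged, simplifyVector = FALSE))
  }
  if (startsWith(name_or_doc, "study_")) {
    return(study_arm_config(name_or_doc))
  }
  nad_stop("unknown scenario: ", name_or_doc)
}

study_arm_config <- function(name) {
  tab <- read_extdata_csv("observed_pk_table.csv")
  key <- sprintf("study_%s_%d_%s", tab$block, tab$row, tab$ref)
  i <- match(name, key)
  if (is.na(i)) nad_stop("unknown study-arm scenario: ", name)
  arm <- as.list(tab[i, ])
  route <- if (startsWith(arm$block, "iv")) "iv_bolus" else "oral"
  pop <- if (!is.na(arm$sim_age_months)) {
    list(n = 100, health_state = "pediatric",
         age_range = rep(arm$sim_age_months / 12, 2),
         female_fraction = arm$female_frac)
  } else {
    list(n = 100,
         health_state = if (identical(arm$block, "ckd")) "moderate_rf"
                        else "healthy",
         age_range = c(arm$age_lo %||% 20, arm$age_hi %||% 40),
         weight_range = if (is.na(arm$wt_lo)) NULL
                        else c(arm$wt_lo, arm$wt_hi),
         female_fraction = arm$female_frac)
  }
  if (!is.null(pop$age_range) && anyNA(pop$age_range)) {
    pop$age_range <- c(20, 40)
  }
  rgm <- list(route = route, amount_mg = arm$dose_mg,
              per_kg = arm$per_kg == 1, duration_h = 96)
  if (arm$steady_state == 1) {
    rgm$n_doses <- 7; rgm$interval_h <- 24; rgm$duration_h <- NULL
  }
  list(name = name, seed = 1, outputs = list("profiles", "nca", "vpc"),
       groups = list(list(label = name, population = pop, regimen = rgm)))
}

scenario_group_auc <- function(profiles, reg) {
  vapply(profiles, function(p) {
    t <- p$times; c <- p$conc
    if (!is.null(reg$interval) && length(reg$events) > 1) {
      # exposure over the final dosing interval
      t0 <- reg$events[[length(reg$events)]]$time
      sel <- t >= t0
      trapz(t[sel], c[sel])
    } else {
      trapz(t, c)
    }
  }, 0)
}

#' Run a scenario end to end
#'
#' Resolves a scenario (packaged name, study-arm name, file path, or
#' config list), validates it, samples each group's population, simulates
#' the regimen, and writes the requested outputs as tidy CSV plus a JSON
#' run log (inputs, seed, package version) to `out_dir`. Deterministic
#' given the seed.
#'
#' @param scenario Scenario name, path, or config list.
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   writing and only returns results.
#' @param seed Optional seed override.
#' @param n Optional population-size override applied to every group.
#' @param drug Drug parameters (default nadolol).
#' @return Invisibly, a list with per-group profiles, NCA tables, box
#'   statistics and VPC summaries.
#' @export
run_scenario <- function(scenario, out_dir = NULL, seed = NULL, n = NULL,
                         drug = nadolol_parameters()) {
  doc <- resolve_scenario(scenario)
  chk <- validate_config(doc)
  if (!chk$valid) {
    nad_stop("invalid scenario config:\n  ",
             paste(chk$errors, collapse = "\n  "),
             class = "nadpbpk_config_error")
  }
  seed <- seed %||% (doc$seed %||% 1)
  outputs <- unlist(doc$outputs)

  results <- list()
  for (gi in seq_along(doc$groups)) {
    g <- doc$groups[[gi]]
    reg <- group_regimen(g$regimen)
    spec <- group_population(g$population, seed = seed + gi - 1,
                             n_override = n)
    pop <- sample_population(spec)
    profiles <- simulate_population(pop, drug, reg, simulation_settings())
    auc <- scenario_group_auc(profiles, reg)
    nca_tab <- do.call(rbind, lapply(profiles, function(p) {
      nc <- run_nca(p)
      data.frame(subject_id = p$subject_id, cmax = nc$cmax, tmax = nc$tmax,
                 auc_0_t = nc$auc_0_t, auc_0_inf = nc$auc_0_inf,
                 cl = nc$cl, t_half = nc$t_half)
    }))
    results[[g$label]] <- list(
      label = g$label, profiles = profiles, nca = nca_tab,
      auc = auc, box = box_summary(auc),
      vpc = if (length(profiles) >= 2) vpc_summary(profiles) else NULL,
      max_mass_balance_error =
        max(vapply(profiles,
                   function(p) max(abs(p$mass_balance$rel_error)), 0))
    )
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if ("profiles" %in% outputs) {
      prof <- do.call(rbind, lapply(results, function(r) {
        cbind(group = r$label, profiles_to_data_frame(r$profiles))
      }))
      utils::write.csv(prof, file.path(out_dir, "profiles.csv"),
                       row.names = FALSE)
    }
    if ("nca" %in% outputs) {
      nca_all <- do.call(rbind, lapply(results, function(r) {
        cbind(group = r$label, r$nca)
      }))
      utils::write.csv(nca_all, file.path(out_dir, "nca.csv"),
                       row.names = FALSE)
    }
    if ("vpc" %in% outputs) {
      vpc_all <- do.call(rbind, lapply(results, function(r) {
        if (is.null(r$vpc)) return(NULL)
        long <- stats::reshape(
          r$vpc, direction = "long",
          varying = c("mean", "minimum", "maximum", "p5", "p95"),
          v.names = "value", timevar = "stat",
          times = c("mean", "minimum", "maximum", "p5", "p95")
        )
        data.frame(group = r$label, time = long$time, stat = long$stat,
                   value = long$value)
      }))
      utils::write.csv(vpc_all, file.path(out_dir, "vpc.csv"),
                       row.names = FALSE)
    }
    if ("box" %in% outputs) {
      box_all <- do.call(rbind, lapply(results, function(r) {
        cbind(group = r$label, r$box)
      }))
      utils::write.csv(box_all, file.path(out_dir, "box.csv"),
                       row.names = FALSE)
    }
    log <- list(
      scenario = doc$name, seed = seed,
      n_override = n, groups = vapply(doc$groups, `[[`, "", "label"),
      package_version = as.character(utils::packageVersion("nadpbpk")),
      r_version = R.version.string,
      max_mass_balance_error =
        max(vapply(results, `[[`, 0, "max_mass_balance_error")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}
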