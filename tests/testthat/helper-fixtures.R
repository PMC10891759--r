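# Shared fixtures: cheap settings and small deterministic populations.

fast_settings <- function(duration = 96, step = 0.2) {
  simulation_settings(grid_step = step)
}

# Reference adult model with the packaged nadolol parameters.
ref_model <- function(drug = nadolol_parameters()) {
  build_model(reference_adult(), drug)
}

# A drug with (numerically) zero clearance for conservation/equilibrium
# tests, optionally with every partition coefficient pinned to 1.
inert_drug <- function(unit_kp = FALSE) {
  d <- nadolol_parameters()
  d$clr_ref <- 0
  d$clt_ref <- 1e-9
  if (unit_kp) {
    orgs <- organ_reference_table()$organ
    d$kp_overrides <- stats::setNames(rep(1, length(orgs)), orgs)
    d$fu <- 1
    d$logp <- 0
  }
  d
}

# Independent trapezoid oracle used against the package's own AUC paths.
trapz_for_test <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Reference adult with GFR overridden (other fields untouched).
adult_with_gfr <- function(gfr) {
  st <- reference_adult()
  st$gfr <- gfr
  st
}
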