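# Physiology module: reference adult, renal-failure scaling, pediatric
# age scaling, and seeded virtual-population sampling.
#
# Units follow field convention: organ volumes L, blood flows L/h,
# GFR mL/min, gastric emptying time min, age years, weight kg, height cm.

GFR_REF_ML_MIN <- 120     # healthy adult reference GFR
WT_REF_KG <- 70           # reference adult body weight
HCT_REF_MALE <- 0.45
HCT_REF_FEMALE <- 0.41
GET_REF_MIN <- 15         # reference gastric emptying time
GFR_TM50_WEEKS <- 47.7    # postmenstrual age of half-mature GFR
GFR_HILL <- 3.4           # Hill coefficient of the maturation sigmoid
WEEKS_PER_YEAR <- 52.1775
ALLOMETRIC_EXP <- 0.75

BLOOD_POOLS <- c("venous_blood", "arterial_blood")

.nad_cache <- new.env(parent = emptyenv())

organ_reference_cached <- function() {
  if (is.null(.nad_cache$organs)) {
    .nad_cache$organs <- read_extdata_csv("organs_reference.csv")
  }
  .nad_cache$organs
}

growth_reference_cached <- function() {
  if (is.null(.nad_cache$growth)) {
    .nad_cache$growth <- read_extdata_csv("growth_reference.csv")
  }
  .nad_cache$growth
}

pediatric_fractions_cached <- function() {
  if (is.null(.nad_cache$pedfrac)) {
    .nad_cache$pedfrac <- read_extdata_csv("pediatric_organ_fractions.csv")
  }
  .nad_cache$pedfrac
}

#' Packaged reference organ table
#'
#' Organ volumes, regional blood flows and homogenized tissue composition
#' (water, lipid, protein mass fractions) for the reference adult. The
#' `lung` row carries the cardiac output as its flow; `venous_blood` and
#' `arterial_blood` are pool volumes without a regional flow.
#'
#' @return A data frame with columns `organ`, `volume_L`, `flow_L_per_h`,
#'   `water`, `lipid`, `protein`.
#' @export
organ_reference_table <- function() {
  organ_reference_cached()
}

systemic_organs <- function(organs) {
  organs[!(organs$organ %in% c(BLOOD_POOLS, "lung")), , drop = FALSE]
}

new_physiology_state <- function(organs, gfr, hematocrit, gastric_emptying_min,
                                 age, body_weight, height, sex,
                                 health_state = "healthy") {
  co <- organs$flow_L_per_h[organs$organ == "lung"]
  state <- structure(
    list(
      organs = organs,
      cardiac_output_L_h = co,
      gfr = gfr,
      hematocrit = hematocrit,
      gastric_emptying_min = gastric_emptying_min,
      age = age,
      body_weight = body_weight,
      height = height,
      sex = sex,
      health_state = health_state
    ),
    class = "physiology_state"
  )
  validate_physiology(state)
  state
}

#' Validate a physiology state
#'
#' Checks the structural invariants of a virtual individual: positive organ
#' volumes, non-negative flows, composition fractions in \[0, 1\] summing to
#' at most 1, hematocrit strictly inside (0, 1), non-negative GFR, positive
#' gastric emptying time, and regional flow balance (the systemic organ
#' flows must sum to the cardiac output to within 1e-6 relative).
#'
#' @param state A `physiology_state`.
#' @return The state, invisibly; an error is raised on any violation.
#' @export
validate_physiology <- function(state) {
  org <- state$organs
  if (any(org$volume_L <= 0)) nad_stop("organ volumes must be positive")
  flows <- org$flow_L_per_h[!(org$organ %in% BLOOD_POOLS)]
  if (any(flows < 0)) nad_stop("organ blood flows must be non-negative")
  comp <- org[, c("water", "lipid", "protein")]
  if (any(comp < 0) || any(comp > 1) || any(rowSums(comp) > 1 + 1e-9)) {
    nad_stop("tissue composition fractions must lie in [0,1] and sum to <= 1")
  }
  if (state$gfr < 0) nad_stop("gfr must be non-negative")
  if (state$hematocrit <= 0 || state$hematocrit >= 1) {
    nad_stop("hematocrit must lie strictly in (0, 1)")
  }
  if (state$gastric_emptying_min <= 0) {
    nad_stop("gastric emptying time must be positive")
  }
  sys <- systemic_organs(org)
  co <- state$cardiac_output_L_h
  if (abs(sum(sys$flow_L_per_h) - co) > 1e-6 * co) {
    nad_stop("regional blood flows do not balance cardiac output")
  }
  invisible(state)
}

#' Reference healthy adult
#'
#' The packaged deterministic reference individual: a 30-year-old,
#' 70 kg, 170 cm male with ICRP-style organ volumes and regional flows,
#' GFR 120 mL/min, hematocrit 0.45, and gastric emptying time 15 min.
#' All simulated and sampled individuals are derived from this template.
#'
#' @return A `physiology_state`.
#' @examples
#' ref <- reference_adult()
#' ref$gfr
#' @export
reference_adult <- function() {
  new_physiology_state(
    organs = organ_reference_cached(),
    gfr = GFR_REF_ML_MIN,
    hematocrit = HCT_REF_MALE,
    gastric_emptying_min = GET_REF_MIN,
    age = 30, body_weight = WT_REF_KG, height = 170, sex = "male"
  )
}

RF_PHYSIOLOGY <- list(
  moderate = list(gfr = 45, hematocrit = 0.42, gastric_emptying_min = 20.4),
  severe   = list(gfr = 18, hematocrit = 0.39, gastric_emptying_min = 24.6)
)

#' Apply renal-failure physiology
#'
#' Overwrites the three fields that change with chronic kidney disease
#' severity -- GFR, hematocrit and gastric emptying time -- leaving every
#' other field (organ volumes, flows, demographics) untouched. Moderate
#' renal failure: GFR 45 mL/min, hematocrit 0.42, gastric emptying
#' 20.4 min. Severe: GFR 18 mL/min, hematocrit 0.39, 24.6 min.
#'
#' @param state A `physiology_state`.
#' @param severity `"moderate"` or `"severe"`.
#' @return A new `physiology_state`; the input is not modified.
#' @examples
#' rf <- apply_renal_failure(reference_adult(), "severe")
#' rf$gfr  # 18
#' @export
apply_renal_failure <- function(state, severity = c("moderate", "severe")) {
  validate_physiology(state)
  if (length(severity) == 1 && !severity %in% names(RF_PHYSIOLOGY)) {
    nad_stop("unknown renal-failure severity: ", severity,
             class = "nadpbpk_severity_error")
  }
  severity <- match.arg(severity)
  vals <- RF_PHYSIOLOGY[[severity]]
  out <- state
  out$gfr <- vals$gfr
  out$hematocrit <- vals$hematocrit
  out$gastric_emptying_min <- vals$gastric_emptying_min
  out$health_state <- paste0(severity, "_rf")
  out
}

#' GFR maturation sigmoid
#'
#' Fraction of adult (weight-normalized) GFR attained at a given
#' postmenstrual age, modeled as a Hill sigmoid with TM50 47.7 weeks and
#' Hill coefficient 3.4 -- a standard published renal maturation function.
#'
#' @param pma_weeks Postmenstrual age in weeks (postnatal age + 40 weeks
#'   for a term birth).
#' @return Maturation fraction in (0, 1).
#' @export
gfr_maturation_fraction <- function(pma_weeks) {
  pma_weeks^GFR_HILL / (GFR_TM50_WEEKS^GFR_HILL + pma_weeks^GFR_HILL)
}

growth_lookup <- function(age) {
  g <- growth_reference_cached()
  list(
    weight = stats::approx(g$age_years, g$weight_kg, age, rule = 2)$y,
    height = stats::approx(g$age_years, g$height_cm, age, rule = 2)$y,
    hematocrit = stats::approx(g$age_years, g$hematocrit, age, rule = 2)$y
  )
}

pediatric_band_fractions <- function(age) {
  pf <- pediatric_fractions_cached()
  sel <- pf$age_lo <= age & (age < pf$age_hi | (age == 18 & pf$age_hi == 18))
  if (!any(sel)) sel <- pf$age_hi == max(pf$age_hi)
  band <- pf[sel, , drop = FALSE]
  stats::setNames(band$fraction, band$organ)
}

#' Scale physiology to a pediatric age
#'
#' Builds a virtual child from the adult template: organ volumes come from
#' age-band volume-fraction-of-body-weight tables; cardiac output and
#' regional flows scale allometrically with body weight (exponent 0.75)
#' keeping the adult flow distribution; GFR is the adult value scaled
#' allometrically and multiplied by the renal maturation sigmoid of
#' postmenstrual age; hematocrit comes from a packaged age table.
#' Gastric emptying time is kept at the adult reference.
#'
#' @param age Age in years, in (0, 18\].
#' @param body_weight Body weight in kg; defaults to the packaged
#'   median weight-for-age.
#' @param height Height in cm; defaults to the packaged median
#'   height-for-age.
#' @param sex `"male"` or `"female"` (recorded; pediatric hematocrit is
#'   taken from the unisex age table).
#' @return A `physiology_state`.
#' @examples
#' inf <- scale_to_age(0.25)   # a 3-month-old at median weight
#' inf$gfr < reference_adult()$gfr
#' @export
scale_to_age <- function(age, body_weight = NULL, height = NULL,
                         sex = "male") {
  if (!is.numeric(age) || age <= 0 || age > 18) {
    nad_stop("age must lie in (0, 18] years")
  }
  g <- growth_lookup(age)
  body_weight <- body_weight %||% g$weight
  height <- height %||% g$height
  if (body_weight <= 0) nad_stop("body weight must be positive")

  ref <- organ_reference_cached()
  org <- ref
  frac <- pediatric_band_fractions(age)
  org$volume_L <- unname(frac[org$organ]) * body_weight

  co_scale <- (body_weight / WT_REF_KG)^ALLOMETRIC_EXP
  org$flow_L_per_h <- ref$flow_L_per_h * co_scale

  pma <- age * WEEKS_PER_YEAR + 40
  gfr <- GFR_REF_ML_MIN * co_scale * gfr_maturation_fraction(pma)

  new_physiology_state(
    organs = org, gfr = gfr, hematocrit = g$hematocrit,
    gastric_emptying_min = GET_REF_MIN,
    age = age, body_weight = body_weight, height = height, sex = sex,
    health_state = "pediatric"
  )
}

scale_adult_to_weight <- function(body_weight, sex = "male", age = 30,
                                  height = NULL) {
  if (body_weight <= 0) nad_stop("body weight must be positive")
  ref <- organ_reference_cached()
  org <- ref
  size <- body_weight / WT_REF_KG
  org$volume_L <- ref$volume_L * size
  org$flow_L_per_h <- ref$flow_L_per_h * size^ALLOMETRIC_EXP
  hct <- if (identical(sex, "female")) HCT_REF_FEMALE else HCT_REF_MALE
  new_physiology_state(
    organs = org,
    gfr = GFR_REF_ML_MIN * size^ALLOMETRIC_EXP,
    hematocrit = hct,
    gastric_emptying_min = GET_REF_MIN,
    age = age, body_weight = body_weight,
    height = if (is.null(height)) 170 * size^(1 / 3) else height,
    sex = sex
  )
}

#' Specify a virtual population
#'
#' @param n Number of individuals (>= 1).
#' @param age_range Two-element numeric range of ages in years.
#' @param weight_range Optional two-element range of body weights in kg;
#'   when omitted, weight is the reference (or weight-for-age) value
#'   perturbed uniformly by +/- 20 percent.
#' @param female_fraction Probability that an individual is female.
#' @param health_state One of `"healthy"`, `"moderate_rf"`, `"severe_rf"`,
#'   `"pediatric"`.
#' @param seed Integer RNG seed; sampling is fully reproducible.
#' @param cv Log-normal inter-individual coefficient of variation applied
#'   to organ volumes, flows and GFR (default 0.16, truncated at 3 SD).
#' @return A `population_spec`.
#' @export
population_spec <- function(n, age_range, weight_range = NULL,
                            female_fraction = 0, health_state = "healthy",
                            seed = 1, cv = 0.16) {
  if (!is.numeric(n) || n < 1) nad_stop("population size n must be >= 1")
  if (length(age_range) != 2 || diff(range(age_range)) < 0 ||
      any(age_range < 0)) {
    nad_stop("age_range must be a non-empty, non-negative range")
  }
  if (!is.null(weight_range) &&
      (length(weight_range) != 2 || any(weight_range <= 0) ||
       diff(range(weight_range)) < 0)) {
    nad_stop("weight_range must be a positive, non-empty range")
  }
  if (female_fraction < 0 || female_fraction > 1) {
    nad_stop("female_fraction must lie in [0, 1]")
  }
  health_state <- match.arg(health_state,
                            c("healthy", "moderate_rf", "severe_rf",
                              "pediatric"))
  structure(
    list(n = as.integer(n), age_range = sort(as.numeric(age_range)),
         weight_range = if (is.null(weight_range)) NULL
                        else sort(as.numeric(weight_range)),
         female_fraction = female_fraction, health_state = health_state,
         seed = as.integer(seed), cv = cv),
    class = "population_spec"
  )
}

apply_iiv <- function(state, cv) {
  if (cv <= 0) return(state)
  org <- state$organs
  n_org <- nrow(org)
  org$volume_L <- org$volume_L * lognormal_factors(n_org, cv)
  sys_idx <- which(!(org$organ %in% c(BLOOD_POOLS, "lung")))
  org$flow_L_per_h[sys_idx] <-
    org$flow_L_per_h[sys_idx] * lognormal_factors(length(sys_idx), cv)
  # cardiac output is re-derived so flow balance holds exactly
  co <- sum(org$flow_L_per_h[sys_idx])
  org$flow_L_per_h[org$organ == "lung"] <- co
  state$organs <- org
  state$cardiac_output_L_h <- co
  state$gfr <- state$gfr * lognormal_factors(1, cv)
  state
}

#' Sample a seeded virtual population
#'
#' Draws `spec$n` individuals: ages and weights uniform within their
#' ranges, sex Bernoulli(`female_fraction`), then log-normal
#' inter-individual variability (CV `spec$cv`, truncated at 3 SD) on organ
#' volumes, regional flows and GFR. Renal-failure populations receive the
#' disease physiology (GFR, hematocrit, gastric emptying) before
#' variability; pediatric populations are built through the age-scaling
#' path. Cardiac output is re-derived from the perturbed flows so the
#' flow-balance invariant holds for every individual.
#'
#' @param spec A `population_spec`.
#' @return A list of `physiology_state` objects of length `spec$n`.
#' @examples
#' pop <- sample_population(population_spec(5, c(18, 74), seed = 42))
#' length(pop)
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
      sex <- if (stats::runif(1) < spec$female_fraction) "female" else "male"
      if (spec$health_state == "pediatric") {
        wt <- if (!is.null(spec$weight_range)) {
          stats::runif(1, spec$weight_range[1], spec$weight_range[2])
        } else {
          growth_lookup(age)$weight * stats::runif(1, 0.8, 1.2)
        }
        st <- scale_to_age(age, body_weight = wt, sex = sex)
      } else {
        wt <- if (!is.null(spec$weight_range)) {
          stats::runif(1, spec$weight_range[1], spec$weight_range[2])
        } else {
          WT_REF_KG * stats::runif(1, 0.8, 1.2)
        }
        st <- scale_adult_to_weight(wt, sex = sex, age = age)
        if (spec$health_state == "moderate_rf") {
          st <- apply_renal_failure(st, "moderate")
        } else if (spec$health_state == "severe_rf") {
          st <- apply_renal_failure(st, "severe")
        }
      }
      st <- apply_iiv(st, spec$cv)
      st$subject_id <- i
      validate_physiology(st)
    })
  })
}

#' @export
print.physiology_state <- function(x, ...) {
  cat(sprintf(
    "<physiology_state> %s, age %.2f y, %.1f kg, %s\n",
    x$health_state, x$age, x$body_weight, x$sex
  ))
  cat(sprintf(
    "  GFR %.1f mL/min | hematocrit %.2f | gastric emptying %.1f min | CO %.0f L/h\n",
    x$gfr, x$hematocrit, x$gastric_emptying_min, x$cardiac_output_L_h
  ))
  cat(sprintf("  %d organs, total tissue volume %.1f L\n",
              nrow(x$organs), sum(x$organs$volume_L)))
  invisible(x)
}
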