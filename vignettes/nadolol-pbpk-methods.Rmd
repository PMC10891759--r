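---
title: "Methods: a whole-body PBPK model of nadolol in renal impairment and pediatrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-body PBPK model of nadolol in renal impairment and pediatrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadpbpk)
```

## Why nadolol, and why PBPK

Nadolol is a long-acting non-selective β-blocker with two properties
that make it a clean PBPK case study: it is not metabolized (about 75%
of a dose leaves through the kidneys unchanged, the rest through
biliary excretion), and its clearance is therefore almost entirely
driven by glomerular filtration. Exposure consequently rises in chronic
kidney disease and falls through childhood as the kidney matures — the
two populations this package exists to simulate. Because the relevant
physiology (GFR, hematocrit, gastric emptying, organ sizes and flows)
is explicit in the model, disease and age enter as parameter changes
rather than empirical covariates.

## Model structure

The disposition model is the field-standard perfusion-limited
whole-body form: venous and arterial blood pools, lung in series, and
thirteen parallel systemic organs. For every organ,

$$\frac{dA_t}{dt} = Q_t\left(C_{art} - \frac{C_t}{K_{p,t}/BP}\right),$$

i.e. tissue is in equilibrium with its venous outflow (uptake limited
by flow, not permeability). Gut and spleen drain through the portal
vein into the liver; the liver receives the hepatic artery besides.
This choice — rather than a permeability-limited or GUI-simulator-
specific formulation — keeps every equation inspectable and gives exact
integral identities used throughout the tests. Its main consequence is
a fast distribution phase: after an IV bolus the venous pool mixes on
the scale of minutes, so the instantaneous curve maximum is a mixing
artifact and all comparisons with clinical data are made on realistic
sampling schedules (first IV sample at 2 min).

**Clearance placement.** Renal clearance (131 mL/min at the reference
GFR of 120 mL/min, scaled proportionally to each individual's GFR) acts
on the kidney inflow (arterial) plasma concentration; the biliary
pathway (219 − 131 = 88 mL/min, scaled with body weight^0.75) acts on
the liver inflow plasma concentration. With a conservative lung, mass
balance then forces

$$AUC_{0\text{-}\infty}^{IV} = \frac{Dose}{CL_T}$$

for the venous plasma curve *exactly*, independent of the partition
coefficients. This identity (152.2 ng·h/mL for 2 mg) is the engine's
primary correctness oracle and is enforced in the tests to 1% under
two-fold perturbations of every Kp.

**Partitioning.** The tissue-to-plasma coefficients use a homogenized
tissue-composition calculation,
$K_p = f_{water} + 10^{\log P} f_{lipid} + (1/f_u - 1) f_{protein}$,
a deliberately simple Poulin–Theil-style stand-in (proprietary
distribution methods are out of scope). It reproduces the aqueous limit
(Kp = 1 for water with no binding) and, with nadolol's LogP 0.81 and
fu 0.7, yields a steady-state volume near 150 L — consistent with
nadolol's reported ~2 L/kg. Every Kp can be pinned per organ via
`kp_overrides`, and IV exposure is Kp-independent by the identity
above, which confines the risk of this approximation to curve *shape*.

**Oral absorption.** The lumen model is stomach → single mixed
small-intestine compartment → gut tissue. Gastric emptying is
first-order with half-life equal to the gastric emptying time (15 min
reference; 20.4/24.6 min in moderate/severe renal failure — the only
GI physiology the disease model varies). Absorption competes with an
intestinal transit loss of half-life 3 h. The raw wall-permeation rate
$k_a = 2 P_{eff}/r$ (with the packaged $P_{eff}$ = 1.03·10⁻⁶ cm/min and
r = 1.17 cm) describes a smooth cylinder; real mucosa amplifies the
absorptive surface by orders of magnitude. The engine therefore applies
an effective surface-area amplification whose packaged value (1230) is
the output of `calibrate_absorption()` — a bisection of the simulated
oral AUC against a target absolute bioavailability of **F = 0.34**,
nadolol's literature value of "about one third". This replaces visual
curve tuning with a reproducible numeric calibration; the achieved
F and the multiplier are both inspectable.

## Virtual physiology

The reference adult (70 kg, 170 cm, male, GFR 120 mL/min, hematocrit
0.45, gastric emptying 15 min) carries ICRP-style organ volumes and
flows summing to a cardiac output of 390 L/h. These reference values
are not unique in the literature; they are packaged as a CSV and
everything downstream treats them as data.

* **Renal failure** replaces exactly three fields, per the clinical
  characterization of CKD populations: GFR 45 / 18 mL/min, hematocrit
  0.42 / 0.39, gastric emptying 20.4 / 24.6 min for moderate / severe
  disease. Protein-binding and enzyme-abundance changes in CKD are
  deliberately out of scope.
* **Pediatrics**: organ volumes come from age-band
  fraction-of-body-weight tables; flows scale with weight^0.75 keeping
  the adult flow split; GFR is the adult value scaled allometrically
  and multiplied by a Hill sigmoid of postmenstrual age (TM50 47.7
  weeks, coefficient 3.4 — a standard published maturation function;
  PMA = postnatal age + 40 weeks). Hematocrit follows a packaged age
  table. The maturation curve saturates: at 18 y / 70 kg the GFR is
  within 2% of the adult reference, and it is monotone in age along the
  default growth curve.
* **Populations** sample age and weight uniformly within study ranges
  (weight defaults to the growth-table value ±20% when a study reported
  none), sex as Bernoulli draws, and apply log-normal inter-individual
  variability with CV 16% (truncated at 3 SD) to organ volumes, flows
  and GFR. Cardiac output is re-derived from the perturbed flows, so
  flow balance holds exactly for every individual. All sampling is
  seeded and bit-reproducible.

## Numerical choices

Integration uses `deSolve::lsoda` (stiff-capable) with default
tolerances 1e-8 absolute / 1e-6 relative and an output grid of 0.1 h.
Doses are instantaneous events. Five refinement points are inserted in
the first 0.05 h after each dose so that linear-trapezoid NCA resolves
the venous mixing transient; without them the IV AUC identity is missed
by ~10% on a uniform 0.1 h grid. Mass balance (body + lumen +
eliminated + transit loss = administered) closes to ~1e-14 relative and
is asserted at 1e-6 in the tests. Halving the grid step changes NCA
results by well under 0.5%.

NCA uses the linear trapezoid (matching the common NCA-tool default),
with the terminal slope fitted by log-linear least squares over the
last 5 points or the points in the last 20% of the time span, whichever
set is larger; a non-negative terminal slope yields `NA` for
AUC₀–∞, CL and t½ while AUC₀–t is still reported. Quartiles and VPC
percentiles use linear interpolation between order statistics
(`quantile` type 7); box whiskers are the data minimum and maximum,
matching the exposure box-plot convention. In the two-compartment
synthetic generator, an absorption rate coinciding with an eigenvalue
is nudged by 1 part in 10⁶ (the one-compartment oral case uses the true
analytic limit).

## Qualification workflow and its inputs

The packaged observed table carries the printed predicted/observed
Cmax, AUC₀–t and CL cells for 22 study arms (4 IV healthy, 12 oral
healthy, 3 IV pediatric, 3 oral pediatric) plus demographics, and the
package re-predicts each arm with a 100-subject virtual population.
Three input conventions had to be fixed where the source tables are
silent or inconsistent:

* Sampling schedules are not published (the original curves were
  digitized from plots), so fixed per-route schedules are used — IV
  from 2 min to 48 h, oral from 30 min to 72 h, shorter for children.
  The 2-min IV start follows from the printed observed Cmax values
  themselves: 81 ng/mL after a 2 mg bolus implies an apparent volume of
  ~25 L, attainable only minutes after dosing.
* The pediatric IV doses are taken in mg as printed (only the oral
  pediatric rows carry the per-kg footnote), and the three pediatric
  rows map in order to the 3-, 5- and 121-month study populations.
* The printed oral CL columns are not dimensionally consistent with
  Dose/AUC in the printed units, so observed CL is carried opaquely and
  oral CL is excluded from the simulation-based comparison; six printed
  ratio cells cannot be reproduced from their own printed
  numerator/denominator and are flagged (`table_ratio_check()`), never
  silently matched.

Statistics follow the standard qualification toolkit: per-cell ratio
R = pred/obs, average fold error AFE = 10^(mean log₁₀ R) per block and
parameter, and the twofold criterion on the closed interval [0.5, 2].

## The synthetic observed-data generator

The original clinical curves are digitized plot data and are not
redistributable; the synthetic module generates statistically analogous
"observed" studies instead: analytic one- or two-compartment profiles
(the closed forms double as oracles for the NCA tests), log-normal
inter-individual variability on CL and V (CV 20%), proportional
measurement noise (CV 10%) with a 0.1 ng/mL additive floor, all seeded.
Sampling stays within the quantifiable range (≤ 36 h for the reference
IV design, ≈4.5 half-lives) — sampling far into the noise floor makes
terminal-slope estimation meaningless, for synthetic and real data
alike. What passing recovery tests show is that the NCA pipeline is
unbiased under this noise model; they cannot show that the noise model
matches the digitization error of the original plots, for which no
residual-error information exists.

## Problem sizes

The test suite re-predicts every study arm with 30-subject populations
and runs the disease/age scenarios at n = 12–15; the acceptance script
uses the full 100-subject populations everywhere (its runtime is a few
minutes on one CPU). Parameter-recovery checks use 200 synthetic
subjects. These sizes were chosen so that Monte-Carlo error is well
inside every asserted tolerance.

## Known limitations

* Perfusion-limited distribution overstates early tissue uptake for a
  low-permeability (BCS class 3) drug; the terminal half-life realized
  (~9 h) sits below nadolol's reported 14–24 h. Qualification relies on
  exposure metrics, which are insensitive to this.
* The single mixed intestinal compartment cannot reproduce multi-peak
  absorption or regional permeability differences; dissolution is never
  rate-limiting (high solubility) and is not modeled.
* Biliary clearance scales only with size; no enterohepatic
  recirculation, no transporter ontogeny.
* Renal failure modifies GFR, hematocrit and gastric emptying only —
  deliberately mirroring the scope of the disease characterization used
  for the populations; CKD changes in plasma-protein binding or CYP
  abundance are not represented.
* The pediatric evaluation rests on a single published clinical study
  with ambiguous dosing units; the age-trend scenarios are therefore
  directional analyses, not dose recommendations.
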