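Package: nadpbpk
Title: Whole-Body Physiologically Based Pharmacokinetic Modeling of Nadolol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body, perfusion-limited physiologically based
    pharmacokinetic (PBPK) simulator for the renally cleared beta-blocker
    nadolol, with disease (renal failure) and pediatric (renal maturation)
    physiology scaling, seeded virtual populations, non-compartmental
    analysis, visual-predictive-check envelopes, and model-qualification
    statistics (predicted/observed ratios, average fold error, twofold
    criterion) against published adult and pediatric pharmacokinetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
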