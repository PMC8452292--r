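Package: mfpbpk
Title: Maternal-Fetal Pharmacokinetic Simulation of Antenatal Corticosteroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced maternal-fetal physiologically-based pharmacokinetic
    (PBPK) simulator for the antenatal corticosteroids dexamethasone and
    betamethasone. Implements a lumped four-state model (dual intramuscular
    depot, maternal central, fetal central) with perfusion-limited placental
    passive diffusion and P-glycoprotein efflux clearances, the unbound
    fetal:maternal partition coefficient (Kp,uu) algebra, noncompartmental
    exposure metrics (AUC, Cmax, Cmin, terminal half-life, time above a
    therapeutic threshold), Emax fitting of umbilical-vein/maternal-plasma
    concentration ratios, Kp,uu calibration against sparse paired delivery
    samples with bootstrap confidence intervals and absolute-average-fold-error
    qualification, Monte-Carlo population variability with percentile bands,
    and reference-versus-alternative dosing-regimen comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
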