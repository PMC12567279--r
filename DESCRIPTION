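Package: escipbpk
Title: Pregnancy Physiologically Based Pharmacokinetic Modeling of Escitalopram
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK) modeling of
    escitalopram across pregnancy. Provides gestational-age scaling of maternal
    physiology, Rodgers-Rowland tissue partitioning, a perfusion-limited
    maternal model with well-stirred hepatic elimination, a permeability-limited
    fetoplacental unit (placental barrier clearances, fetal renal and
    amniotic-swallowing clearances), CYP2C19 phenotype-stratified virtual
    populations, model-qualification statistics (prediction ratio, absolute
    average fold error, interval coverage), Morris elementary-effects
    sensitivity screening, weighted least-squares parameter estimation, and
    therapeutic-window dose assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
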