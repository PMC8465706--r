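Package: clrkinetics
Title: Compartmental Biokinetic Modelling of Radioiodinated CLR1404
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and exercising linear compartmental
    biokinetic models of the phospholipid ether analog CLR1404 labelled
    with 124I/131I. Implements the full model-construction pipeline:
    forcing-function decoupling of organ subsystems, weighted
    least-squares fitting by simulated annealing, small-sample Akaike
    (AICc) structure selection, variance-based (Sobol) sensitivity
    pruning, Monte Carlo parameter-uncertainty estimation, closed-form
    cumulated (time-integrated) activities, and simplified dosimetric
    estimators (reduced model, biexponential and single-point
    monoexponential fits). Ships the published 17-compartment model with
    its best-fit rate constants and blood fractions, reference organ
    masses, and a synthetic time-activity data generator emulating the
    PET/SPECT/blood/urine acquisition structure of the clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
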