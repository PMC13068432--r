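Package: rhoflux
Title: Rho GTPase Signalling Flux Under Optogenetic GEF Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and inference for an optogenetic
    GEF-Rho-GAP signalling circuit. Implements the three-species ordinary
    differential equation model of light-induced LARG recruitment, RhoA
    activation and Rho-dependent GAP feedback (wild type) together with its
    reduced knockout variant in which GAP activation is independent of Rho;
    generation of noisy per-ROI biosensor trace ensembles with fold-change
    normalisation and bootstrap median confidence bands; two-stage bounded
    least-squares fitting (recruitment kinetics first, circuit parameters
    with the GEF profile frozen) with staged multistart to cope with
    practical non-identifiability; profile-likelihood and bound-sensitivity
    identifiability diagnostics; 10-90 percent window observed-rate
    statistics; and a focal-adhesion/non-adhesion ROI targeting pipeline on
    synthetic two-channel fluorescence images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
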