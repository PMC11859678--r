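Package: hipecsim
Title: Multiscale Simulation of Oxaliplatin Delivery During (H)IPEC with
    Vascular Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates oxaliplatin transport into peritoneal tumour nodules
    during 30-minute (hyperthermic) intraperitoneal chemotherapy. Couples
    per-organ surface temperature and drug-concentration boundary series to
    an axisymmetric diffusion-reaction solver with cellular elimination and
    Starling/Peclet transvascular washout modulated by mild hyperthermia, a
    Pennes bioheat slab model with a lumped arterial update, a well-mixed
    cavity balance, and a two-compartment systemic pharmacokinetic model.
    Evaluates tumour exposure (AUC), IC50-referenced effective penetration
    depth with thermal enhancement, pharmacokinetic-advantage ratios, and
    dose-equivalence searches, including scenario transforms describing
    bevacizumab-induced vascular normalization, collagen-density and
    microvascular-permeability sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
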