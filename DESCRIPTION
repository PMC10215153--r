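Package: kneelax
Title: Quasi-Static Simulation of TKA Knee Laxity under Femoral Component Malrotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A digital-twin, quasi-static six-degree-of-freedom simulator of a total knee
    arthroplasty (TKA) joint mounted in a joint motion simulator. The knee is modelled as two
    rigid bodies (femur plus a single-radius cruciate-retaining femoral component; tibia plus
    tray and dished polyethylene insert) connected by a multifiber nonlinear ligament system
    (five-bundle superficial MCL with tibial wrapping, five-bundle LCL, three-bundle PCL) and
    inferior-superior penalty contact. Provides parametric synthetic implant and bone-surrogate
    geometry, posterior condylar axis component alignment with controlled external malrotation,
    mixed force/displacement equilibrium solving, Grood-Suntay joint coordinate kinematics, and
    an experiment pipeline reproducing neutral-flexion, posterior-drawer, varus-valgus and
    internal-external laxity envelope tests across malrotation conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
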