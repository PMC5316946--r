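Package: thrombosim
Title: Continuum Simulation of Thrombus Deposition in Flowing Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A multi-constituent continuum model of thrombus formation and
    growth. Blood is treated as a single-phase fluid coupled to a deposited
    platelet (thrombus) phase through a hindrance-based resistance force, and
    ten chemical and biological species (resting/activated platelets, three
    deposited platelet states, ADP, thromboxane A2, prothrombin, thrombin and
    antithrombin III) are advanced by convection-diffusion-reaction transport
    with platelet activation by chemical agonists and shear, surface-flux
    deposition on reactive walls, threshold-triggered thrombus propagation,
    shear-driven embolization and heparin-catalyzed thrombin inhibition.
    Includes an axisymmetric injured-vessel benchmark and a planar
    micro-crevice benchmark on staggered finite-volume grids, a well-mixed
    (0D) kinetics harness, morphometrics and occlusion detection, and
    VTK/CSV/YAML input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    deSolve,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
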