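Package: c4flex
Title: Compartmental Kinetic Modelling of Mixed C4 Photosynthetic Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady-state kinetic simulation of C4 photosynthesis in a
    four-compartment mesophyll/bundle-sheath leaf model. Implements five
    pathway variants that differ in the transfer acids (malate, aspartate,
    alanine, pyruvate, PEP) and decarboxylases (NADP-malic enzyme, PEPCK)
    they employ, electron-transport-driven ATP/NADPH supply with an
    adjustable linear electron transport fraction in bundle sheath cells,
    plasmodesmatal metabolite diffusion, and bundle-sheath CO2 leakiness.
    Provides parameter scans for light response, light allocation between
    cell types, and PEPC sensitivity, together with derived metrics
    (assimilation, leakiness, photorespiration, metabolite gradients and
    pools).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
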