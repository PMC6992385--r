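Package: polcpm
Title: Extended Cellular Potts Simulation of Polarized Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hexagonal-lattice cellular Potts simulator of single-cell and
    collective cell migration driven by a self-regulating polarization field.
    Cells are contiguous sets of lattice sites evolving by Metropolis-type
    protrusion and retraction events under an effective energy combining area
    and perimeter contractility, a bounded per-site polarization field with
    positive/negative mechanochemical feedback of range R, intercellular
    adhesion and friction, substrate micropatterns, and a three-state cell
    cycle with contact inhibition of proliferation. Ships experiment harnesses
    for free single cells, confined cell clusters on circular micropatterns,
    and expanding proliferating monolayers, together with the full analysis
    layer: mean-squared displacement and velocity autocorrelation, persistent
    random walk fits, gyration-tensor shape metrics, trajectory curvature,
    cluster rotation statistics, tissue kymographs (density, stress, velocity)
    and front roughness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
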