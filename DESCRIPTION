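Package: DropletTimer
Title: Timing-Controlled Division of DNA Droplets via RNase H Time-Delay Circuits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analyses the timing-controlled division of DNA-based
    liquid-liquid phase-separated droplets. Implements the well-mixed and
    reaction-diffusion kinetics of an RNase H time-delay circuit coupled to
    toehold-mediated linker cleavage, a Hill-type map from uncleaved-linker
    fraction to droplet division ratio, a molecular comparator of microRNA
    concentrations read out through the division pathway, image-based
    quantification of division ratios from multi-channel fluorescence stacks,
    and a synthetic-data generator producing droplet-division movies and noisy
    concentration traces with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    minpack.lm,
    yaml,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Software, CellBiology, MathematicalBiology, Visualization
RoxygenNote: 7.3.3
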