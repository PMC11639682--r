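Package: ferrowave
Title: Bistable ROS Reaction-Diffusion Modelling and Trigger-Wave Image
    Analysis for Ferroptosis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the propagation of ferroptotic cell death as
    trigger waves of reactive oxygen species (ROS). Implements a bistable
    reaction-diffusion model of cellular ROS under ferroptotic stress
    (erastin), including steady-state and saddle-node bifurcation analysis,
    an explicit lattice simulator of ROS trigger waves with photoinduction
    and a cell-death rule, seeded generators of synthetic time-lapse image
    stacks and spontaneous-initiation event series, image-analysis routines
    (wave outlines, kymographs and wave-speed estimation, wavefront width
    and amplitude, intensity profiles, cell-death vector fields and their
    angular entropy, initiation-site detection with Poisson/geometric event
    statistics, lipid-peroxidation ratios, fibre-orientation entropy), and
    parametric curve fits for dose-response (Michaelian inhibition and
    activation, biphasic inhibition) and logistic gap-crossing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    EBImage,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Software, CellBiology, ImageAnalysis, TimeCourse, MathematicalBiology
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic.R'
    'fits.R'
    'initiation.R'
    'kymograph.R'
    'model.R'
    'outlines.R'
    'simulate.R'
    'vectors.R'
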