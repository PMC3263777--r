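Package: meshnpm
Title: Neural Population Models on Cortical Meshes with Simultaneous EEG and fMRI BOLD Forward Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Forward-simulation chain for mean-field neural population models
    discretized on triangulated cortical surfaces. Provides curvature-preserving
    mesh pruning by edge collapse, geodesic and through-volume route distances
    for conduction delays, exponentially decaying background plus region-to-region
    specific connectivity with delay ring buffers, Catmull-Rom band-limited noise
    drive, a delay-buffered forward-Euler integrator for coupled
    excitatory-inhibitory populations, a three-compartment boundary-element EEG
    forward model, balloon-windkessel BOLD haemodynamics, Gaussian vertex-voxel
    projection, and a connectivity-strength sweep protocol with Welch spectra.
    All inputs (hemisphere meshes, parcellations, graded connectivity matrices,
    head shells, electrode caps, voxel grids) can be generated synthetically.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Matrix,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
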