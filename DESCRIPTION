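Package: radsms
Title: Simultaneous-Multislice Radial Real-Time MRI Simulation and
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibration-less simultaneous-multislice (SMS) radial real-time
    MRI at desk scale: golden-angle and SMS golden-angle trajectories with
    CAIPIRINHA phase cycling, a dynamic digital phantom of the oral cavity
    with smooth synthetic coil sensitivities, Kaiser-Bessel gridding NUFFT
    operators, PCA coil compression, ESPIRiT coil-sensitivity estimation from
    conjugate-phase motion-averaged k-space, ADMM compressed-sensing
    reconstruction with temporal finite-difference regularization, a CG-SENSE
    baseline, temporal median filtering, and quantitative metrics (tSNR, RMSE,
    ROI signal variation, x-t profiles). Data sets round-trip through an HDF5
    container and a command-line driver exposes simulation, reconstruction and
    parameter-sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
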