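Package: stencen
Title: Coupled Signal-Transduction and Cytoskeletal Excitable Network
    Wave Simulation and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic reaction-diffusion simulation of coupled
    excitable networks underlying cortical actin waves: a slow
    signal-transduction excitable network (STEN) coupled to a fast
    cytoskeletal excitable network (CEN) with local positive and global
    negative feedback.  Includes phase-plane wave theory (threshold,
    net-area wave-speed proxy, stopping level), perturbation presets
    emulating acute recruitment experiments, level-set viscoelastic
    cell-shape simulation driven by wave activity, quantification of
    wave movies (front speed, patch statistics, biosensor peak
    distance, puncta lifetime, kymographs), and a ground-truth
    synthetic movie generator for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
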