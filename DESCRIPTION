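Package: mstrace
Title: Multiple Scattering Tracing for Reflection-Matrix Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for deep imaging through
    scattering media with time-gated reflection matrices. Models a thick
    scattering medium as a stack of thin random phase plates, builds the
    multi-slice angular-spectrum forward model for transmission and
    reflection matrices of a buried reflective object, and recovers the
    per-layer phase functions and the object image by Green's-function
    normalized correlation and power iteration (the multiple scattering
    tracing algorithm). Includes ballistic-enhancement diagnostics
    (ballistic fractions, optical thickness in scattering mean free paths,
    angular spread functions, Pearson scores), synthetic phantom
    generators with calibrated optical thickness, scan-frame matrix
    assembly, a hierarchical result container, and command-line recipes
    for depth scans and plate-number sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
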