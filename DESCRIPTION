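Package: ptxhybrid
Title: Hybrid Parallel-Transmit RF Pulse Design and Variable Flip Angle R1 Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of kT-points parallel-transmit (pTx) excitation pulses that
    simultaneously homogenize the flip angle and the root-mean-squared transmit
    field (B1rms) under hardware and specific absorption rate (SAR) constraints,
    together with the downstream dual-flip-angle R1-mapping pipeline whose
    magnetization-transfer (MT) bias the B1rms term controls. Includes a
    synthetic 8-channel head phantom generator (transmit sensitivities,
    off-resonance, tissue compartments, compressed local-SAR model), a
    small-tip-angle forward model with analytic design gradients, a multi-start
    constrained optimizer, full Bloch and binary spin-bath SPGR simulators, and
    linearized dual-flip-angle R1 fitting with map-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
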