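Package: pulmoasl
Title: In Silico Arterial Spin Labeling of the Pulmonary Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation pipeline for arterial spin labeling (ASL) MR
    perfusion imaging of the lung. Generates synthetic pulmonary vascular
    networks by volume-filling branching, solves steady-state hemodynamics
    with gravity, vessel distension and Fung-Sobin capillary sheet flow,
    simulates the ASL bright image for sagittal slices via backward tracing
    of blood to its tagging-time position and the inversion-recovery signal
    equations, and optimizes the intensity threshold used to remove conduit
    (large-vessel) signal via a five-term cost function combining perfusion
    fraction, perfusion retention, conduit removal, and the match of the
    coefficient of variation and gravitational gradient to the underlying
    capillary perfusion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
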