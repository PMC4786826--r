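Package: spinevib
Title: Vibration-Based Structural Health Monitoring of the Lumbar Spine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for non-invasive, vibration-based
    structural health monitoring (SHM) of the lumbar spine. Generates
    random-phase multisine pulse-train excitation and synthetic accelerometer
    recordings from a lumped-parameter (mass-spring-damper) spinal chain with
    soft-tissue attenuation, sensor noise and controllable structural
    alterations; estimates per-sensor frequency response functions (FRF) and
    magnitude-squared coherence by pulse averaging; reduces smoothed FRFs to
    peak frequency (PEAK), area under the curve (AUC) and root-mean-square
    (RMS) outcomes with coherence-based sensor quality control; and tests
    within-pair outcome differences of monozygotic twin cohorts (paired t-test
    or ANCOVA) to distinguish structurally concordant from discordant spines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
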