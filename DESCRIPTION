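Package: somatomap
Title: Simulation and Analysis of Cortical Hand-Map Changes Under a
    Single-Finger Nerve Block
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A synthetic-data pipeline for studying how the primary
    somatosensory (S1) hand map responds to acute loss of input from one
    finger. Generates voxel-wise finger activity patterns, traveling-wave
    localizer runs and two-alternative forced-choice psychophysics trials
    with known ground truth; implements a minimal GLM stage (double-gamma
    HRF, least-squares betas, contrasts, fixed-effects averaging),
    phase-encoded traveling-wave finger mapping with FDR-thresholded
    winner-takes-all cluster definition, univariate selectivity and
    winner-takes-all remapping analyses, cross-validated Mahalanobis
    (cross-nobis) representational similarity analysis with MDS and
    scaling-free Procrustes group alignment, a five-unit recurrent
    cortical model with peripheral afferent spread and homeostatic gain
    fitting, and Weibull psychometric threshold estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
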