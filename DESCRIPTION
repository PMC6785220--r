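Package: ecogwaves
Title: Rhythmic and Arrhythmic Dynamics of Sensorimotor ECoG
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissociating rhythmic (alpha/beta) from arrhythmic
    (1/f) activity in electrocorticography recordings of sensorimotor
    cortex.  Implements irregular-resampling auto-spectral analysis
    (IRASA) with Gaussian band parameterization, aperiodic-slope and
    high-frequency excitability indices, confidence-interval based
    electrode localization, time-resolved band power with cluster-based
    permutation statistics, representational similarity analysis with
    default-prior Bayes factors, traveling-wave quantification via phase
    gradients and circular statistics, and a psychometric analysis of
    grasp-orientation choices.  A synthetic-ECoG generator with known
    ground truth (1/f background, narrowband traveling oscillations,
    condition-dependent amplitude modulation, broadband co-modulation,
    and sine-law choice behavior) closes the loop for recovery testing,
    with EDF and BIDS-iEEG style tabular I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
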