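Package: aeqsig
Title: Simulation and Quantification of Aequorin-Based Cytosolic Calcium Signatures
Version: 0.1.0
Authors@R:
    person("Plate", "Luminometrics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of calcium-dependent aequorin bioluminescence
    under plate-luminometer and photon-counting-camera protocols, and the
    inverse analysis converting photon counts to cytosolic free calcium
    concentration traces. Includes a library of stimulus-specific calcium
    signature presets (salt, osmotic, oxidative and flagellin-22 elicitation
    in barley and Arabidopsis leaf and root tissue), extraction of signature
    features (amplitude, time-to-peak, onset delay, sustained elevation),
    dose-response and channel-blocker inhibition analysis, leaf
    developmental-gradient section profiling with one-way ANOVA and Tukey
    compact letter displays, and region-of-interest normalisation of
    photon-counting image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
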