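Package: cystokit
Title: Simulation, Feature Extraction and Reliability Analysis for Serial
    Cystometry with External Urethral Sphincter EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dual-channel urodynamic recordings (bladder
    pressure plus external urethral sphincter electromyogram) acquired during
    continuous-infusion cystometry in rodents. Provides a generative simulator
    of rhythmic micturition cycles with known ground truth, the standard
    conditioning steps (EMG rectification, block-mean resampling to an
    effective 0.1 kHz rate, catheter offset correction), detection of voiding
    contractions and extraction of the six classic urodynamic features (peak,
    threshold and minimum bladder pressure, volume threshold, EUS burst
    duration and burst count), and the reliability statistics used for serial
    recording protocols: ICC(3,k) with 95% confidence intervals and one-way
    repeated-measures ANOVA across sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
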