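Package: topotest
Title: Global Randomization Statistics for Event-Related EEG/MEG Scalp
    Field Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assumption-free randomization statistics for multichannel
    event-related EEG/MEG scalp field data. Implements topographic
    analysis of variance (TANOVA) and covariance (TANCOVA) based on
    global field power of condition/group mean-map differences, factorial
    within/between-subject designs with effect-specific permutation
    schemes, time-point-wise and window-averaged inference, global
    multiple-testing control over time via count-of-significant-time-
    points and duration-threshold statistics, the topographic consistency
    test, multidimensional scaling of condition mean topographies, a
    plain-ASCII data importer, and a synthetic ERP generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
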