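Package: wwpe
Title: Wavelet Weighted Permutation Entropy Features for Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification toolkit for multi-channel
    surface electromyography (sEMG) built around wavelet weighted permutation
    entropy (WWPE). Decomposes each channel with a multilevel discrete wavelet
    transform (sym8 by default), reconstructs the sub-band signals, computes
    weighted permutation entropy of every sub-band, and assembles the
    resulting feature sets for hand-movement recognition with support vector
    machine and feed-forward neural network classifiers. Includes ordinal
    pattern and (weighted) permutation entropy primitives, a classical
    time-domain feature baseline (RMS, MAV, WL, ZC, SSC), a synthetic sEMG
    generator for end-to-end testing, and delimiter-separated-value readers
    and writers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    nnet,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
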