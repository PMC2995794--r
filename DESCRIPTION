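Package: smoothCNA
Title: Kernel-Smoothed Detection of Recurrent and Differential DNA Copy
    Number Aberrations in Multi-Sample aCGH Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects statistically significant DNA copy number aberrations
    in collections of array-CGH log2-ratio profiles without discretizing
    the data. Probe signals are smoothed onto a regular genomic grid by
    truncated-Gaussian kernel convolution with a Nadaraya-Watson correction
    for unequal probe density. An unsupervised mode finds recurrent gains
    and losses from the sample-summed signal with a permutation-derived
    family-wise significance threshold, repeated across a user-selected
    scale space of kernel widths. A supervised mode compares two sample
    classes with a regularized signal-to-noise statistic on per-sample
    smoothed profiles and controls the false discovery rate by class-label
    permutation. Includes a synthetic aCGH data generator with known truth
    regions, recovery scoring, genome-wide plots, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
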