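Package: kymowave
Title: Oscillation Analysis for Tip-Growing Cells from Kymographs and Ion-Flux Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Analysis pipeline for oscillatory dynamics in tip-growing cells
    (e.g. pollen tubes) observed through kymographs and concurrently measured
    ion-flux time series. Provides subpixel tip localization on fluorescence
    kymographs by regression on the edge profile, ratiometric (YFP/CFP)
    kymograph processing with quantile-based background subtraction and
    tip-aligned series extraction, shift-invariant discrete wavelet
    multiresolution filtering (1-D and 2-D), continuous Morlet wavelet spectra
    with red-noise significance and ridge extraction, cross-wavelet phase and
    time-resolved delay estimation between paired series, and the summary
    statistics used to characterize growth regimes (two-component Gaussian
    mixtures, Welch tests with Bonferroni correction, McNemar paired
    proportion tests, tracking-noise quantification). Includes synthetic
    kymograph and series generators with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust
Config/testthat/edition: 3
biocViews: Software, TimeCourse, CellBiology, Visualization
RoxygenNote: 7.3.3
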