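Package: ssvepTCSC
Title: Temporal Contrast Sensitivity Curves from Steady-State Visual Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives electrophysiological and psychophysical temporal contrast
    sensitivity curves (TCSC) from steady-state visual evoked potential (SSVEP)
    responses to square-wave luminance flicker. Implements square-wave stimulus
    construction and Fourier decomposition, the flicker visibility measure
    (Minkowski summation over frequency components), EEG preprocessing (notch,
    resampling, high-pass, common average reference, epoching, variance-based
    artifact rejection), spectral Cohen's d / z-score detection statistics with
    best-harmonic and best-channel selection, probit psychometric threshold
    estimation with deviance-based validity gates, rational-polynomial curve
    fitting with prediction bounds, and Wilcoxon/FDR comparison of the two
    curves. Includes a synthetic multi-subject EEG cohort generator with 1/f
    background noise, alpha activity and a probit observer, providing known
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'stimulus.R'
    'referenceTCSC.R'
    'syntheticEEG.R'
    'preprocess.R'
    'detect.R'
    'psychometric.R'
    'tcsc.R'
    'pipeline.R'
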