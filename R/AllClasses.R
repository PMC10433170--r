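#' @import methods
NULL

#' Temporal contrast sensitivity curve
#'
#' Represents a reference temporal contrast sensitivity curve (TCSC), either
#' as a cubic/linear rational polynomial
#' \deqn{S(f) = scale \cdot (p_1 f^3 + p_2 f^2 + p_3 f + p_4) / (f + q_1)}
#' or as a tabulated (frequency, sensitivity) set interpolated log-log
#' linearly. Sensitivity is the reciprocal of the Michelson modulation-depth
#' threshold, so `1/S(f)` is the just-visible modulation depth at `f`.
#'
#' @slot form `"rational"` or `"tabulated"`.
#' @slot coef named numeric (`p1`,`p2`,`p3`,`p4`,`q1`) for the rational form.
#' @slot table data.frame with columns `frequency_hz`, `sensitivity` for the
#'   tabulated form.
#' @slot domain numeric length-2, the frequency interval (Hz) on which the
#'   curve may be evaluated; no silent extrapolation outside it.
#' @slot scale multiplicative factor applied to the evaluated curve.
#' @slot label free-text identifier.
#' @export
setClass("SensitivityCurve",
  representation(form = "character", coef = "numeric", table = "data.frame",
                 domain = "numeric", scale = "numeric", label = "character"),
  prototype(form = "rational", coef = numeric(), table = data.frame(),
            domain = c(1, 60), scale = 1, label = ""))

setValidity("SensitivityCurve", function(object) {
  msg <- character()
  if (!object@form %in% c("rational", "tabulated"))
    msg <- c(msg, "form must be 'rational' or 'tabulated'")
  if (length(object@domain) != 2L || object@domain[1] >= object@domain[2])
    msg <- c(msg, "domain must be an increasing length-2 interval")
  if (object@form == "rational" &&
      !all(c("p1", "p2", "p3", "p4", "q1") %in% names(object@coef)))
    msg <- c(msg, "rational form needs coefficients p1..p4, q1")
  if (object@form == "tabulated") {
    if (!all(c("frequency_hz", "sensitivity") %in% names(object@table)))
      msg <- c(msg, "tabulated form needs columns frequency_hz, sensitivity")
    else if (any(object@table$sensitivity <= 0))
      msg <- c(msg, "tabulated sensitivities must be positive")
  }
  if (length(object@scale) != 1L || object@scale <= 0)
    msg <- c(msg, "scale must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Continuous multi-channel recording
#'
#' A channels-by-samples signal matrix with sampling rate and event markers.
#' Marker positions are 0-based sample offsets from the start of the record
#' (the convention of common acquisition systems), so a marker at offset
#' `3 * rate` has exactly 3 s of signal before it.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot rate sampling rate, Hz.
#' @slot markers data.frame with columns `sample` (0-based offset) and `label`.
#' @slot channels character vector of channel names.
#' @export
setClass("Recording",
  representation(data = "matrix", rate = "numeric", markers = "data.frame",
                 channels = "character"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a positive scalar")
  if (nrow(object@markers)) {
    if (!all(c("sample", "label") %in% names(object@markers)))
      msg <- c(msg, "markers need columns sample, label")
    else {
      if (is.unsorted(object@markers$sample))
        msg <- c(msg, "markers must be sorted by sample")
      if (any(object@markers$sample < 0) ||
          any(object@markers$sample >= ncol(object@data)))
        msg <- c(msg, "marker offsets must lie within the record")
    }
  }
  if (length(object@channels) && length(object@channels) != nrow(object@data))
    msg <- c(msg, "one channel name per data row required")
  if (length(msg)) msg else TRUE
})

#' Baseline/stimulation epoch pair for one trial
#'
#' @slot trialId integer trial identifier.
#' @slot baseline channels x samples matrix (3 s before stimulus onset).
#' @slot stimulation channels x samples matrix (3 s from stimulus onset).
#' @slot rate sampling rate, Hz.
#' @slot frequencyHz stimulation frequency (NA if unknown).
#' @slot md modulation depth (NA if unknown).
#' @slot subjectiveReport logical; `NA` when no report was collected.
#' @export
setClass("EpochPair",
  representation(trialId = "integer", baseline = "matrix",
                 stimulation = "matrix", rate = "numeric",
                 frequencyHz = "numeric", md = "numeric",
                 subjectiveReport = "logical"))

setValidity("EpochPair", function(object) {
  msg <- character()
  if (!identical(dim(object@baseline), dim(object@stimulation)))
    msg <- c(msg, "baseline and stimulation must have identical shape")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Ground-truth observer profile for the synthetic cohort
#'
#' Encodes everything the generator needs to emulate one participant: the
#' psychophysical threshold curve and probit observer (threshold, slope,
#' lapse/guess rates), the electrophysiological gain and threshold curve,
#' background-EEG shape (1/f exponent, alpha peak), and a subject seed.
#'
#' @slot subjectId character identifier.
#' @slot thetaPsy function(f) -> psychophysical MD threshold in (0, 1].
#' @slot sigmaPsy probit observer slope (MD units, as a fraction of threshold
#'   when `sigmaRelative` is TRUE).
#' @slot sigmaRelative logical; interpret `sigmaPsy` relative to threshold.
#' @slot lapse,guess lapse and guess rates in \[0, 0.1\].
#' @slot gain SSVEP spectral amplitude gain (microvolts per decade of
#'   suprathreshold log-contrast).
#' @slot thetaEeg function(f) -> electrophysiological MD threshold.
#' @slot alphaHz,alphaAmp alpha-peak frequency (Hz) and bump amplitude.
#' @slot noiseExponent spectral exponent of the 1/f background.
#' @slot noiseScale overall background amplitude scale (microvolts).
#' @slot seed integer subject seed.
#' @export
setClass("SubjectProfile",
  representation(subjectId = "character", thetaPsy = "function",
                 sigmaPsy = "numeric", sigmaRelative = "logical",
                 lapse = "numeric", guess = "numeric", gain = "numeric",
                 thetaEeg = "function", alphaHz = "numeric",
                 alphaAmp = "numeric", noiseExponent = "numeric",
                 noiseScale = "numeric", seed = "integer"))

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (object@lapse < 0 || object@lapse > 0.1 ||
      object@guess < 0 || object@guess > 0.1)
    msg <- c(msg, "lapse and guess rates must lie in [0, 0.1]")
  if (object@gain <= 0) msg <- c(msg, "gain must be positive")
  if (object@noiseScale <= 0) msg <- c(msg, "noiseScale must be positive")
  if (length(msg)) msg else TRUE
})

#' Synthetic (or ingested) epoched dataset
#'
#' @slot trials data.frame with one row per trial: `subject_id`,
#'   `experiment_id`, `trial_id`, `frequency_hz`, `md`, `subjective_report`,
#'   `seed`.
#' @slot epochs list of [EpochPair-class], keyed by `as.character(trial_id)`.
#' @slot profiles list of [SubjectProfile-class], keyed by subject id.
#' @slot groundTruth data.frame of per-subject per-frequency true thresholds
#'   (`subject_id`, `frequency_hz`, `theta_psy`, `theta_eeg`).
#' @slot seed master seed used for generation (NA for ingested data).
#' @export
setClass("FlickerDataset",
  representation(trials = "data.frame", epochs = "list", profiles = "list",
                 groundTruth = "data.frame", seed = "integer"))

setValidity("FlickerDataset", function(object) {
  msg <- character()
  need <- c("subject_id", "experiment_id", "trial_id", "frequency_hz", "md")
  if (nrow(object@trials) && !all(need %in% names(object@trials)))
    msg <- c(msg, paste("trial table needs columns:", paste(need, collapse = ", ")))
  if (length(object@epochs) && nrow(object@trials) &&
      !all(as.character(object@trials$trial_id) %in% names(object@epochs)))
    msg <- c(msg, "every trial must have an epoch entry")
  if (length(msg)) msg else TRUE
})

#' Per-condition spectral statistics
#'
#' Per-frequency-bin summaries of log-amplitude spectra for one condition:
#' baseline mean and SD, stimulation mean, pooled SD, Cohen's d, and the
#' per-stimulation-epoch z-score matrix.
#'
#' @slot bins integer frequency bins, Hz (1..128 at 256 Hz sampling).
#' @slot baselineMean,baselineSD,stimMean,pooledSD,cohensD numeric per bin.
#' @slot z matrix, stimulation epochs x bins.
#' @export
setClass("SpectrumStats",
  representation(bins = "integer", baselineMean = "numeric",
                 baselineSD = "numeric", stimMean = "numeric",
                 pooledSD = "numeric", cohensD = "numeric", z = "matrix"))

setValidity("SpectrumStats", function(object) {
  n <- length(object@bins)
  lens <- c(length(object@baselineMean), length(object@baselineSD),
            length(object@stimMean), length(object@pooledSD),
            length(object@cohensD))
  msg <- character()
  if (any(lens != n)) msg <- c(msg, "all per-bin vectors must match bins")
  if (ncol(object@z) && ncol(object@z) != n)
    msg <- c(msg, "z matrix must have one column per bin")
  if (any(object@baselineSD < 0, na.rm = TRUE) ||
      any(object@pooledSD < 0, na.rm = TRUE))
    msg <- c(msg, "standard deviations must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Probit psychometric fit
#'
#' Binomial GLM with probit link of detection probability on modulation
#' depth, with its residual deviance against the saturated model and
#' degeneracy flags.
#'
#' @slot frequencyHz stimulation frequency.
#' @slot coef named numeric `(intercept, slope)` on the probit scale.
#' @slot deviance residual deviance.
#' @slot converged,separation logical fit diagnostics.
#' @slot data data.frame (`md`, `detected`, `trials`) used for the fit.
#' @slot source `"subjective"` or `"electrophysiological"`.
#' @export
setClass("PsychometricFit",
  representation(frequencyHz = "numeric", coef = "numeric",
                 deviance = "numeric", converged = "logical",
                 separation = "logical", data = "data.frame",
                 source = "character"))

setValidity("PsychometricFit", function(object) {
  msg <- character()
  if (length(object@deviance) == 1L && is.finite(object@deviance) &&
      object@deviance < -1e-8)
    msg <- c(msg, "deviance must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Fitted rational-polynomial TCSC
#'
#' @slot coef named numeric `p1..p4`, `q1`.
#' @slot cov 5x5 coefficient covariance from the fit Jacobian.
#' @slot data data.frame (`frequency_hz`, `sensitivity`, `n`) of the pooled
#'   mean sensitivities the curve was fitted to.
#' @slot r2 coefficient of determination against mean sensitivities.
#' @slot r2Threshold same, computed on reciprocal (threshold) scale.
#' @slot sigma residual standard deviation.
#' @slot df residual degrees of freedom.
#' @slot domain fitted frequency interval.
#' @export
setClass("TCSCFit",
  representation(coef = "numeric", cov = "matrix", data = "data.frame",
                 r2 = "numeric", r2Threshold = "numeric", sigma = "numeric",
                 df = "numeric", domain = "numeric"))

setValidity("TCSCFit", function(object) {
  msg <- character()
  if (!all(c("p1", "p2", "p3", "p4", "q1") %in% names(object@coef)))
    msg <- c(msg, "coefficients p1..p4, q1 required")
  if (!identical(dim(object@cov), c(5L, 5L)))
    msg <- c(msg, "covariance must be 5x5")
  if (length(object@r2) == 1L && is.finite(object@r2) && object@r2 > 1 + 1e-12)
    msg <- c(msg, "R^2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SensitivityCurve", function(object) {
  cat(sprintf("SensitivityCurve '%s' (%s), domain [%g, %g] Hz, scale %g\n",
              object@label, object@form, object@domain[1], object@domain[2],
              object@scale))
  if (object@form == "rational")
    cat("  coefficients:", paste(sprintf("%s=%g", names(object@coef),
                                         object@coef), collapse = ", "), "\n")
  else
    cat(sprintf("  %d tabulated knots\n", nrow(object@table)))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s) x %d samples at %g Hz, %d marker(s)\n",
              nrow(object@data), ncol(object@data), object@rate,
              nrow(object@markers)))
})

setMethod("show", "EpochPair", function(object) {
  cat(sprintf(
    "EpochPair trial %d: %d ch x %d samples at %g Hz (F=%g Hz, MD=%g)\n",
    object@trialId, nrow(object@baseline), ncol(object@baseline),
    object@rate, object@frequencyHz, object@md))
})

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf(
    "SubjectProfile %s: gain %.2f uV/decade, alpha %.1f Hz, 1/f^%.2f\n",
    object@subjectId, object@gain, object@alphaHz, object@noiseExponent))
})

setMethod("show", "FlickerDataset", function(object) {
  cat(sprintf(
    "FlickerDataset: %d trial(s), %d subject(s), %d experiment(s)\n",
    nrow(object@trials), length(unique(object@trials$subject_id)),
    length(unique(object@trials$experiment_id))))
})

setMethod("show", "SpectrumStats", function(object) {
  cat(sprintf("SpectrumStats: %d bins, %d stimulation epoch(s); max d = %.3f at %d Hz\n",
              length(object@bins), nrow(object@z),
              suppressWarnings(max(object@cohensD, na.rm = TRUE)),
              object@bins[which.max(object@cohensD)]))
})

setMethod("show", "PsychometricFit", function(object) {
  cat(sprintf(
    "PsychometricFit (%s) at %g Hz: intercept %.3g, slope %.3g, deviance %.3g%s\n",
    object@source, object@frequencyHz, object@coef[1], object@coef[2],
    object@deviance, if (object@separation) " [separation]" else ""))
})

setMethod("show", "TCSCFit", function(object) {
  pk <- curvePeak(object)
  cat(sprintf("TCSCFit on [%g, %g] Hz: R^2 = %.3f, peak %.2f Hz (S = %.1f)\n",
              object@domain[1], object@domain[2], object@r2,
              pk["frequency_hz"], pk["sensitivity"]))
  cat("  coefficients:", paste(sprintf("%s=%.4g", names(object@coef),
                                       object@coef), collapse = ", "), "\n")
})

# ---- accessors ----

#' Trial table of a dataset
#' @param x a [FlickerDataset-class]
#' @return data.frame of trials
#' @export
trialTable <- function(x) {
  stopifnot(is(x, "FlickerDataset"))
  x@trials
}

#' Epoch pairs of a dataset
#' @param x a [FlickerDataset-class]
#' @param trialId optional trial id(s) to extract
#' @return list of [EpochPair-class] (or a single pair for one id)
#' @export
epochs <- function(x, trialId = NULL) {
  stopifnot(is(x, "FlickerDataset"))
  if (is.null(trialId)) return(x@epochs)
  out <- x@epochs[as.character(trialId)]
  if (length(out) == 1L) out[[1L]] else out
}

#' Ground-truth thresholds of a synthetic dataset
#' @param x a [FlickerDataset-class]
#' @return data.frame with true psychophysical and electrophysiological
#'   thresholds per subject and frequency
#' @export
groundTruth <- function(x) {
  stopifnot(is(x, "FlickerDataset"))
  x@groundTruth
}

#' Subject profiles of a synthetic dataset
#' @param x a [FlickerDataset-class]
#' @return named list of [SubjectProfile-class]
#' @export
subjectProfiles <- function(x) {
  stopifnot(is(x, "FlickerDataset"))
  x@profiles
}

#' Cohen's d spectrum of a [SpectrumStats-class]
#' @param x a [SpectrumStats-class]
#' @return named numeric vector of d per integer frequency bin
#' @export
cohensD <- function(x) {
  stopifnot(is(x, "SpectrumStats"))
  stats::setNames(x@cohensD, x@bins)
}

#' Per-epoch z-scores of a [SpectrumStats-class]
#' @param x a [SpectrumStats-class]
#' @param bin optional integer bin (Hz); if given, returns that column
#' @return matrix epochs x bins, or a numeric vector for one bin
#' @export
zScores <- function(x, bin = NULL) {
  stopifnot(is(x, "SpectrumStats"))
  if (is.null(bin)) return(x@z)
  x@z[, match(bin, x@bins)]
}
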