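# RBJ biquad notch (quality factor Q); the signal package ships no notch
# designer. Returns b, a coefficient vectors.
.notchDesign <- function(f0, rate, Q = 30) {
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * Q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

# Zero-phase filtering helpers applied row-wise to channels x samples data.
.filtfiltRows <- function(b, a, x) {
  b <- as.numeric(b)  # fir1 returns an 'Ma' object that would mis-dispatch
  t(apply(x, 1, function(ch) signal::filtfilt(b, as.numeric(a), ch)))
}

.highpassFIR <- function(rate, cutoffHz = 2, taps = 257) {
  signal::fir1(taps - 1, cutoffHz / (rate / 2), type = "high")
}

#' Condition a raw recording
#'
#' Signal conditioning chain, in order: 50 Hz notch (biquad, Q = 30,
#' zero-phase), anti-aliased resampling to `targetRate` (256 Hz), and a 2 Hz
#' high-pass FIR (Hamming window, 257 taps, zero-phase). Event marker
#' offsets are rescaled to the new rate. All filters are applied
#' forward-backward so epochs keep their temporal alignment.
#'
#' @param rec a [Recording-class] with rate >= 512 Hz.
#' @param notchHz mains frequency to attenuate.
#' @param targetRate output sampling rate, Hz.
#' @param highpassHz high-pass cutoff, Hz.
#' @return a conditioned [Recording-class] at `targetRate`.
#' @export
conditionSignal <- function(rec, notchHz = 50, targetRate = 256,
                            highpassHz = 2) {
  stopifnot(is(rec, "Recording"))
  if (rec@rate < 512)
    stop("conditionSignal needs rate >= 512 Hz (notch then downsample)")
  nt <- .notchDesign(notchHz, rec@rate)
  x <- .filtfiltRows(nt$b, nt$a, rec@data)
  factor <- rec@rate / targetRate
  if (abs(factor - round(factor)) < 1e-9) {
    factor <- round(factor)
    aa <- signal::fir1(256, 0.9 / factor)  # anti-alias low-pass
    x <- .filtfiltRows(aa, 1, x)
    x <- x[, seq(1, ncol(x), by = factor), drop = FALSE]
  } else {
    x <- t(apply(x, 1, function(ch) signal::resample(ch, targetRate, rec@rate)))
    factor <- rec@rate / targetRate
  }
  hp <- .highpassFIR(targetRate, highpassHz)
  x <- .filtfiltRows(hp, 1, x)
  markers <- rec@markers
  if (nrow(markers)) markers$sample <- floor(markers$sample / factor)
  new("Recording", data = x, rate = targetRate, markers = markers,
      channels = rec@channels)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is identically zero at each sample. A single-channel
#' recording is returned unchanged with a warning.
#'
#' @param rec a [Recording-class].
#' @return the re-referenced [Recording-class].
#' @export
commonAverageReference <- function(rec) {
  stopifnot(is(rec, "Recording"))
  if (nrow(rec@data) < 2) {
    warning("common average reference needs >= 2 channels; returning input")
    return(rec)
  }
  rec@data <- sweep(rec@data, 2, colMeans(rec@data))
  rec
}

#' Segment a recording into baseline/stimulation epoch pairs
#'
#' For each stimulus-onset marker (0-based sample offset `o`), extracts the
#' half-open windows `[o - duration, o)` (baseline) and `[o, o + duration)`
#' (stimulation), each exactly `duration * rate` samples. Onsets without a
#' full window on both sides are dropped and reported via the
#' `"dropped"` attribute.
#'
#' @param rec a [Recording-class].
#' @param duration epoch duration, s.
#' @return list of [EpochPair-class]; attribute `"dropped"` holds the labels
#'   of markers that could not be segmented.
#' @export
segmentEpochs <- function(rec, duration = 3) {
  stopifnot(is(rec, "Recording"))
  n <- round(duration * rec@rate)
  pairs <- list()
  dropped <- character()
  for (i in seq_len(nrow(rec@markers))) {
    o <- rec@markers$sample[i]   # 0-based onset offset
    lab <- rec@markers$label[i]
    if (o < n || o + n > ncol(rec@data)) {
      dropped <- c(dropped, lab)
      next
    }
    id <- suppressWarnings(as.integer(lab))
    pairs[[length(pairs) + 1L]] <- new("EpochPair",
      trialId = if (is.na(id)) i else id,
      baseline = rec@data[, (o - n + 1):o, drop = FALSE],
      stimulation = rec@data[, (o + 1):(o + n), drop = FALSE],
      rate = rec@rate, frequencyHz = NA_real_, md = NA_real_,
      subjectiveReport = NA)
  }
  attr(pairs, "dropped") <- dropped
  pairs
}

#' Variance-based artifact rejection within a condition
#'
#' For the epoch pairs of one condition, computes a per-trial broadband
#' variance (by default of the stimulation epoch at the analysis channel)
#' and rejects, in a single pass, every trial whose variance exceeds the
#' condition mean plus two standard deviations.
#'
#' @param pairs list of [EpochPair-class] belonging to one condition (>= 3).
#' @param channel analysis channel index (default 1, Pz).
#' @param epoch which epoch's variance to use: `"stimulation"` (default),
#'   `"baseline"`, or `"both"` (pooled samples of the trial).
#' @param k rejection multiplier (2 in the standard rule).
#' @return list with `kept` (surviving pairs), `rejected` (logical mask, TRUE
#'   = rejected), and `variance` (the per-trial variances).
#' @export
rejectArtifacts <- function(pairs, channel = 1L,
                            epoch = c("stimulation", "baseline", "both"),
                            k = 2) {
  epoch <- match.arg(epoch)
  if (length(pairs) < 3) stop("artifact rejection needs >= 3 trials per condition")
  v <- vapply(pairs, function(p) {
    x <- switch(epoch,
                stimulation = p@stimulation[channel, ],
                baseline = p@baseline[channel, ],
                both = c(p@baseline[channel, ], p@stimulation[channel, ]))
    stats::var(x)
  }, numeric(1))
  bad <- v > mean(v) + k * stats::sd(v)
  if (all(bad)) stop("artifact rejection removed every trial of the condition")
  list(kept = pairs[!bad], rejected = bad, variance = v)
}

#' Hook for external ocular-artifact removal
#'
#' Ocular (blink) artifact removal by independent component analysis is out
#' of scope here (the synthetic data contain no blinks); this hook applies a
#' user-supplied callable `fun(Recording) -> Recording` at the point in the
#' chain where component removal belongs (after conditioning, before
#' re-referencing), validating the result.
#'
#' @param rec a [Recording-class].
#' @param fun function taking and returning a [Recording-class]; `NULL`
#'   leaves the recording untouched.
#' @return a [Recording-class].
#' @export
removeOcularArtifacts <- function(rec, fun = NULL) {
  if (is.null(fun)) return(rec)
  out <- fun(rec)
  if (!is(out, "Recording") || !identical(dim(out@data), dim(rec@data)))
    stop("ocular-removal hook must return a Recording of identical shape")
  out
}
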