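#' Log-amplitude spectrum of one epoch
#'
#' Splits a 3-s epoch into three non-overlapping 1-s rectangular windows,
#' takes the FFT amplitude spectrum of each (1 Hz resolution), and returns
#' the log10 of the mean amplitude over the windows at the integer bins
#' 1..rate/2 Hz.
#'
#' @param x numeric vector, one channel of one epoch (`3 * rate` samples).
#' @param rate sampling rate, Hz (256 in the analysis chain, giving 128 bins).
#' @return named numeric vector of log10 mean amplitudes, names = bin (Hz).
#' @export
epochSpectrum <- function(x, rate = 256) {
  n <- round(3 * rate)
  if (length(x) != n)
    stop("epochSpectrum expects a 3-s epoch (", n, " samples at ", rate, " Hz)")
  half <- rate / 2
  amps <- vapply(0:2, function(w) {
    seg <- x[(w * rate + 1):((w + 1) * rate)]
    Mod(stats::fft(seg))[2:(half + 1)] * 2 / rate
  }, numeric(half))
  m <- rowMeans(amps)
  stats::setNames(log10(pmax(m, .Machine$double.xmin)), seq_len(half))
}

# Epoch x bin matrix of log-spectra for a list of pairs.
.spectraMatrix <- function(pairs, which = c("stimulation", "baseline"),
                           channel = 1L) {
  which <- match.arg(which)
  rate <- pairs[[1]]@rate
  t(vapply(pairs, function(p) {
    x <- if (which == "stimulation") p@stimulation[channel, ] else p@baseline[channel, ]
    epochSpectrum(x, rate)
  }, numeric(rate / 2)))
}

#' Cohen's d between stimulation and baseline spectra
#'
#' Per-bin standardised mean difference
#' `d(f) = (mean_S(f) - mean_B(f)) / sd_pooled(f)` with the pooled standard
#' deviation `sqrt(((nS-1) sS^2 + (nB-1) sB^2) / (nS + nB - 2))`. Bins with
#' zero pooled SD get d = 0 with a warning.
#'
#' @param stimSpectra,baseSpectra matrices (epochs x bins) of log-amplitude
#'   spectra, >= 2 rows each.
#' @return named numeric vector of d per bin.
#' @export
cohensDSpectrum <- function(stimSpectra, baseSpectra) {
  if (nrow(stimSpectra) < 2 || nrow(baseSpectra) < 2)
    stop("Cohen's d needs >= 2 epochs per group")
  nS <- nrow(stimSpectra); nB <- nrow(baseSpectra)
  mS <- colMeans(stimSpectra); mB <- colMeans(baseSpectra)
  vS <- apply(stimSpectra, 2, stats::var)
  vB <- apply(baseSpectra, 2, stats::var)
  pooled <- sqrt(((nS - 1) * vS + (nB - 1) * vB) / (nS + nB - 2))
  d <- (mS - mB) / pooled
  if (any(pooled == 0)) {
    warning("zero pooled SD at ", sum(pooled == 0), " bin(s); d set to 0")
    d[pooled == 0] <- 0
  }
  d
}

#' Spectral statistics of one condition
#'
#' Aggregates the baseline and stimulation log-spectra of a condition's
#' epoch pairs into a [SpectrumStats-class]: per-bin means and SDs, pooled
#' SD, Cohen's d, and the per-stimulation-epoch z-score matrix
#' `z_i(f) = (x_Si(f) - mean_B(f)) / sd_B(f)`.
#'
#' @param pairs list of [EpochPair-class] for one condition (>= 2).
#' @param channel analysis channel index.
#' @return a [SpectrumStats-class].
#' @export
conditionStats <- function(pairs, channel = 1L) {
  S <- .spectraMatrix(pairs, "stimulation", channel)
  B <- .spectraMatrix(pairs, "baseline", channel)
  bins <- as.integer(colnames(S) <- colnames(B) <- seq_len(ncol(S)))
  mB <- colMeans(B); sB <- apply(B, 2, stats::sd)
  d <- cohensDSpectrum(S, B)
  nS <- nrow(S); nB <- nrow(B)
  pooled <- sqrt(((nS - 1) * apply(S, 2, stats::var) +
                    (nB - 1) * apply(B, 2, stats::var)) / (nS + nB - 2))
  z <- sweep(sweep(S, 2, mB), 2, sB, "/")
  new("SpectrumStats", bins = bins, baselineMean = mB, baselineSD = sB,
      stimMean = colMeans(S), pooledSD = pooled, cohensD = unname(d), z = z)
}

#' Best harmonic component for a stimulation frequency
#'
#' The harmonic `h` in 1..10 with `h * F` below the Nyquist bin (128 Hz)
#' maximising Cohen's d at bin `h * F`; ties resolve to the smaller h. The d
#' spectrum should come from trials predicted visible by the flicker
#' visibility measure, so low sub-threshold MDs do not bias the choice.
#'
#' @param d named numeric d spectrum over integer bins (names = Hz).
#' @param frequencyHz stimulation frequency F.
#' @param hMax highest harmonic considered.
#' @param nyquistHz exclusive upper bin bound.
#' @return list with `h`, `bin` (= h * F), and `candidates` (data.frame of
#'   all considered harmonics with their d).
#' @export
bestHarmonic <- function(d, frequencyHz, hMax = 10L, nyquistHz = 128) {
  h <- seq_len(hMax)
  h <- h[h * frequencyHz < nyquistHz]
  if (!length(h)) stop("no harmonic of ", frequencyHz, " Hz below ", nyquistHz, " Hz")
  bins <- h * frequencyHz
  dh <- d[as.character(bins)]
  best <- h[order(-dh, h)][1]
  list(h = best, bin = best * frequencyHz,
       candidates = data.frame(h = h, bin = bins, d = unname(dh)))
}

#' Best channel at the selected harmonic bin
#'
#' Given per-channel Cohen's d values at the selected harmonic bin, returns
#' the maximising channel (ties resolve to the first in canonical order) and
#' the full ranking.
#'
#' @param dByChannel named numeric vector, d per channel at the selected bin.
#' @return list with `channel` and a `ranking` data.frame.
#' @export
bestChannel <- function(dByChannel) {
  if (!length(dByChannel)) stop("no channels supplied")
  ord <- order(-dByChannel, seq_along(dByChannel))
  list(channel = names(dByChannel)[ord[1]],
       ranking = data.frame(channel = names(dByChannel)[ord],
                            d = unname(dByChannel[ord])))
}

#' Per-epoch z-scores at a bin
#'
#' `z_i = (x_Si(bin) - mean_B(bin)) / sd_B(bin)` for each stimulation epoch
#' `i`, against the baseline mean and SD of the same condition.
#'
#' @param stimSpectra matrix epochs x bins of stimulation log-spectra.
#' @param baselineMean,baselineSD per-bin baseline statistics.
#' @param bin integer bin (Hz).
#' @return numeric vector of z-scores, one per stimulation epoch.
#' @export
zscoreEpochs <- function(stimSpectra, baselineMean, baselineSD, bin) {
  j <- match(as.character(bin), colnames(stimSpectra))
  if (is.na(j)) stop("bin ", bin, " not present in the spectra")
  if (baselineSD[j] <= 0) stop("baseline SD is zero at bin ", bin)
  (stimSpectra[, j] - baselineMean[j]) / baselineSD[j]
}

#' SSVEP detection from z-scores
#'
#' A trial counts as a detectable SSVEP response iff its z-score at the best
#' harmonic bin is strictly positive; the condition's detection probability
#' is the fraction of (non-rejected) trials detected.
#'
#' @param z numeric z-scores at the best harmonic bin.
#' @return list with `responses` (0/1 per trial) and `probability`.
#' @export
detectSSVEP <- function(z) {
  r <- as.integer(z > 0)
  list(responses = r, probability = if (length(r)) mean(r) else NA_real_)
}

#' Frequency-level quality control
#'
#' Checks that a stimulation frequency's effect is anchored at its expected
#' response frequencies: for each subject, the global argmax bin of the d
#' spectrum over `binRange` is computed, and the frequency is kept only if
#' the fraction of subjects whose argmax falls exactly on an expected
#' harmonic bin (`h * F`) is at least `alignFraction` AND the mean (over
#' subjects) of d at the best harmonic is at least `minMeanD`. A noise-only
#' condition shows a uniform argmax pattern and fails the alignment rule —
#' the behaviour that excluded the 7 Hz condition in the study design.
#'
#' @param dSpectra list of named numeric d spectra, one per subject.
#' @param frequencyHz stimulation frequency under test.
#' @param binRange inclusive bin range searched for the global argmax.
#' @param alignFraction minimal aligned fraction (>= rule; default 0.25).
#' @param minMeanD minimal mean best-harmonic d (>= rule; default 0.05).
#' @return list with `include`, `fraction`, `meanBestD`, `argmaxBins`,
#'   `expectedBins`.
#' @export
qcFrequency <- function(dSpectra, frequencyHz, binRange = c(3, 127),
                        alignFraction = 0.25, minMeanD = 0.05) {
  h <- seq_len(10)
  expected <- h[h * frequencyHz <= binRange[2]] * frequencyHz
  expected <- expected[expected >= binRange[1]]
  argmax <- vapply(dSpectra, function(d) {
    bins <- as.integer(names(d))
    keep <- bins >= binRange[1] & bins <= binRange[2]
    bins[keep][which.max(d[keep])]
  }, numeric(1))
  bestD <- vapply(dSpectra, function(d) max(d[as.character(expected)]), numeric(1))
  fraction <- mean(argmax %in% expected)
  meanBestD <- mean(bestD)
  list(include = fraction >= alignFraction && meanBestD >= minMeanD,
       fraction = fraction, meanBestD = meanBestD,
       argmaxBins = unname(argmax), expectedBins = expected)
}
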