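# Independent brute-force DFT amplitude at integer bin f (Hz) of a 1-s
# window sampled at `rate`; used to cross-check the FFT-based spectra.
dftAmplitude <- function(x, f, rate) {
  n <- length(x)
  t <- seq_len(n) - 1
  re <- sum(x * cos(-2 * pi * f * t / n))
  im <- sum(x * sin(-2 * pi * f * t / n))
  sqrt(re^2 + im^2) * 2 / rate
}

# Oracle for epochSpectrum at one bin: mean over the three 1-s windows.
epochSpectrumOracle <- function(x, f, rate = 256) {
  amps <- vapply(0:2, function(w)
    dftAmplitude(x[(w * rate + 1):((w + 1) * rate)], f, rate), numeric(1))
  log10(mean(amps))
}

# Exhaustive two-sided rank-sum p-value by enumerating all splits.
ranksumExact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  ws <- apply(splits, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}

# Plain-noise epoch pair (no SSVEP structure) for null / rejection tests.
noisePair <- function(seed, n = 768, rate = 256, sd = 1, trialId = 1L) {
  set.seed(seed)
  new("EpochPair", trialId = as.integer(trialId),
      baseline = matrix(rnorm(n, sd = sd), 1),
      stimulation = matrix(rnorm(n, sd = sd), 1),
      rate = rate, frequencyHz = NA_real_, md = NA_real_,
      subjectiveReport = NA)
}

testProfile <- function(seed = 42, ...) subjectProfile("T", seed, ...)
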