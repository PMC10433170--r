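# Frequency-dependent ratio between electrophysiological and psychophysical
# thresholds in the synthetic observer: above 1 below ~50 Hz (EEG less
# sensitive than behaviour), below 1 at 60 Hz (SSVEP detectable without
# percept), emulating the crossing of the two sensitivity curves.
.kappaEeg <- function(f) 1.8 - 1.1 * pmin(1, pmax(0, (f - 45) / 15))

#' Construct a synthetic observer profile
#'
#' Ground-truth observer for the synthetic cohort. Psychophysical thresholds
#' follow a reference sensitivity curve with a per-subject multiplicative
#' jitter; electrophysiological thresholds are a frequency-dependent multiple
#' of the psychophysical ones (larger below 50 Hz, smaller at 60 Hz).
#'
#' @param subjectId identifier.
#' @param seed integer subject seed; the jitters and all trial seeds derive
#'   from it.
#' @param referenceCurve [SensitivityCurve-class] defining the threshold
#'   shape (default [defaultReferenceCurve()]).
#' @param gain SSVEP amplitude gain, microvolts per decade of suprathreshold
#'   log-contrast (see [ssvepAmplitude()]).
#' @param sigmaPsy probit observer slope as a fraction of the threshold.
#' @param lapse,guess lapse and guess rates.
#' @param alphaHz,alphaAmp alpha-peak frequency (Hz) and amplitude (uV).
#' @param noiseExponent exponent of the 1/f background amplitude spectrum.
#' @param noiseScale background amplitude scale (uV at 1 Hz).
#' @param thresholdJitterSD SD of the log-normal per-subject threshold jitter.
#' @return a [SubjectProfile-class].
#' @export
subjectProfile <- function(subjectId, seed,
                           referenceCurve = defaultReferenceCurve(),
                           gain = 8, sigmaPsy = 0.25, lapse = 0.02,
                           guess = 0.02, alphaHz = NULL, alphaAmp = 4,
                           noiseExponent = 1, noiseScale = 10,
                           thresholdJitterSD = 0.1) {
  seed <- as.integer(seed)
  draws <- withSeed(seed, list(jitter = exp(stats::rnorm(1, 0, thresholdJitterSD)),
                               alpha = stats::runif(1, 8.5, 11.5)))
  if (is.null(alphaHz)) alphaHz <- draws$alpha
  jit <- draws$jitter
  force(referenceCurve)
  thetaPsy <- function(f) pmin(1, jit * curveThreshold(referenceCurve, f))
  thetaEeg <- function(f) pmin(1, .kappaEeg(f) * thetaPsy(f))
  new("SubjectProfile", subjectId = as.character(subjectId),
      thetaPsy = thetaPsy, sigmaPsy = sigmaPsy, sigmaRelative = TRUE,
      lapse = lapse, guess = guess, gain = gain, thetaEeg = thetaEeg,
      alphaHz = alphaHz, alphaAmp = alphaAmp, noiseExponent = noiseExponent,
      noiseScale = noiseScale, seed = seed)
}

#' Synthetic background EEG
#'
#' Random-phase noise whose amplitude spectrum is proportional to
#' `1/f^noiseExponent` for f >= 1 Hz (zero below 1 Hz and at DC, so the
#' signal has zero mean), plus a Gaussian alpha bump (SD 2 Hz) at the
#' subject's alpha frequency. Phases are the only random element, so a long
#' realisation's periodogram recovers the target spectral slope exactly.
#'
#' @param duration seconds.
#' @param rate samples per second.
#' @param profile a [SubjectProfile-class].
#' @param seed integer seed (determinism contract: same seed, same signal).
#' @return numeric vector of `duration * rate` samples (microvolts).
#' @export
synthBackground <- function(duration, rate, profile, seed) {
  n <- round(duration * rate)
  half <- floor(n / 2)
  f <- seq_len(half - 1) / duration
  amp <- ifelse(f >= 1, profile@noiseScale / f^profile@noiseExponent, 0) +
    profile@alphaAmp * exp(-(f - profile@alphaHz)^2 / (2 * 2^2))
  phi <- withSeed(seed, stats::runif(half - 1, 0, 2 * pi))
  spec <- complex(modulus = amp * n / 2, argument = phi)
  full <- complex(real = numeric(n))
  full[2:half] <- spec
  full[n:(n - half + 2)] <- Conj(spec)
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' SSVEP harmonic amplitudes of the synthetic observer
#'
#' Total response amplitude grows linearly with log contrast once the
#' modulation depth passes the response-onset point:
#' `A = gain * max(0, log10(MD / thetaEeg(F)) + c0)`. The default onset
#' offset `c0 = -0.15` places the onset knee slightly above the nominal
#' threshold `thetaEeg`; it is calibrated so that the 50% point of a probit
#' fitted to the z > 0 detection probabilities (whose floor under the null
#' is 0.5) coincides with `thetaEeg` — i.e. the stored ground truth is the
#' quantity the detection pipeline estimates (see the package vignette). The amplitude is distributed over
#' harmonics `h * F < 128` Hz: for F < 20 Hz the dominant weight sits on the
#' even harmonic closest to 40 Hz (ties resolved to the smaller h),
#' reproducing the empirical preference for even gamma-band harmonics at low
#' stimulation frequencies; for F >= 20 Hz the fundamental dominates.
#'
#' @param profile a [SubjectProfile-class].
#' @param frequencyHz stimulation frequency F, Hz.
#' @param md modulation depth in \[0, 1\].
#' @param c0 onset offset in decades (default -0.15, calibrated).
#' @return data.frame with columns `h`, `frequency_hz`, `amplitude` (uV);
#'   weights sum to 1 so amplitudes sum to A.
#' @export
ssvepAmplitude <- function(profile, frequencyHz, md, c0 = -0.15) {
  stopifnot(md >= 0, md <= 1)
  h <- seq_len(10)
  h <- h[h * frequencyHz < 128]
  if (!length(h)) stop("no harmonic below 128 Hz for F = ", frequencyHz)
  if (md <= 0) {
    return(data.frame(h = h, frequency_hz = h * frequencyHz,
                      amplitude = numeric(length(h))))
  }
  total <- profile@gain * max(0, log10(md / profile@thetaEeg(frequencyHz)) + c0)
  if (frequencyHz >= 20) {
    hBest <- 1L
  } else {
    even <- h[h %% 2 == 0]
    dist <- abs(even * frequencyHz - 40)
    hBest <- even[order(dist, even)][1]
  }
  w <- 0.4 / h
  w[h == hBest] <- 0
  w <- if (sum(w) > 0) 0.4 * w / sum(w) else w
  w[h == hBest] <- 0.6
  w <- w / sum(w)
  data.frame(h = h, frequency_hz = h * frequencyHz, amplitude = total * w)
}

.psychObserverP <- function(profile, frequencyHz, md) {
  th <- profile@thetaPsy(frequencyHz)
  sig <- if (profile@sigmaRelative) profile@sigmaPsy * th else profile@sigmaPsy
  profile@guess + (1 - profile@guess - profile@lapse) *
    stats::pnorm((md - th) / sig)
}

.ssvepSignal <- function(profile, frequencyHz, md, rate, duration, phases) {
  t <- (seq_len(round(duration * rate)) - 1) / rate
  amps <- ssvepAmplitude(profile, frequencyHz, md)
  sig <- numeric(length(t))
  for (i in seq_len(nrow(amps)))
    sig <- sig + amps$amplitude[i] *
      sin(2 * pi * amps$frequency_hz[i] * t + phases[i])
  sig
}

#' Synthesise one trial
#'
#' One baseline/stimulation epoch pair: the baseline is background EEG only;
#' the stimulation epoch adds the SSVEP harmonic series with random phases.
#' The subjective report is a Bernoulli draw from the observer's probit
#' psychometric function (`guess + (1 - guess - lapse) * Phi((MD - theta) /
#' sigma)`).
#'
#' @param profile a [SubjectProfile-class].
#' @param frequencyHz,md stimulation condition.
#' @param seed integer trial seed.
#' @param rate sampling rate (256 generates analysis-ready epochs directly).
#' @param duration epoch duration, s.
#' @param trialId integer id stored in the pair.
#' @param nChannels number of EEG channels (1 = Pz only; more channels get
#'   scaled SSVEP copies and independent backgrounds, for exercising CAR and
#'   best-channel selection).
#' @param collectReport logical; FALSE yields `NA` (no report collected).
#' @return an [EpochPair-class].
#' @export
synthTrial <- function(profile, frequencyHz, md, seed, rate = 256,
                       duration = 3, trialId = 1L, nChannels = 1L,
                       collectReport = TRUE) {
  gains <- .channelGains(nChannels)
  phases <- withSeed(deriveSeed(seed, 7L), stats::runif(10, 0, 2 * pi))
  n <- round(duration * rate)
  base <- matrix(0, nChannels, n)
  stim <- matrix(0, nChannels, n)
  ssvep <- .ssvepSignal(profile, frequencyHz, md, rate, duration, phases)
  for (ch in seq_len(nChannels)) {
    base[ch, ] <- synthBackground(duration, rate, profile,
                                  deriveSeed(seed, 2L * ch))
    stim[ch, ] <- synthBackground(duration, rate, profile,
                                  deriveSeed(seed, 2L * ch + 1L)) +
      gains[ch] * ssvep
  }
  report <- NA
  if (collectReport) {
    p <- .psychObserverP(profile, frequencyHz, md)
    report <- withSeed(deriveSeed(seed, 3L), stats::runif(1)) < p
  }
  new("EpochPair", trialId = as.integer(trialId), baseline = base,
      stimulation = stim, rate = rate, frequencyHz = frequencyHz, md = md,
      subjectiveReport = report)
}

# Pz carries the full SSVEP; other channels get strongly attenuated copies
# (parieto-occipital falloff), so the best-channel rule has a well-defined
# answer.
.channelGains <- function(nChannels) {
  if (nChannels == 1L) return(1)
  c(1, 0.3 * exp(-seq_len(nChannels - 1) / 5))
}

.channelNames <- function(nChannels) {
  if (nChannels == 1L) return("Pz")
  c("Pz", paste0("ch", seq_len(nChannels - 1)))
}

#' Synthesise one trial as a continuous recording
#'
#' Full-rate variant for exercising the preprocessing chain: a padded record
#' (`pad` + 3 s baseline + 3 s stimulation + `pad`) at `rate` (2048 Hz in the
#' study design) with a stimulus-onset marker, to be passed through
#' [conditionSignal()] and [segmentEpochs()].
#'
#' @inheritParams synthTrial
#' @param pad padding seconds on each side (absorbs filter transients).
#' @return a [Recording-class] with one marker at the stimulus onset and the
#'   trial id as its label.
#' @export
synthTrialRecording <- function(profile, frequencyHz, md, seed, rate = 2048,
                                duration = 3, pad = 1, trialId = 1L,
                                nChannels = 1L) {
  total <- pad + 2 * duration + pad
  n <- round(total * rate)
  phases <- withSeed(deriveSeed(seed, 7L), stats::runif(10, 0, 2 * pi))
  gains <- .channelGains(nChannels)
  onset <- round((pad + duration) * rate)  # 0-based offset of stimulation
  idx <- onset + seq_len(round(duration * rate))
  dat <- matrix(0, nChannels, n)
  ssvep <- .ssvepSignal(profile, frequencyHz, md, rate, duration, phases)
  for (ch in seq_len(nChannels)) {
    dat[ch, ] <- synthBackground(total, rate, profile, deriveSeed(seed, 2L * ch))
    dat[ch, idx] <- dat[ch, idx] + gains[ch] * ssvep
  }
  new("Recording", data = dat, rate = rate,
      markers = data.frame(sample = onset, label = as.character(trialId)),
      channels = .channelNames(nChannels))
}

#' Default generation configuration
#'
#' The study-design defaults: all four experiments, the published cohort
#' sizes (10/12/24/16), 10 repetitions per condition, acquisition at 2048 Hz
#' (set `rate = 256` for the fast mode that synthesises analysis-ready
#' epochs directly), single channel (Pz).
#'
#' @param ... overrides of the default fields.
#' @return named list.
#' @export
datasetConfig <- function(...) {
  cfg <- list(experiments = 1:4, cohortSizes = cohortSizes(),
              repetitions = 10L, rate = 2048, nChannels = 1L,
              referenceCurve = defaultReferenceCurve(),
              gain = 8, sigmaPsy = 0.25, lapse = 0.02, guess = 0.02,
              noiseExponent = 1, noiseScale = 10, alphaAmp = 4)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a synthetic multi-subject dataset
#'
#' Builds the full cohort: per experiment, a set of observer profiles, the
#' experiment's condition grid, and `repetitions` trials per condition in a
#' per-subject randomised order. Everything is reproducible from
#' `masterSeed` through a master -> subject -> trial seed hierarchy, and the
#' ground-truth thresholds are stored alongside the epochs.
#'
#' @param config list as from [datasetConfig()].
#' @param masterSeed integer.
#' @return a [FlickerDataset-class].
#' @export
generateDataset <- function(config = datasetConfig(), masterSeed = 1L) {
  masterSeed <- as.integer(masterSeed)
  ref <- config$referenceCurve
  trials <- list()
  epochs <- list()
  profiles <- list()
  gt <- list()
  trialCounter <- 0L
  for (e in config$experiments) {
    eId <- as.character(e)
    nSub <- config$cohortSizes[[eId]]
    conds <- experimentConditions(e, referenceCurve = ref,
                                  repetitions = config$repetitions)
    hasReports <- e != 1L  # no subjective reports were collected in exp 1
    for (s in seq_len(nSub)) {
      sid <- sprintf("S%s_%02d", eId, s)
      sSeed <- deriveSeed(masterSeed, 1000L * e + s)
      prof <- subjectProfile(sid, sSeed, referenceCurve = ref,
                             gain = config$gain, sigmaPsy = config$sigmaPsy,
                             lapse = config$lapse, guess = config$guess,
                             noiseExponent = config$noiseExponent,
                             noiseScale = config$noiseScale,
                             alphaAmp = config$alphaAmp)
      profiles[[sid]] <- prof
      freqs <- unique(conds$frequency_hz)
      gt[[sid]] <- data.frame(subject_id = sid, frequency_hz = freqs,
                              theta_psy = prof@thetaPsy(freqs),
                              theta_eeg = prof@thetaEeg(freqs))
      condIdx <- rep(seq_len(nrow(conds)), times = conds$repetitions)
      ord <- withSeed(deriveSeed(sSeed, 11L), sample(length(condIdx)))
      condIdx <- condIdx[ord]
      for (k in seq_along(condIdx)) {
        trialCounter <- trialCounter + 1L
        cnd <- conds[condIdx[k], ]
        tSeed <- deriveSeed(sSeed, 100L + k)
        pair <- .synthPair(prof, cnd$frequency_hz, cnd$md, tSeed,
                           config$rate, trialCounter, config$nChannels,
                           hasReports)
        epochs[[as.character(trialCounter)]] <- pair
        trials[[trialCounter]] <- data.frame(
          subject_id = sid, experiment_id = e, trial_id = trialCounter,
          frequency_hz = cnd$frequency_hz, md = cnd$md,
          subjective_report = pair@subjectiveReport, seed = tSeed)
      }
    }
  }
  new("FlickerDataset", trials = do.call(rbind, trials), epochs = epochs,
      profiles = profiles, groundTruth = do.call(rbind, gt),
      seed = masterSeed)
}

# Fast mode synthesises 256 Hz epochs directly; the full-rate mode runs the
# complete conditioning + epoching chain on a padded 2048 Hz record.
.synthPair <- function(profile, frequencyHz, md, seed, rate, trialId,
                       nChannels, collectReport) {
  if (rate == 256) {
    return(synthTrial(profile, frequencyHz, md, seed, rate = 256,
                      trialId = trialId, nChannels = nChannels,
                      collectReport = collectReport))
  }
  rec <- synthTrialRecording(profile, frequencyHz, md, seed, rate = rate,
                             trialId = trialId, nChannels = nChannels)
  rec <- conditionSignal(rec)
  if (nChannels > 1L) rec <- commonAverageReference(rec)
  pair <- segmentEpochs(rec)[[1]]
  pair@trialId <- as.integer(trialId)
  pair@frequencyHz <- frequencyHz
  pair@md <- md
  pair@subjectiveReport <- if (collectReport) {
    p <- .psychObserverP(profile, frequencyHz, md)
    withSeed(deriveSeed(seed, 3L), stats::runif(1)) < p
  } else NA
  validObject(pair)
  pair
}

#' Export a trial table / ground truth
#'
#' @param dataset a [FlickerDataset-class].
#' @param path output file (CSV for trials, JSON for ground truth).
#' @return the path, invisibly.
#' @export
writeTrialTable <- function(dataset, path) {
  utils::write.csv(trialTable(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
writeGroundTruth <- function(dataset, path) {
  jsonlite::write_json(groundTruth(dataset), path, digits = NA)
  invisible(path)
}
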