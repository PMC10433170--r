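#' Michelson modulation depth
#'
#' Michelson contrast of a periodic luminance stimulus,
#' `MD = (Lmax - Lmin) / (Lmax + Lmin)`, dimensionless in \[0, 1\].
#'
#' @param lMax,lMin maximum and minimum luminance (same units, >= 0).
#' @return modulation depth in \[0, 1\].
#' @examples
#' michelsonMD(1026, 974)  # 0.026
#' @export
michelsonMD <- function(lMax, lMin) {
  if (any(lMin < 0) || any(lMax <= 0)) stop("luminance must be nonnegative with lMax > 0")
  if (any(lMax < lMin)) stop("lMax must be >= lMin")
  (lMax - lMin) / (lMax + lMin)
}

#' Square-wave luminance waveform
#'
#' Builds the photometric stimulus
#' `L(t) = AvgLL * (1 + square(2*pi*t*F) * MD)`, where `square` is the
#' unit-amplitude square wave `sgn(sin(2*pi*t*F))` with `sgn(0)` taken as +1
#' (half-open duty convention; affects at most two samples per cycle).
#'
#' @param frequencyHz stimulation frequency F, Hz (must be below Nyquist).
#' @param md modulation depth in \[0, 1\].
#' @param avgLL mean luminance, lux.
#' @param duration seconds.
#' @param rate samples per second.
#' @return list with `samples` (lux), `rate`, `duration`, `avgLL`,
#'   `frequencyHz`, `md`.
#' @examples
#' w <- squareWaveform(6, 0.026, 1000, 3, 2048)
#' range(w$samples)  # 974 1026
#' @export
squareWaveform <- function(frequencyHz, md, avgLL, duration, rate) {
  if (md < 0 || md > 1) stop("md must lie in [0, 1]")
  if (frequencyHz >= rate / 2) stop("frequencyHz must be below the Nyquist frequency")
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  s <- sin(2 * pi * t * frequencyHz)
  sq <- ifelse(s >= 0, 1, -1)
  list(samples = avgLL * (1 + sq * md), rate = rate, duration = duration,
       avgLL = avgLL, frequencyHz = frequencyHz, md = md)
}

#' Fourier components of an ideal square wave
#'
#' The square wave of modulation depth `MD` has only odd harmonics, with
#' amplitude relative to the DC level `C_m = (4/pi) * MD / m`. Components are
#' returned for odd `m` with `m * F <= fCap`; even harmonics (amplitude 0)
#' are omitted.
#'
#' @param md modulation depth in \[0, 1\].
#' @param frequencyHz fundamental frequency F, Hz.
#' @param fCap highest component frequency to retain, Hz (> F).
#' @return data.frame with columns `m`, `frequency_hz`, `amplitude` (C_m).
#' @examples
#' squareFourierComponents(0.026, 6, 60)
#' @export
squareFourierComponents <- function(md, frequencyHz, fCap) {
  if (md < 0 || md > 1) stop("md must lie in [0, 1]")
  if (fCap < frequencyHz) stop("fCap must not lie below the fundamental frequency")
  m <- seq(1, floor(fCap / frequencyHz), by = 2)
  data.frame(m = m, frequency_hz = m * frequencyHz,
             amplitude = (4 / pi) * md / m)
}

# Frequency sets per experiment (study design). Experiment 4 uses a larger
# multiplier fan, with its own set at 4 Hz.
.expFrequencies <- list(`1` = c(8, 24, 32, 40, 48),
                        `2` = c(6, 24, 32, 40, 60),
                        `3` = c(7, 13, 19, 37, 48, 60),
                        `4` = c(4, 6, 8, 13, 19))
.expMultipliers <- list(`1` = c(0.6, 0.8, 1.0, 1.2, 1.4),
                        `3` = c(0.6, 0.8, 1.0, 1.2, 1.4),
                        `4` = c(0.8, 1.6, 3.2, 6.4, 9.6, 12.8))
.exp4At4Hz <- c(0.4, 0.8, 1.6, 3.2, 4.8, 6.4)
.exp2AbsoluteMDs <- c(0.002, 0.008, 0.014, 0.020, 0.026)

#' Cohort sizes of the four flicker experiments
#'
#' Number of participants per experiment in the study design the synthetic
#' cohort generator emulates (10, 12, 24, 16; 62 in total).
#'
#' @return named integer vector, one entry per experiment.
#' @export
cohortSizes <- function() c(`1` = 10L, `2` = 12L, `3` = 24L, `4` = 16L)

#' Stimulation conditions of one experiment
#'
#' Builds the (frequency, modulation depth) grid of an experiment.
#' Experiment 2 uses absolute modulation depths; experiments 1, 3 and 4 use
#' multipliers of the reference-curve visibility threshold at each frequency
#' (experiment 4 with a dedicated multiplier set at 4 Hz). Relative MDs are
#' `multiplier / sensitivity(f)`, clamped to 1.
#'
#' @param experimentId 1, 2, 3 or 4.
#' @param referenceCurve a [SensitivityCurve-class]; required for the
#'   relative-MD experiments (1, 3, 4).
#' @param repetitions trials per condition (10 in the study design).
#' @return data.frame with columns `experiment_id`, `frequency_hz`, `md`,
#'   `md_rule`, `multiplier`, `repetitions`.
#' @export
experimentConditions <- function(experimentId, referenceCurve = NULL,
                                 repetitions = 10L) {
  id <- as.character(experimentId)
  if (!id %in% c("1", "2", "3", "4")) stop("unknown experiment id: ", experimentId)
  freqs <- .expFrequencies[[id]]
  if (id == "2") {
    out <- expand.grid(frequency_hz = freqs, md = .exp2AbsoluteMDs)
    out$md_rule <- "absolute"
    out$multiplier <- NA_real_
  } else {
    if (is.null(referenceCurve))
      stop("experiment ", id, " uses threshold-relative MDs; supply a reference curve")
    rows <- lapply(freqs, function(f) {
      mult <- if (id == "4" && f == 4) .exp4At4Hz else .expMultipliers[[id]]
      data.frame(frequency_hz = f, md = pmin(1, mult * curveThreshold(referenceCurve, f)),
                 md_rule = "relative-to-threshold", multiplier = mult)
    })
    out <- do.call(rbind, rows)
  }
  out <- cbind(experiment_id = as.integer(id), out,
               repetitions = as.integer(repetitions))
  rownames(out) <- NULL
  stopifnot(all(out$md >= 0 & out$md <= 1))
  out[order(out$frequency_hz, out$md), , drop = FALSE]
}

#' Write / read a condition table
#'
#' CSV round-trip for condition grids (columns `experiment_id`,
#' `frequency_hz`, `md`, `md_rule`, `multiplier`, `repetitions`).
#'
#' @param conditions data.frame as returned by [experimentConditions()].
#' @param path file path.
#' @return `readConditions` returns the condition data.frame.
#' @export
writeConditions <- function(conditions, path) {
  utils::write.csv(conditions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConditions
#' @export
readConditions <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "frequency_hz", "md", "md_rule", "multiplier",
            "repetitions")
  if (!all(need %in% names(out)))
    stop("condition file must have columns: ", paste(need, collapse = ", "))
  out
}
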