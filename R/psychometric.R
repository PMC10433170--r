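#' Fit a probit psychometric function
#'
#' Binomial GLM with probit link of detection counts on modulation depth:
#' `probit(p) = b0 + b1 * MD` (or on log10 MD with `logMD = TRUE`), by
#' maximum likelihood. The residual deviance against the saturated model is
#' the goodness-of-fit statistic gating threshold validity. Perfect
#' separation (all detected / none detected, or fitted probabilities pinned
#' to 0/1) is flagged and makes the fit invalid downstream.
#'
#' @param md modulation depths (>= 3 distinct values).
#' @param detected detected-trial counts per MD.
#' @param trials trial counts per MD (`detected <= trials`).
#' @param frequencyHz stimulation frequency (metadata).
#' @param source `"subjective"` or `"electrophysiological"`.
#' @param logMD fit the linear predictor on log10(MD) instead of raw MD.
#' @return a [PsychometricFit-class].
#' @export
fitProbit <- function(md, detected, trials, frequencyHz = NA_real_,
                      source = "subjective", logMD = FALSE) {
  if (length(unique(md)) < 3) stop("probit fit needs >= 3 distinct MDs")
  if (any(detected > trials) || any(detected < 0)) stop("counts must satisfy 0 <= detected <= trials")
  x <- if (logMD) log10(md) else md
  fit <- withCallingHandlers(
    stats::glm(cbind(detected, trials - detected) ~ x,
               family = stats::binomial(link = "probit")),
    warning = function(w) invokeRestart("muffleWarning"))
  # complete separation: every cell at 0% or 100%, so the ML slope diverges;
  # a steep but identifiable fit (some interior cell) is NOT flagged
  sep <- all(detected == 0 | detected == trials) || !fit$converged
  new("PsychometricFit", frequencyHz = frequencyHz,
      coef = stats::setNames(unname(stats::coef(fit)), c("intercept", "slope")),
      deviance = fit$deviance, converged = fit$converged, separation = sep,
      data = data.frame(md = md, detected = detected, trials = trials),
      source = source)
}

#' Predicted detection probability of a probit fit
#' @param fit a [PsychometricFit-class].
#' @param md modulation depths to predict at.
#' @param logMD must match the scale the fit was made on.
#' @return numeric probabilities.
#' @export
predictProbit <- function(fit, md, logMD = FALSE) {
  x <- if (logMD) log10(md) else md
  stats::pnorm(fit@coef["intercept"] + fit@coef["slope"] * x)
}

#' Visibility threshold from a psychometric fit
#'
#' The threshold is the MD detected with probability 0.5, `-b0/b1` on the
#' probit scale. The record is invalid when the slope is nonpositive, the
#' threshold nonpositive, the deviance at least `devianceMax` (1 in the
#' study rule), or the fit is degenerate (separation / non-convergence);
#' invalidity is a value, not an error. Sensitivity is the reciprocal of a
#' valid threshold.
#'
#' @param fit a [PsychometricFit-class].
#' @param subjectId identifier copied into the record.
#' @param devianceMax deviance gate (fits with deviance >= this are invalid).
#' @return one-row data.frame: `subject_id`, `source`, `frequency_hz`,
#'   `threshold_md`, `sensitivity`, `valid`, `invalid_reason`, `deviance`.
#' @export
thresholdFromFit <- function(fit, subjectId = NA_character_, devianceMax = 1) {
  b0 <- fit@coef["intercept"]; b1 <- fit@coef["slope"]
  thr <- unname(-b0 / b1)
  reason <- NA_character_
  if (fit@separation || !fit@converged) reason <- "degenerate_fit"
  else if (b1 <= 0) reason <- "negative_slope"
  else if (!is.finite(thr) || thr <= 0) reason <- "negative_threshold"
  else if (fit@deviance >= devianceMax) reason <- "high_deviance"
  valid <- is.na(reason)
  data.frame(subject_id = subjectId, source = fit@source,
             frequency_hz = fit@frequencyHz,
             threshold_md = if (valid) thr else NA_real_,
             sensitivity = if (valid) 1 / thr else NA_real_,
             valid = valid, invalid_reason = reason,
             deviance = fit@deviance)
}

#' Detection probability tables
#'
#' Aggregates per-trial binary outcomes into detection probabilities per
#' (subject, frequency, MD). `records` carries one row per non-rejected
#' trial with its outcome: the subjective report, or the z > 0 SSVEP
#' response. Rows with missing outcomes (e.g. an experiment without
#' subjective reports) are dropped.
#'
#' @param records data.frame with columns `subject_id`, `frequency_hz`,
#'   `md`, `response` (0/1 or logical; NA allowed and dropped).
#' @return data.frame: `subject_id`, `frequency_hz`, `md`, `detected`,
#'   `trials`, `probability`.
#' @export
detectionCurves <- function(records) {
  need <- c("subject_id", "frequency_hz", "md", "response")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  rec <- records[!is.na(records$response), , drop = FALSE]
  if (!nrow(rec)) return(data.frame(subject_id = character(),
                                    frequency_hz = numeric(), md = numeric(),
                                    detected = integer(), trials = integer(),
                                    probability = numeric()))
  agg <- stats::aggregate(as.integer(rec$response),
                          by = list(subject_id = rec$subject_id,
                                    frequency_hz = rec$frequency_hz,
                                    md = rec$md),
                          FUN = function(v) c(sum(v), length(v)))
  out <- data.frame(agg[, 1:3], detected = agg$x[, 1], trials = agg$x[, 2])
  out$probability <- out$detected / out$trials
  out[order(out$subject_id, out$frequency_hz, out$md), ]
}

#' Per-subject thresholds from a detection table
#'
#' Fits a probit psychometric function per (subject, frequency) cell of a
#' detection table and extracts the 50% threshold records with their
#' validity gates.
#'
#' @param curves data.frame from [detectionCurves()].
#' @param source label stored in the records.
#' @param devianceMax deviance gate.
#' @param logMD fit on log10 MD.
#' @return data.frame of threshold records (one row per subject x frequency
#'   with >= 3 distinct MDs).
#' @export
thresholdTable <- function(curves, source = "subjective", devianceMax = 1,
                           logMD = FALSE) {
  out <- list()
  for (sid in unique(curves$subject_id)) {
    sub <- curves[curves$subject_id == sid, ]
    for (f in unique(sub$frequency_hz)) {
      cell <- sub[sub$frequency_hz == f, ]
      if (length(unique(cell$md)) < 3) next
      fit <- fitProbit(cell$md, cell$detected, cell$trials,
                       frequencyHz = f, source = source, logMD = logMD)
      out[[length(out) + 1L]] <- thresholdFromFit(fit, subjectId = sid,
                                                  devianceMax = devianceMax)
    }
  }
  if (!length(out)) stop("no (subject, frequency) cell had >= 3 distinct MDs")
  do.call(rbind, out)
}
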