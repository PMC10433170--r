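#' Pool sensitivity estimates at one frequency
#'
#' Single-pass outlier exclusion (values farther than `k` standard
#' deviations from the mean are dropped) followed by the arithmetic mean of
#' the remainder.
#'
#' @param values numeric sensitivity estimates (at least `minN`).
#' @param k exclusion multiplier (2 in the study rule).
#' @param minN minimal number of records (3 in the study rule).
#' @return list with `mean`, `n` (values kept), `excluded` (logical mask).
#' @export
poolSensitivities <- function(values, k = 2, minN = 3) {
  if (length(values) < minN)
    stop("pooling needs >= ", minN, " records at a frequency")
  excl <- abs(values - mean(values)) > k * stats::sd(values)
  list(mean = mean(values[!excl]), n = sum(!excl), excluded = excl)
}

.evalRational <- function(coef, f) {
  (coef["p1"] * f^3 + coef["p2"] * f^2 + coef["p3"] * f + coef["p4"]) /
    (f + coef["q1"])
}

# Linearised least squares S * (f + q1) = p1 f^3 + ... + p4 over a grid of
# q1 candidates; the best becomes the Levenberg-Marquardt start.
.rationalInit <- function(f, s, q1Grid = c(1, 5, 10, 20, 40)) {
  best <- NULL; bestSS <- Inf
  X <- cbind(f^3, f^2, f, 1)
  for (q1 in q1Grid) {
    beta <- tryCatch(stats::lm.fit(X, s * (f + q1))$coefficients,
                     error = function(e) NULL)
    if (is.null(beta) || anyNA(beta)) next
    cf <- c(p1 = unname(beta[1]), p2 = unname(beta[2]), p3 = unname(beta[3]),
            p4 = unname(beta[4]), q1 = q1)
    ss <- sum((s - .evalRational(cf, f))^2)
    if (is.finite(ss) && ss < bestSS) { bestSS <- ss; best <- cf }
  }
  if (is.null(best)) stop("no usable initialisation for the rational fit")
  best
}

#' Fit the rational-polynomial TCSC
#'
#' Least-squares fit of the cubic/linear rational curve
#' `S(f) = (p1 f^3 + p2 f^2 + p3 f + p4) / (f + q1)` to mean sensitivities
#' by Levenberg-Marquardt, initialised from a linearised solve over a grid
#' of `q1` candidates. R^2 is reported against the mean sensitivities and,
#' because the quantity the goodness of fit refers to is ambiguous between
#' sensitivities and thresholds, also on the reciprocal (threshold) scale.
#'
#' @param frequencyHz frequencies, Hz (>= 5 points for 5 parameters).
#' @param sensitivity mean sensitivities at those frequencies.
#' @param init optional named start vector `p1..p4`, `q1`.
#' @param logDomain minimise on log sensitivities instead of linear ones.
#' @return a [TCSCFit-class].
#' @export
fitRational <- function(frequencyHz, sensitivity, init = NULL,
                        logDomain = FALSE) {
  f <- as.numeric(frequencyHz); s <- as.numeric(sensitivity)
  if (length(f) < 5) stop("rational fit needs >= 5 frequency points")
  if (is.null(init)) init <- .rationalInit(f, s)
  dat <- data.frame(f = f, s = s)
  fit <- if (logDomain) {
    minpack.lm::nlsLM(log(s) ~ log((p1 * f^3 + p2 * f^2 + p3 * f + p4) / (f + q1)),
                      data = dat, start = as.list(init),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(s ~ (p1 * f^3 + p2 * f^2 + p3 * f + p4) / (f + q1),
                      data = dat, start = as.list(init),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  pred <- .evalRational(cf, f)
  ssRes <- sum((s - pred)^2)
  r2 <- 1 - ssRes / sum((s - mean(s))^2)
  r2Thr <- 1 - sum((1 / s - 1 / pred)^2) / sum((1 / s - mean(1 / s))^2)
  df <- length(f) - 5
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 5, 5))
  dimnames(vc) <- list(names(cf), names(cf))
  new("TCSCFit", coef = cf, cov = vc,
      data = data.frame(frequency_hz = f, sensitivity = s, n = NA_integer_),
      r2 = r2, r2Threshold = r2Thr,
      sigma = if (df > 0) sqrt(ssRes / df) else NA_real_,
      df = df, domain = range(f))
}

#' Evaluate a fitted TCSC
#' @param fit a [TCSCFit-class] (or a rational [SensitivityCurve-class]).
#' @param f frequencies, Hz.
#' @return fitted sensitivities.
#' @export
tcscSensitivity <- function(fit, f) {
  if (is(fit, "SensitivityCurve")) return(curveSensitivity(fit, f))
  stopifnot(is(fit, "TCSCFit"))
  unname(.evalRational(fit@coef, f))
}

#' Peak of a sensitivity curve
#'
#' Global maximiser over the closed domain, located on a dense grid (0.01 Hz
#' by default) and refined locally by golden-section search. Maxima on the
#' domain edge are flagged via the `"edge"` attribute.
#'
#' @param fit a [TCSCFit-class], rational [SensitivityCurve-class], or named
#'   coefficient vector `p1..p4`, `q1`.
#' @param domain frequency interval searched (defaults to the fit domain).
#' @param gridStep grid resolution, Hz.
#' @return named numeric `c(frequency_hz, sensitivity)` with attribute
#'   `"edge"` (logical).
#' @export
curvePeak <- function(fit, domain = NULL, gridStep = 0.01) {
  evalFun <- if (is(fit, "TCSCFit")) {
    if (is.null(domain)) domain <- fit@domain
    function(f) .evalRational(fit@coef, f)
  } else if (is(fit, "SensitivityCurve")) {
    if (is.null(domain)) domain <- fit@domain
    function(f) curveSensitivity(fit, f)
  } else {
    stopifnot(is.numeric(fit), all(c("p1", "p4", "q1") %in% names(fit)))
    if (is.null(domain)) domain <- c(1, 60)
    function(f) .evalRational(fit, f)
  }
  grid <- seq(domain[1], domain[2], by = gridStep)
  v <- evalFun(grid)
  if (!all(is.finite(v))) stop("curve not finite on the search domain")
  i <- which.max(v)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(evalFun, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  fPeak <- opt$maximum; sPeak <- opt$objective
  if (v[i] > sPeak) { fPeak <- grid[i]; sPeak <- v[i] }
  out <- c(frequency_hz = fPeak, sensitivity = unname(sPeak))
  attr(out, "edge") <- (i == 1L || i == length(grid))
  out
}

# Gradient of the rational curve in its coefficients, for the delta method.
.rationalGradient <- function(coef, f) {
  den <- f + coef["q1"]
  num <- coef["p1"] * f^3 + coef["p2"] * f^2 + coef["p3"] * f + coef["p4"]
  cbind(p1 = f^3 / den, p2 = f^2 / den, p3 = f / den, p4 = 1 / den,
        q1 = -num / den^2)
}

#' 95% prediction bounds of a fitted TCSC
#'
#' Observation-level bounds
#' `S(f) +/- t(1 - alpha/2, df) * sqrt(sigma^2 + g(f)' Cov g(f))`, with `g`
#' the coefficient gradient at `f` (delta method), covering a new mean
#' sensitivity observation at each frequency.
#'
#' @param fit a [TCSCFit-class] with df > 0 and finite covariance.
#' @param f frequency grid, Hz.
#' @param level confidence level.
#' @return data.frame: `frequency_hz`, `fit`, `lower`, `upper`.
#' @export
predictionBounds <- function(fit, f, level = 0.95) {
  stopifnot(is(fit, "TCSCFit"))
  if (fit@df <= 0) stop("prediction bounds need positive residual degrees of freedom")
  g <- .rationalGradient(fit@coef, f)
  varCurve <- rowSums((g %*% fit@cov) * g)
  se <- sqrt(fit@sigma^2 + pmax(varCurve, 0))
  tq <- stats::qt(1 - (1 - level) / 2, fit@df)
  pred <- .evalRational(fit@coef, f)
  data.frame(frequency_hz = f, fit = unname(pred),
             lower = unname(pred - tq * se), upper = unname(pred + tq * se))
}

#' Compare psychophysical and electrophysiological sensitivities
#'
#' Per-frequency two-sided Wilcoxon rank-sum tests between the two sources'
#' valid sensitivity records (midranks for ties; exact where the samples
#' allow), with Storey q-values across frequencies and significance flags at
#' q < 0.005 and q < 0.001.
#'
#' @param psych,electro data.frames with columns `frequency_hz`,
#'   `sensitivity` (valid records only).
#' @param minN minimal records per source per frequency (default 3).
#' @param lambda Storey tuning parameter.
#' @return data.frame: `frequency_hz`, `n_psy`, `n_eeg`, `W`, `p`, `q`,
#'   `sig_q005`, `sig_q001`.
#' @export
compareCurves <- function(psych, electro, minN = 3, lambda = 0.5) {
  freqs <- sort(intersect(unique(psych$frequency_hz),
                          unique(electro$frequency_hz)))
  rows <- list()
  for (f in freqs) {
    x <- psych$sensitivity[psych$frequency_hz == f]
    y <- electro$sensitivity[electro$frequency_hz == f]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < minN || length(y) < minN) next
    if (stats::sd(c(x, y)) == 0) {
      W <- length(x) * length(y) / 2; p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
      W <- unname(wt$statistic); p <- wt$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(frequency_hz = f,
                                            n_psy = length(x),
                                            n_eeg = length(y), W = W, p = p)
  }
  if (!length(rows)) stop("no frequency has >= ", minN, " records in both sources")
  out <- do.call(rbind, rows)
  out$q <- storeyQ(out$p, lambda = lambda)
  out$sig_q005 <- out$q < 0.005
  out$sig_q001 <- out$q < 0.001
  out
}
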