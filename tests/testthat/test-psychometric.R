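test_that("probit fits recover generating parameters at large n", {
  b0 <- -6; b1 <- 1500  # threshold 0.004
  mds <- seq(0.001, 0.007, length.out = 7)
  p <- pnorm(b0 + b1 * mds)
  set.seed(8)
  k <- rbinom(7, 1000, p)
  fit <- fitProbit(mds, k, rep(1000, 7), frequencyHz = 24)
  expect_false(fit@separation)
  expect_equal(unname(-fit@coef["intercept"] / fit@coef["slope"]), -b0 / b1,
               tolerance = 0.03)
  expect_equal(unname(fit@coef["slope"]), b1, tolerance = 0.1)
  expect_gte(fit@deviance, 0)
})

test_that("degenerate detection patterns raise the separation flag", {
  fitAll <- fitProbit(c(0.01, 0.02, 0.03), c(10, 10, 10), rep(10, 3))
  expect_true(fitAll@separation)
  fitNone <- fitProbit(c(0.01, 0.02, 0.03), c(0, 0, 0), rep(10, 3))
  expect_true(fitNone@separation)
  expect_error(fitProbit(c(0.01, 0.01, 0.02), c(1, 2, 3), rep(10, 3)),
               "3 distinct")
  expect_error(fitProbit(c(0.01, 0.02, 0.03), c(11, 2, 3), rep(10, 3)),
               "counts")
})

test_that("threshold records apply the validity gates", {
  mkFit <- function(coef, deviance, sep = FALSE)
    new("PsychometricFit", frequencyHz = 24,
        coef = setNames(coef, c("intercept", "slope")), deviance = deviance,
        converged = TRUE, separation = sep,
        data = data.frame(), source = "subjective")

  ok <- thresholdFromFit(mkFit(c(-5, 500), 0.4), subjectId = "s")
  expect_true(ok$valid)
  expect_equal(ok$threshold_md, 0.01)
  expect_equal(ok$sensitivity, 100)

  neg <- thresholdFromFit(mkFit(c(-5, -500), 0.4))
  expect_false(neg$valid)
  expect_equal(neg$invalid_reason, "negative_slope")

  negThr <- thresholdFromFit(mkFit(c(5, 500), 0.4))
  expect_false(negThr$valid)
  expect_equal(negThr$invalid_reason, "negative_threshold")

  dev <- thresholdFromFit(mkFit(c(-5, 500), 1.2))
  expect_false(dev$valid)
  expect_equal(dev$invalid_reason, "high_deviance")
  # boundary: deviance exactly 1 is already invalid (below-one rule)
  expect_false(thresholdFromFit(mkFit(c(-5, 500), 1.0))$valid)

  sep <- thresholdFromFit(mkFit(c(-5, 500), 0.1, sep = TRUE))
  expect_false(sep$valid)
  expect_equal(sep$invalid_reason, "degenerate_fit")
})

test_that("fitted probability is monotone in MD whenever the slope is positive", {
  fit <- new("PsychometricFit", frequencyHz = 10,
             coef = c(intercept = -2, slope = 300), deviance = 0,
             converged = TRUE, separation = FALSE, data = data.frame(),
             source = "subjective")
  p <- predictProbit(fit, seq(0.001, 0.02, length.out = 50))
  expect_true(all(diff(p) > 0))
})

test_that("detection tables aggregate trials and drop missing responses", {
  rec <- data.frame(subject_id = "a", frequency_hz = 10,
                    md = rep(c(0.01, 0.02), each = 10),
                    response = c(rep(c(1, 0), c(7, 3)), rep(1, 10)))
  out <- detectionCurves(rec)
  expect_equal(out$probability, c(0.7, 1.0))
  expect_equal(out$trials, c(10L, 10L))

  recNA <- rec; recNA$response[1] <- NA
  outNA <- detectionCurves(recNA)
  expect_equal(outNA$trials[1], 9L)  # rejected/missing trial leaves the denominator

  empty <- detectionCurves(data.frame(subject_id = "a", frequency_hz = 1,
                                      md = 0.1, response = NA))
  expect_equal(nrow(empty), 0L)
})

test_that("empirical detection curves track the generating probit observer", {
  prof <- testProfile(22)
  f <- 24; th <- prof@thetaPsy(f)
  mds <- c(0.6, 0.8, 1.0, 1.2, 1.4) * th
  rows <- do.call(rbind, lapply(mds, function(m) {
    reps <- vapply(1:100, function(k)
      synthTrial(prof, f, m, seed = round(m * 1e6) + k)@subjectiveReport,
      logical(1))
    data.frame(subject_id = "s", frequency_hz = f, md = m, response = reps)
  }))
  curves <- detectionCurves(rows)
  truth <- ssvepTCSC:::.psychObserverP(prof, f, mds)
  expect_true(all(abs(curves$probability - truth) <
                    4 * sqrt(truth * (1 - truth) / 100) + 0.02))
})

test_that("threshold recovery from subjective reports is accurate in the median", {
  errs <- vapply(1:60, function(s) {
    prof <- testProfile(3000 + s)
    f <- 13; th <- prof@thetaPsy(f)
    mds <- c(0.6, 0.8, 1.0, 1.2, 1.4) * th
    k <- vapply(seq_along(mds), function(i)
      sum(vapply(1:10, function(j)
        synthTrial(prof, f, mds[i], seed = s * 5000 + i * 100 + j)@subjectiveReport,
        logical(1))), numeric(1))
    fit <- fitProbit(mds, k, rep(10, 5), frequencyHz = f)
    thr <- unname(-fit@coef["intercept"] / fit@coef["slope"])
    abs(thr - th) / th
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("the deviance gate passes fewer fits as response noise grows", {
  set.seed(60)
  validFrac <- vapply(c(0, 0.2, 0.4), function(noise) {
    ok <- vapply(1:200, function(r) {
      th <- 0.004
      mds <- c(0.6, 0.8, 1.0, 1.2, 1.4) * th
      p <- pnorm((mds - th) / (0.25 * th))
      p <- pmin(1, pmax(0, p + rnorm(5, 0, noise)))
      k <- rbinom(5, 10, p)
      fit <- fitProbit(mds, k, rep(10, 5))
      rec <- thresholdFromFit(fit)
      isTRUE(rec$valid)
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_true(all(diff(validFrac) <= 0))
  expect_gt(validFrac[1], validFrac[3])
})
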