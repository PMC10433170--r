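test_that("epoch spectra have 1 Hz bins and match a brute-force DFT oracle", {
  t <- (0:767) / 256
  x <- sin(2 * pi * 10 * t)
  sp <- epochSpectrum(x)
  expect_length(sp, 128L)
  expect_equal(diff(as.numeric(names(sp))), rep(1, 127))
  expect_equal(names(which.max(sp)), "10")
  expect_equal(sp[["10"]], 0, tolerance = 1e-9)  # unit amplitude, log10(1)
  expect_gt(sp[["10"]] - max(sp[-10]), 2)

  set.seed(21)
  y <- rnorm(768)
  spy <- epochSpectrum(y)
  for (f in sample(1:128, 5)) {
    expect_equal(spy[[as.character(f)]], epochSpectrumOracle(y, f),
                 tolerance = 1e-9)
  }
  expect_error(epochSpectrum(rnorm(700)), "768")
})

test_that("Cohen's d matches hand arithmetic and degenerates safely", {
  stim <- matrix(c(1.5, 1.6, 1.7), ncol = 1)
  base <- matrix(c(1.0, 1.2, 1.1), ncol = 1)
  colnames(stim) <- colnames(base) <- "1"
  # pooled SD = sqrt((2*0.01 + 2*0.01)/4) = 0.1; d = 0.5 / 0.1 = 5
  expect_equal(unname(cohensDSpectrum(stim, base)), 5, tolerance = 1e-12)

  same <- matrix(rnorm(40), 4)
  colnames(same) <- 1:10
  expect_equal(unname(cohensDSpectrum(same, same)), rep(0, 10))

  degS <- matrix(c(1, 1), ncol = 1); degB <- matrix(c(0, 0), ncol = 1)
  colnames(degS) <- colnames(degB) <- "1"
  expect_warning(d0 <- cohensDSpectrum(degS, degB), "zero pooled SD")
  expect_equal(unname(d0), 0)
  expect_error(cohensDSpectrum(matrix(1, 1, 1), matrix(1, 2, 1)), ">= 2")
})

test_that("d and z are invariant to a constant shift of all spectra", {
  set.seed(3)
  pairs <- lapply(1:6, function(k) noisePair(300 + k))
  st <- conditionStats(pairs)
  shifted <- lapply(pairs, function(p) {
    p@baseline <- p@baseline * 10      # multiplicative in amplitude is
    p@stimulation <- p@stimulation * 10  # additive in log spectrum
    p
  })
  st2 <- conditionStats(shifted)
  expect_equal(cohensD(st2), cohensD(st), tolerance = 1e-9)
  expect_equal(zScores(st2), zScores(st), tolerance = 1e-9)
})

test_that("mean stimulation z equals d * pooledSD / baselineSD algebraically", {
  pairs <- lapply(1:8, function(k) noisePair(400 + k))
  st <- conditionStats(pairs)
  lhs <- colMeans(zScores(st))
  rhs <- st@cohensD * st@pooledSD / st@baselineSD
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-10)
})

test_that("best harmonic respects the Nyquist cap and tie rules", {
  d <- setNames(rep(0.1, 128), 1:128)
  b40 <- bestHarmonic(d, 40)
  expect_equal(b40$candidates$h, 1:3)
  expect_equal(b40$h, 1L)  # tie resolves to the smaller harmonic
  b60 <- bestHarmonic(d, 60)
  expect_equal(b60$candidates$h, 1:2)
  d2 <- d; d2["80"] <- 0.9
  expect_equal(bestHarmonic(d2, 40)$h, 2L)
  expect_equal(bestHarmonic(d2, 40)$bin, 80)
  expect_error(bestHarmonic(d, 130), "no harmonic")

  # synthetic low-frequency stimulation: energy lands on the 4th harmonic
  prof <- testProfile(7)
  md <- min(1, 30 * prof@thetaEeg(8))
  pairs <- lapply(1:8, function(k) synthTrial(prof, 8, md, seed = 700 + k))
  st <- conditionStats(pairs)
  expect_equal(bestHarmonic(cohensD(st), 8)$h, 4L)
})

test_that("best channel maximises d with first-in-order ties", {
  d <- c(Pz = 0.4, Oz = 0.6, Cz = 0.2)
  expect_equal(bestChannel(d)$channel, "Oz")
  tie <- c(Pz = 0.5, Oz = 0.5)
  expect_equal(bestChannel(tie)$channel, "Pz")
  expect_equal(bestChannel(d)$ranking$channel, c("Oz", "Pz", "Cz"))
})

test_that("z-scores standardise against the baseline statistics", {
  sp <- matrix(c(2, 3, 4), ncol = 1)
  colnames(sp) <- "5"
  expect_equal(zscoreEpochs(sp, setNames(3, "5"), setNames(1, "5"), 5),
               c(-1, 0, 1))
  expect_error(zscoreEpochs(sp, setNames(3, "5"), setNames(0, "5"), 5),
               "SD is zero")
  # batch equals loop
  set.seed(5)
  S <- matrix(rnorm(30), 5); colnames(S) <- 1:6
  mB <- rnorm(6); sB <- runif(6, 0.5, 2)
  z <- zscoreEpochs(S, mB, sB, 4)
  zLoop <- vapply(1:5, function(i) (S[i, 4] - mB[4]) / sB[4], numeric(1))
  expect_equal(z, zLoop)
})

test_that("the z > 0 rule maps to binary detections and probabilities", {
  out <- detectSSVEP(c(-0.5, 0, 1e-9, 2))
  expect_equal(out$responses, c(0L, 0L, 1L, 1L))
  expect_equal(out$probability, 0.5)
  expect_equal(detectSSVEP(c(1, 2, 3))$probability, 1)
})

test_that("detection probability grows with injected SSVEP amplitude", {
  prof <- testProfile(15)
  th <- prof@thetaEeg(32)
  probs <- vapply(c(0, 2, 8), function(mult) {
    pairs <- lapply(1:10, function(k)
      synthTrial(prof, 32, min(1, mult * th), seed = 50 * mult + k))
    st <- conditionStats(pairs)
    detectSSVEP(zScores(st, 32))$probability
  }, numeric(1))
  expect_true(all(diff(probs) >= -0.1))
  expect_gt(probs[3], probs[1])
})

test_that("frequency QC keeps anchored responses and drops noise-like ones", {
  prof <- testProfile(31)
  md <- min(1, 30 * prof@thetaEeg(40))
  strong <- lapply(1:6, function(s) {
    pairs <- lapply(1:8, function(k) synthTrial(prof, 40, md, seed = s * 1000 + k))
    cohensD(conditionStats(pairs))
  })
  qcS <- qcFrequency(strong, 40)
  expect_true(qcS$include)
  expect_equal(qcS$expectedBins, c(40, 80, 120))
  expect_gte(qcS$fraction, 0.25)

  noise <- lapply(1:6, function(s) {
    pairs <- lapply(1:8, function(k) noisePair(s * 2000 + k))
    cohensD(conditionStats(pairs))
  })
  qcN <- qcFrequency(noise, 40)
  expect_false(qcN$include)
  expect_lt(qcN$fraction, 0.25)

  # boundary: fraction exactly at the threshold is included (>= rule)
  mkD <- function(peakBin) {
    d <- setNames(rep(0, 128), 1:128); d[as.character(peakBin)] <- 1; d
  }
  dList <- list(mkD(40), mkD(17), mkD(23), mkD(55))
  qcB <- qcFrequency(dList, 40)
  expect_equal(qcB$fraction, 0.25)
  expect_true(qcB$include)
})
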