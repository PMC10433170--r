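test_that("pooling excludes only the >2 SD tail before averaging", {
  v <- c(rep(1, 10), 10)
  out <- poolSensitivities(v)
  expect_true(out$excluded[11])
  expect_equal(sum(out$excluded), 1L)
  expect_equal(out$mean, 1)
  expect_equal(out$n, 10L)
  # manual oracle
  expect_identical(out$excluded, abs(v - mean(v)) > 2 * sd(v))

  allEq <- poolSensitivities(rep(4, 5))
  expect_equal(allEq$mean, 4)
  expect_false(any(allEq$excluded))
  expect_equal(poolSensitivities(c(9, 10, 11))$mean, 10)
  expect_error(poolSensitivities(c(1, 2)), ">= 3")
})

test_that("rational fit reproduces a noiseless generating curve", {
  cf <- psychophysicalCoefficients()
  f <- c(4, 6, 8, 13, 19, 24, 32, 37, 40, 48, 60)
  s <- (cf["p1"] * f^3 + cf["p2"] * f^2 + cf["p3"] * f + cf["p4"]) / (f + cf["q1"])
  fit <- fitRational(f, s)
  grid <- seq(4, 60, by = 0.5)
  truth <- (cf["p1"] * grid^3 + cf["p2"] * grid^2 + cf["p3"] * grid + cf["p4"]) /
    (grid + cf["q1"])
  expect_equal(tcscSensitivity(fit, grid), unname(truth), tolerance = 1e-6)
  expect_equal(fit@r2, 1, tolerance = 1e-9)
  expect_error(fitRational(1:4, (1:4)^2), ">= 5")
})

test_that("curve peak matches the algebraic maximiser of a quadratic/linear toy", {
  # (-f^2 + b f) / (f + q): stationary point f* = -q + sqrt(q^2 + b q)
  b <- 20; q <- 5
  cf <- c(p1 = 0, p2 = -1, p3 = b, p4 = 0, q1 = q)
  fStar <- -q + sqrt(q^2 + b * q)
  pk <- curvePeak(cf, domain = c(1, 15))
  expect_equal(unname(pk["frequency_hz"]), fStar, tolerance = 1e-4)
  expect_equal(unname(pk["sensitivity"]),
               (-fStar^2 + b * fStar) / (fStar + q), tolerance = 1e-8)
  expect_false(attr(pk, "edge"))
  # maximum pinned at the domain edge is flagged
  inc <- c(p1 = 0, p2 = 0, p3 = 1, p4 = 0, q1 = 0)
  expect_true(attr(curvePeak(inc, domain = c(1, 10)), "edge"))
})

test_that("rational fit is scale-equivariant and its peak location scale-invariant", {
  cf <- electrophysiologicalCoefficients()
  f <- c(4, 6, 8, 13, 19, 24, 32, 37, 40, 48, 60)
  s <- (cf["p1"] * f^3 + cf["p2"] * f^2 + cf["p3"] * f + cf["p4"]) / (f + cf["q1"])
  f1 <- fitRational(f, s)
  f2 <- fitRational(f, 10 * s)
  grid <- seq(4, 60, by = 1)
  expect_equal(tcscSensitivity(f2, grid), 10 * tcscSensitivity(f1, grid),
               tolerance = 1e-6)
  expect_equal(unname(curvePeak(f2)["frequency_hz"]),
               unname(curvePeak(f1)["frequency_hz"]), tolerance = 1e-3)
})

test_that("prediction bounds collapse without noise and widen with residual SD", {
  cf <- psychophysicalCoefficients()
  f <- c(4, 6, 8, 13, 19, 24, 32, 37, 40, 48, 60)
  s <- (cf["p1"] * f^3 + cf["p2"] * f^2 + cf["p3"] * f + cf["p4"]) / (f + cf["q1"])
  fit <- fitRational(f, s)
  pbTight <- predictionBounds(fit, c(10, 20, 40))
  expect_equal(pbTight$upper - pbTight$lower, rep(0, 3), tolerance = 1e-4)

  wider <- fit
  wider@sigma <- 2
  pb1 <- predictionBounds(wider, c(10, 20, 40))
  wider@sigma <- 4
  pb2 <- predictionBounds(wider, c(10, 20, 40))
  expect_true(all(pb2$upper - pb2$lower > pb1$upper - pb1$lower))

  zero <- fit; zero@df <- 0
  expect_error(predictionBounds(zero, 10), "degrees of freedom")
})

test_that("Wilcoxon comparison matches exhaustive permutation for small samples", {
  set.seed(14)
  x <- rnorm(4); y <- rnorm(4) + 1
  cmp <- compareCurves(data.frame(frequency_hz = 10, sensitivity = x),
                       data.frame(frequency_hz = 10, sensitivity = y),
                       minN = 3)
  expect_equal(cmp$p, ranksumExact(x, y), tolerance = 1e-12)

  x5 <- rnorm(5); y5 <- rnorm(5)
  cmp5 <- compareCurves(data.frame(frequency_hz = 7, sensitivity = x5),
                        data.frame(frequency_hz = 7, sensitivity = y5))
  expect_equal(cmp5$p, ranksumExact(x5, y5), tolerance = 1e-12)
})

test_that("identical samples compare as indistinguishable with q-value flags", {
  same <- data.frame(frequency_hz = rep(c(10, 20), each = 4),
                     sensitivity = rep(c(3, 3, 3, 3), 2))
  cmp <- compareCurves(same, same)
  expect_equal(cmp$p, c(1, 1))
  expect_false(any(cmp$sig_q005))
  diffd <- same; diffd$sensitivity <- same$sensitivity + 5
  cmp2 <- compareCurves(same, diffd)
  expect_true(all(cmp2$p < 0.05))
})

test_that("Storey q-values are monotone in p and reduce to BH at pi0 = 1", {
  set.seed(2)
  p <- c(runif(15, 0, 0.04), runif(15))
  q <- storeyQ(p)
  expect_true(all(q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_equal(unname(storeyQ(p, pi0 = 1)), unname(p.adjust(p, "BH")),
               tolerance = 1e-12)
  # pi0 estimate never exceeds 1, so q <= BH
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
})

test_that("Pearson correlation agrees with the closed-form estimator", {
  x <- c(1, 2, 4, 7, 11); y <- c(2.2, 2.9, 5.1, 7.4, 12.0)
  out <- pearsonCor(x, y)
  rManual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(out["rho"]), rManual, tolerance = 1e-12)
  expect_equal(unname(pearsonCor(x, 2 * x + 3)["rho"]), 1)
  expect_equal(unname(pearsonCor(x, -x)["rho"]), -1)
  expect_error(pearsonCor(x, rep(1, 5)), "zero variance")
  expect_error(pearsonCor(1:2, 1:2), "length")
})
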