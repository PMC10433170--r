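makeRec <- function(x, rate = 2048, marker = NULL) {
  mk <- if (is.null(marker)) data.frame(sample = numeric(), label = character())
        else data.frame(sample = marker, label = as.character(seq_along(marker)))
  new("Recording", data = matrix(x, nrow = 1), rate = rate, markers = mk,
      channels = "Pz")
}

test_that("signal conditioning notches 50 Hz, keeps 10 Hz, removes DC, rescales markers", {
  t <- (0:(8 * 2048 - 1)) / 2048
  mid <- 513:1536  # away from edges after decimation to 2048 samples

  r50 <- conditionSignal(makeRec(sin(2 * pi * 50 * t), marker = 8192))
  att <- 20 * log10(sd(r50@data[1, mid]) / sd(sin(2 * pi * 50 * t)))
  expect_lt(att, -20)
  expect_equal(r50@rate, 256)
  expect_equal(r50@markers$sample, 1024)

  r10 <- conditionSignal(makeRec(sin(2 * pi * 10 * t)))
  expect_equal(sd(r10@data[1, mid]) / sd(sin(2 * pi * 10 * t)), 1,
               tolerance = 0.05)

  rdc <- conditionSignal(makeRec(rep(100, length(t))))
  expect_lt(abs(mean(rdc@data[1, mid])), 0.1)

  expect_error(conditionSignal(makeRec(rnorm(1024), rate = 256)), ">= 512")
})

test_that("conditioning filters are idempotent on already-filtered data", {
  set.seed(1)
  x <- matrix(rnorm(4096), 1)
  hp <- ssvepTCSC:::.highpassFIR(256)
  once <- ssvepTCSC:::.filtfiltRows(hp, 1, x)
  twice <- ssvepTCSC:::.filtfiltRows(hp, 1, once)
  mid <- 1025:3072
  expect_equal(twice[1, mid], once[1, mid], tolerance = 0.05)
  nt <- ssvepTCSC:::.notchDesign(50, 256)
  n1 <- ssvepTCSC:::.filtfiltRows(nt$b, nt$a, once)
  n2 <- ssvepTCSC:::.filtfiltRows(nt$b, nt$a, n1)
  expect_equal(n2[1, mid], n1[1, mid], tolerance = 0.05)
})

test_that("common average reference zeroes the cross-channel mean", {
  x <- matrix(rnorm(300), nrow = 3)
  rec <- new("Recording", data = x, rate = 256,
             markers = data.frame(sample = numeric(), label = character()),
             channels = c("a", "b", "c"))
  out <- commonAverageReference(rec)
  expect_equal(colSums(out@data), rep(0, 100), tolerance = 1e-12)

  same <- rec; same@data <- matrix(rep(x[1, ], 3), nrow = 3, byrow = TRUE)
  expect_equal(max(abs(commonAverageReference(same)@data)), 0)

  anti <- rec; anti@data <- rbind(x[1, ], -x[1, ])
  anti@channels <- c("a", "b")
  expect_equal(commonAverageReference(anti)@data, anti@data)

  single <- makeRec(rnorm(100), rate = 256)
  expect_warning(out1 <- commonAverageReference(single), "2 channels")
  expect_equal(out1@data, single@data)
})

test_that("epoch segmentation uses half-open 3-s windows with exact boundaries", {
  rate <- 256; n3 <- 3 * rate
  x <- seq_len(10 * rate)  # strictly increasing ramp: windows identifiable
  recOk <- new("Recording", data = matrix(x, 1), rate = rate,
               markers = data.frame(sample = n3, label = "1"), channels = "Pz")
  pairs <- segmentEpochs(recOk)
  expect_length(pairs, 1L)
  expect_equal(ncol(pairs[[1]]@baseline), 768)
  expect_equal(pairs[[1]]@baseline[1, ], x[1:768])
  expect_equal(pairs[[1]]@stimulation[1, ], x[769:1536])

  recShort <- recOk
  recShort@markers$sample <- n3 - 1
  pr <- segmentEpochs(recShort)
  expect_length(pr, 0L)
  expect_equal(attr(pr, "dropped"), "1")
})

test_that("segmentation has no off-by-one drift over 100 consecutive markers", {
  rate <- 256
  onsets <- 3 * rate + (0:99) * 7 * rate  # 0-based, 7 s apart
  n <- max(onsets) + 3 * rate
  x <- sin(2 * pi * 10 * (seq_len(n) - 1) / rate)
  rec <- new("Recording", data = matrix(x, 1), rate = rate,
             markers = data.frame(sample = onsets,
                                  label = as.character(1:100)),
             channels = "Pz")
  pairs <- segmentEpochs(rec)
  expect_length(pairs, 100L)
  firstStim <- vapply(pairs, function(p) p@stimulation[1, 1], numeric(1))
  # every onset is an integer multiple of the 10 Hz period: identical phase
  expect_equal(firstStim, rep(firstStim[1], 100), tolerance = 1e-9)
})

test_that("variance-based rejection removes exactly the high-variance tail", {
  pairs <- lapply(1:10, function(k) noisePair(k, sd = 1))
  out <- rejectArtifacts(pairs)
  expect_false(any(out$rejected))

  loud <- noisePair(99, sd = sqrt(10), trialId = 11L)
  out2 <- rejectArtifacts(c(pairs, list(loud)))
  v <- vapply(c(pairs, list(loud)), function(p) var(p@stimulation[1, ]),
              numeric(1))
  expect_identical(out2$rejected, v > mean(v) + 2 * sd(v))
  expect_true(out2$rejected[11])
  expect_equal(sum(out2$rejected), 1L)
  expect_length(out2$kept, 10L)

  expect_error(rejectArtifacts(pairs[1:2]), ">= 3")
})

test_that("rejection rate on homogeneous Gaussian epochs stays in the distribution tail", {
  rates <- vapply(1:40, function(r) {
    pairs <- lapply(1:10, function(k) noisePair(r * 100 + k, n = 256))
    mean(rejectArtifacts(pairs)$rejected)
  }, numeric(1))
  expect_lt(mean(rates), 0.08)
})

test_that("the ocular-artifact hook validates its callable", {
  rec <- makeRec(rnorm(1024), rate = 256)
  expect_identical(removeOcularArtifacts(rec), rec)
  flip <- function(r) { r@data <- -r@data; r }
  expect_equal(removeOcularArtifacts(rec, flip)@data, -rec@data)
  bad <- function(r) { r@data <- r@data[, 1:10, drop = FALSE]; r }
  expect_error(removeOcularArtifacts(rec, bad), "identical shape")
})
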