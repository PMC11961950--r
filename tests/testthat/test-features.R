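# brute-force central-moment oracle, independent of the implementation
momentOracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  cm <- function(k) sum((x - mu)^k) / n
  c(mean = mu, variance = cm(2),
    skewness = cm(3) / cm(2)^1.5,
    kurtosis = cm(4) / cm(2)^2 - 3)
}

test_that("moment features match hand values on canonical signals", {
  f <- timeDomainFeatures(c(1, 2, 3, 4, 5))
  expect_equal(unname(f[c("mean", "variance", "skewness")]), c(3, 2, 0))
  alt <- timeDomainFeatures(rep(c(-1, 1), 8))
  expect_equal(unname(alt[c("mean", "variance", "kurtosis")]), c(0, 1, -2))
  spike <- timeDomainFeatures(c(0, 0, 0, 1))
  expect_equal(spike, momentOracle(c(0, 0, 0, 1)))
})

test_that("moments agree with the brute-force oracle on random signals", {
  withr::local_seed(10)
  for (i in 1:25) {
    x <- rnorm(50 + i, sd = runif(1, 0.1, 10))
    expect_equal(timeDomainFeatures(x), momentOracle(x), tolerance = 1e-10)
  }
})

test_that("skewness and kurtosis are invariant under affine rescaling", {
  withr::local_seed(11)
  x <- rexp(200)
  for (a in c(0.1, 3, 250)) {
    f0 <- timeDomainFeatures(x)
    f1 <- timeDomainFeatures(a * x + 7)
    expect_equal(f1[["skewness"]], f0[["skewness"]], tolerance = 1e-9)
    expect_equal(f1[["kurtosis"]], f0[["kurtosis"]], tolerance = 1e-9)
  }
})

test_that("degenerate inputs yield sentinels or errors, not NaN", {
  f <- timeDomainFeatures(rep(2, 10))
  expect_true(is.na(f[["skewness"]]) && is.na(f[["kurtosis"]]))
  expect_equal(f[["variance"]], 0)
  expect_error(timeDomainFeatures(c(1, 2, 3)), "length")
  expect_error(timeDomainFeatures(c(1, 2, NA, 4)), "finite")
})

test_that("a pure tone peaks at its own frequency bin", {
  fs <- 500
  x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / fs))
  for (win in c("rectangular", "hamming", "hann")) {
    w <- welchPsd(x, fs, welchConfig(segmentLength = 1000, window = win))
    expect_equal(w$freq[which.max(w$psd)], 10, tolerance = 0.5)
    expect_true(all(w$psd >= 0))
  }
})

test_that("integrated Welch PSD of white noise recovers its variance", {
  withr::local_seed(12)
  x <- rnorm(8000, sd = 3)
  w <- welchPsd(x, 500, welchConfig(segmentLength = 500, window = "rectangular"))
  expect_equal(bandPower(w$freq, w$psd, c(0, 250)),
               mean((x - mean(x))^2), tolerance = 0.1)
})

test_that("single-segment rectangular Welch equals the direct periodogram", {
  withr::local_seed(13)
  x <- rnorm(1024)
  fs <- 256
  w <- welchPsd(x, fs, welchConfig(segmentLength = length(x), overlap = 0,
                                   window = "rectangular"))
  # directly coded periodogram oracle
  M <- length(x)
  X <- fft(x)[1:(M / 2 + 1)]
  oracle <- 2 * Mod(X)^2 / (M * fs)
  oracle[1] <- oracle[1] / 2
  oracle[length(oracle)] <- oracle[length(oracle)] / 2
  expect_equal(w$psd, oracle, tolerance = 1e-10)
})

test_that("doubling the amplitude quadruples band power", {
  fs <- 500
  x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / fs))
  bp <- function(sig) {
    w <- welchPsd(sig, fs, shortWelch(1000))
    bandPower(w$freq, w$psd, c(8, 13))
  }
  expect_equal(bp(2 * x) / bp(x), 4, tolerance = 1e-6)
})

test_that("band power separates bands and validates its inputs", {
  fs <- 500
  x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / fs))
  w <- welchPsd(x, fs, shortWelch(1000))
  expect_gt(bandPower(w$freq, w$psd, c(8, 13)),
            10 * bandPower(w$freq, w$psd, c(20, 30)))
  z <- welchPsd(rep(0, 2000), fs, shortWelch(1000))
  expect_equal(bandPower(z$freq, z$psd, c(8, 13)), 0)
  expect_error(bandPower(w$freq, w$psd, c(100, 500)), "outside")
  expect_error(welchPsd(x, fs, welchConfig(segmentLength = 1e6)), "exceeds")
  expect_error(welchPsd(numeric(0), fs), "zero-length")
})

test_that("white-noise band power scales with band width", {
  withr::local_seed(14)
  ratios <- replicate(12, {
    w <- welchPsd(rnorm(10000), 500, welchConfig(segmentLength = 1000,
                                                 window = "rectangular"))
    bandPower(w$freq, w$psd, c(20, 60)) / bandPower(w$freq, w$psd, c(100, 120))
  })
  expect_equal(mean(ratios), 2, tolerance = 0.15)
})

test_that("region features average channels and epochs as specified", {
  withr::local_seed(15)
  m <- matrix(rnorm(3 * 1000, sd = 5), 3)
  m[3, ] <- m[1, ]   # duplicate channel
  es <- new("EpochSet", epochs = list(m), labels = "calm",
            conditions = "baseline", subjectIds = "s1", rejectedCount = 0L,
            fs = 500, channelNames = c("Fp1", "Fp2", "AF3"))
  single <- extractRegionFeatures(es, list(Fp = "Fp2"), shortWelch(500))
  byHand <- stressEEG:::.channelFeatures(m[2, ], 500, shortWelch(500))
  expect_equal(unlist(single[1, stressEEG:::.FEATURE_NAMES]),
               byHand[stressEEG:::.FEATURE_NAMES])
  dup <- extractRegionFeatures(es, list(Fp = c("Fp1", "AF3")), shortWelch(500))
  one <- extractRegionFeatures(es, list(Fp = "Fp1"), shortWelch(500))
  expect_equal(dup[, 5:9], one[, 5:9], tolerance = 1e-12)
  expect_error(extractRegionFeatures(es, list(Fp = c("Fp1", "Oz")),
                                     shortWelch(500)), "Oz")
})

test_that("each recording yields one feature vector per region", {
  spec <- smallSpec(n = 1, duration = 4, channels = fullMontage)
  sets <- lapply(generateCohort(spec), preprocessRecording,
                 cfg = preprocessConfig(epochLength = 2))
  ft <- extractRegionFeatures(combineEpochSets(sets), cfg = shortWelch(1000))
  expect_equal(nrow(ft), 5 * 5)  # 5 recordings x 5 regions
  expect_equal(sort(unique(ft$region)), sort(c("Fp", "F", "C", "P", "O")))
  expect_equal(as.integer(table(ft$subject_id)), rep(5L, 5))
  expect_true(all(is.finite(as.matrix(ft[, 5:9]))))
})

test_that("the default region map partitions the 31-channel montage", {
  rm31 <- regionMap(fullMontage)
  expect_setequal(unlist(rm31), fullMontage)
  expect_equal(sum(vapply(rm31, length, 0L)), 31L)
  expect_setequal(rm31$Fp, c("Fp1", "Fp2", "AF3", "AF4"))
  expect_error(regionMap(c(fullMontage, "T7")), "T7")
})
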