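mkSine <- function(f, dur = 4, fs = 500, amp = 10) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * f * t)
}
rms <- function(x) sqrt(mean(x^2))

test_that("band-pass keeps pass-band tones and kills stop-band tones", {
  cfg <- preprocessConfig()
  recStop <- recFromMatrix(rbind(mkSine(50)), channels = "Fp1")
  recPass <- recFromMatrix(rbind(mkSine(10)), channels = "Fp1")
  expect_lt(rms(eegData(bandpassFilter(recStop, cfg))[1, ]),
            0.05 * rms(eegData(recStop)[1, ]))
  expect_equal(rms(eegData(bandpassFilter(recPass, cfg))[1, ]),
               rms(eegData(recPass)[1, ]), tolerance = 0.05)
})

test_that("filtered white noise has negligible out-of-band power", {
  withr::local_seed(1)
  rec <- recFromMatrix(rbind(rnorm(5000, sd = 10)), channels = "Cz")
  out <- bandpassFilter(rec, preprocessConfig())
  w <- welchPsd(eegData(out)[1, ], 500, shortWelch(1000))
  inside <- bandPower(w$freq, w$psd, c(1, 40))
  above <- bandPower(w$freq, w$psd, c(50, 250))
  expect_lt(above / inside, 0.01)
})

test_that("filtering is idempotent within tolerance", {
  rec <- generateRecording(smallSpec(duration = 4), "calm", seed = 9)
  f1 <- bandpassFilter(rec, preprocessConfig())
  f2 <- bandpassFilter(f1, preprocessConfig())
  r1 <- apply(eegData(f1), 1, rms)
  r2 <- apply(eegData(f2), 1, rms)
  expect_true(all(abs(r2 - r1) / r1 < 0.01))
})

test_that("infeasible filter edges raise configuration errors", {
  rec <- recFromMatrix(rbind(mkSine(10)), channels = "Fp1")
  expect_error(bandpassFilter(rec, preprocessConfig(bandpassHigh = 300)),
               "Nyquist")
  expect_error(preprocessConfig(bandpassLow = 0))
  expect_error(preprocessConfig(bandpassLow = 45, bandpassHigh = 40))
})

test_that("re-referencing schemes behave by construction", {
  withr::local_seed(4)
  rec <- recFromMatrix(matrix(rnorm(4 * 100), 4), channels = c("Fp1", "Fp2", "Cz", "Pz"))
  car <- rereference(rec, preprocessConfig(reference = "common_average"))
  expect_equal(max(abs(colMeans(eegData(car)))), 0, tolerance = 1e-12)
  # common-average twice = once
  expect_equal(eegData(rereference(car, preprocessConfig())), eegData(car))
  cz <- rereference(rec, preprocessConfig(reference = "Cz"))
  expect_equal(unname(eegData(cz)[3, ]), rep(0, 100))
  asIs <- rereference(rec, preprocessConfig(reference = "as_recorded"))
  expect_identical(eegData(asIs), eegData(rec))
  expect_error(rereference(rec, preprocessConfig(reference = "TP10")), "not found")
  expect_identical(stressLabel(car), stressLabel(rec))
})

test_that("segmentation floors to whole epochs and preserves content", {
  fs <- 100
  rec <- recFromMatrix(matrix(seq_len(2 * 9500), 2), fs = fs,
                       channels = c("Fp1", "Fp2"))
  es <- segmentEpochs(rec, preprocessConfig(epochLength = 30))
  expect_length(epochs(es), 3)                      # 95 s -> 3 epochs, 5 s dropped
  expect_equal(ncol(epochs(es)[[1]]), 3000)
  expect_equal(do.call(cbind, epochs(es)),
               unname(eegData(rec)[, 1:9000]))       # reconstruction
  one <- segmentEpochs(recFromMatrix(matrix(1:600, 2), fs = 10,
                                     channels = c("Fp1", "Fp2")),
                       preprocessConfig(epochLength = 30))
  expect_length(epochs(one), 1)
  expect_equal(unname(epochs(one)[[1]]), unname(matrix(1:600, 2)))
  expect_error(segmentEpochs(rec, preprocessConfig(epochLength = 120)),
               "shorter than one epoch")
  expect_equal(epochLabels(es), rep("calm", 3))
})

test_that("segment shapes follow the sampling rate", {
  rec <- generateRecording(smallSpec(duration = 200, channels = c("Fp1", "Fp2"),
                                     noiseSd = 1), "calm", seed = 1)
  es <- segmentEpochs(rec, preprocessConfig(epochLength = 30))
  expect_length(epochs(es), 6)
  expect_true(all(vapply(epochs(es), ncol, 0L) == 15000))
})

test_that("artifact rejection removes exactly the contaminated epochs", {
  clean <- matrix(rnorm(2 * 100, sd = 5), 2)
  spiky <- clean
  spiky[1, 50] <- 300
  es <- new("EpochSet", epochs = list(clean, spiky, clean),
            labels = c("calm", "slight", "severe"),
            conditions = rep("baseline", 3), subjectIds = c("a", "b", "c"),
            rejectedCount = 0L, fs = 100, channelNames = c("Fp1", "Fp2"))
  out <- rejectArtifacts(es, preprocessConfig(artifactThreshold = 150))
  expect_equal(rejectedCount(out), 1L)
  expect_equal(epochLabels(out), c("calm", "severe"))
  ident <- rejectArtifacts(es, preprocessConfig(artifactThreshold = Inf))
  expect_identical(epochs(ident), epochs(es))
  expect_error(rejectArtifacts(es, preprocessConfig(artifactThreshold = 1e-9)),
               "all .* epochs")
})

test_that("artifact-free synthetic cohorts pass screening untouched", {
  spec <- smallSpec(n = 1, duration = 5, artifactRate = 0)
  sets <- lapply(generateCohort(spec), preprocessRecording,
                 cfg = preprocessConfig(epochLength = 5))
  es <- combineEpochSets(sets)
  expect_equal(rejectedCount(es), 0L)
  expect_length(epochs(es), 5)
})
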