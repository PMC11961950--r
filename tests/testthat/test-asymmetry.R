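toneRec <- function(ampFp1, ampFp2, f = 10, dur = 4, fs = 500) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  recFromMatrix(rbind(ampFp1 * sin(2 * pi * f * t),
                      ampFp2 * sin(2 * pi * f * t)),
                fs = fs, channels = c("Fp1", "Fp2"))
}

test_that("identical hemispheres give zero asymmetry; swapping negates it", {
  rec <- toneRec(3, 3)
  expect_equal(asymmetryIndex(rec, cfg = shortWelch(1000)), 0)
  withr::local_seed(30)
  m <- matrix(rnorm(2 * 4000, sd = 5), 2)
  a <- asymmetryIndex(recFromMatrix(m, channels = c("Fp1", "Fp2")),
                      cfg = shortWelch(1000))
  b <- asymmetryIndex(recFromMatrix(m[2:1, ], channels = c("Fp1", "Fp2")),
                      cfg = shortWelch(1000))
  expect_equal(a, -b, tolerance = 1e-12)
  expect_error(asymmetryIndex(recFromMatrix(m, channels = c("Cz", "Pz")),
                              cfg = shortWelch(1000)), "Fp1/Fp2")
})

test_that("asymmetry scales with squared amplitude (power subtraction)", {
  rec <- toneRec(2, 4)   # Fp2 amplitude doubled
  ai <- asymmetryIndex(rec, cfg = shortWelch(1000))
  pFp1 <- 2^2 / 2        # sinusoid power = A^2/2
  expect_lt(ai, 0)
  expect_equal(ai, -3 * pFp1, tolerance = 0.05)
  # log-ratio variant: log(P1) - log(P2) = log(1/4)
  expect_equal(asymmetryIndex(rec, cfg = shortWelch(1000), method = "log_ratio"),
               log(1 / 4), tolerance = 0.05)
})

test_that("Spearman rho matches a rank-then-Pearson oracle and handles ties", {
  withr::local_seed(31)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    lv <- sample(n)                 # no ties
    v <- rnorm(n)
    sr <- spearmanRho(lv, v)
    expect_equal(sr$rho, cor(rank(lv), rank(v)), tolerance = 1e-12)
    expect_equal(sr$rho, cor(lv, v, method = "spearman"), tolerance = 1e-12)
  }
  lvT <- c(1, 2, 2, 3, 4, 5, 5, 5, 3, 1, 2, 4)
  vT <- rnorm(12) + lvT
  vT[3] <- vT[2]                    # ties on both margins
  expect_equal(spearmanRho(lvT, vT)$rho, cor(lvT, vT, method = "spearman"),
               tolerance = 1e-12)
})

test_that("identity and inverse rankings give +1 and -1 with exact p", {
  up <- spearmanRho(1:6, 1:6)
  expect_equal(up$rho, 1)
  expect_equal(up$method, "exact")
  dn <- spearmanRho(1:5, 5:1)
  expect_equal(dn$rho, -1)
  expect_equal(dn$p, 2 / factorial(5))   # enumeration over all 120 permutations
  big <- spearmanRho(1:20, rnorm(20))
  expect_equal(big$method, "t-approximation")
  const <- spearmanRho(1:5, rep(2, 5))
  expect_true(is.na(const$rho))
})

test_that("exact permutation p matches full enumeration on a small case", {
  withr::local_seed(32)
  lv <- 1:4
  v <- c(0.3, -1.2, 0.7, 2.0)
  sr <- spearmanRho(lv, v)
  perms <- stressEEG:::.permutations(4)
  rhos <- apply(perms, 1, function(p) cor(rank(lv), rank(v[p])))
  expect_equal(sr$p, mean(abs(rhos) >= abs(sr$rho) - 1e-12))
})

test_that("per-state asymmetry summarises recordings and correlates with level", {
  spec <- smallSpec(n = 4, duration = 8, channels = c("Fp1", "Fp2"))
  res <- asymmetryByState(generateCohort(spec), cfg = shortWelch(1000))
  expect_equal(res$table$state, names(stressLevels()))
  expect_equal(res$table$n, rep(4, 5))
  expect_lt(res$rho, -0.8)
  expect_equal(res$pMethod, "exact")
})

test_that("scoring an unchanged cohort reports zero reduction", {
  spec <- smallSpec(n = 3, duration = 6)
  pre <- generateCohort(spec)
  model <- local({
    sets <- lapply(pre, preprocessRecording, cfg = preprocessConfig(epochLength = 6))
    ft <- extractRegionFeatures(combineEpochSets(sets), cfg = shortWelch(1000))
    trainBpnn(as.matrix(ft[, stressEEG:::.FEATURE_NAMES]), ft$label,
              bpnnConfig(epochs = 40))
  })
  post <- lapply(pre[stressLevel(vapply(pre, stressLabel, "")) >= 3], function(r)
    methods::initialize(r, condition = "gentle"))
  out <- scoreRegulation(pre, post, model, cfg = shortWelch(1000),
                         preCfg = preprocessConfig(epochLength = 6))
  expect_equal(out$summary$percent_reduction, rep(0, nrow(out$summary)))
  expect_true(all(out$outcomes$objective_score >= 1 &
                    out$outcomes$objective_score <= 5))
  bad <- methods::initialize(post[[1]], subjectId = "GHOST")
  expect_error(scoreRegulation(pre, list(bad), model), "unpaired")
})
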