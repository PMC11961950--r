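# independent recomputation of the four metrics from one-vs-rest counts
metricOracle <- function(cm) {
  n <- sum(cm)
  prec <- rec <- f1 <- numeric(nrow(cm))
  for (k in seq_len(nrow(cm))) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  present <- rowSums(cm) > 0
  list(accuracy = sum(diag(cm)) / n, precision = mean(prec[present]),
       recall = mean(rec[present]), f1 = mean(f1[present]))
}

test_that("binary hand case gives accuracy .7, precision .75, recall .6, F1 2/3", {
  cm <- matrix(c(3, 2, 1, 4), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  # row 'pos': TP=3, FN=2; row 'neg': FP=1, TN=4
  m <- metricsFromConfusion(cm)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$perClass$precision[1], 0.75)
  expect_equal(m$perClass$recall[1], 0.6)
  expect_equal(m$perClass$f1[1], 2 / 3, tolerance = 1e-12)
  expect_equal(m$perClass[1, c("TP", "TN", "FP", "FN")],
               data.frame(TP = 3, TN = 4, FP = 1, FN = 2),
               ignore_attr = TRUE)
})

test_that("a perfect predictor scores 1 and an all-one-class predictor 1/k", {
  perfect <- diag(c(4, 6, 5, 3, 2))
  dimnames(perfect) <- list(stressEEG:::.STATE_NAMES, stressEEG:::.STATE_NAMES)
  m <- metricsFromConfusion(perfect)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  oneClass <- matrix(0, 5, 5, dimnames = dimnames(perfect))
  oneClass[, 1] <- 10  # balanced truth, everything predicted calm
  expect_equal(metricsFromConfusion(oneClass)$accuracy, 0.2)
})

test_that("metrics are reproducible from any random confusion matrix", {
  withr::local_seed(20)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 4), k, k)
    if (sum(cm) == 0) cm[1, 1] <- 1
    m <- metricsFromConfusion(cm)
    o <- metricOracle(cm)
    expect_equal(m[c("accuracy", "precision", "recall", "f1")], o)
    # F1 is the harmonic mean of per-class precision/recall before averaging
    pc <- m$perClass
    hm <- ifelse(pc$precision + pc$recall > 0,
                 2 * pc$precision * pc$recall / (pc$precision + pc$recall), 0)
    expect_equal(pc$f1, hm)
  }
})

test_that("stratified holdout preserves class proportions within one sample", {
  withr::local_seed(21)
  y <- rep(stressEEG:::.STATE_NAMES, times = c(60, 12, 16, 16, 16))
  sp <- stratifiedSplit(y, 0.7, seed = 5)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(y))
  for (cl in unique(y)) {
    nTr <- sum(y[sp$train] == cl)
    expect_lte(abs(nTr - 0.7 * sum(y == cl)), 1)
    expect_gte(sum(y[sp$test] == cl), 1)
  }
  expect_error(stratifiedSplit(c("calm", "severe", "severe"), 0.7, 1),
               "need >= 2")
})

test_that("the network fits separable clusters and is seed-deterministic", {
  d <- twoClusterFeatures()
  cfg <- bpnnConfig(epochs = 200, seed = 3)
  m <- trainBpnn(d$x, d$y, cfg)
  expect_gte(mean(predict(m, d$x) == d$y), 0.95)
  m2 <- trainBpnn(d$x, d$y, cfg)
  expect_identical(m$weights, m2$weights)
  expect_error(bpnnConfig(epochs = 0), "epochs")
  P <- predict(m, d$x, type = "prob")
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
  lv <- predict(m, d$x, type = "level")
  expect_true(all(lv >= 1 & lv <= 5))
})

test_that("zero-variance feature columns are dropped from scaling with a warning", {
  d <- twoClusterFeatures(10)
  d$x[, 2] <- 1
  expect_warning(m <- trainBpnn(d$x, d$y, bpnnConfig(epochs = 20)),
                 "zero-variance")
  expect_true(all(is.finite(predict(m, d$x, type = "prob"))))
})

test_that("a minimal GA run completes and refinement never worsens the GA-best", {
  d <- twoClusterFeatures(8)
  m <- trainGaBpnn(d$x, d$y, bpnnConfig(epochs = 10, seed = 2),
                   gaConfig(popSize = 2, nGenerations = 1, seed = 2))
  expect_s3_class(m, "bpnn")
  expect_lte(m$ga$finalLoss, m$ga$initialLoss)
  m2 <- trainGaBpnn(d$x, d$y, bpnnConfig(epochs = 10, seed = 2),
                    gaConfig(popSize = 2, nGenerations = 1, seed = 2))
  expect_identical(m$weights, m2$weights)
})

test_that("with crossover and mutation off the GA reduces to random restarts", {
  d <- twoClusterFeatures(10)
  bp <- bpnnConfig(epochs = 15, seed = 1)
  ga <- gaConfig(popSize = 6, nGenerations = 3, crossoverProb = 0,
                 mutationProb = 0, seed = 9)
  m <- trainGaBpnn(d$x, d$y, bp, ga)
  # replicate the GA's own initial population and pick the best by fitness
  std <- stressEEG:::.standardizer(d$x)
  Xs <- stressEEG:::.applyStd(d$x, std)
  classes <- c("calm", "severe")
  Y <- stressEEG:::.oneHot(d$y, classes)
  nw <- stressEEG:::.nWeights(5, bp$nHidden, 2)
  pop <- stressEEG:::withSeed(ga$seed, matrix(runif(ga$popSize * nw, -0.5, 0.5),
                                              ga$popSize, nw))
  fit <- apply(pop, 1, function(v) {
    wts <- stressEEG:::.decodeWeights(v, 5, bp$nHidden, 2)
    -stressEEG:::.mse(stressEEG:::.forward(wts, Xs, "sigmoid")$P, Y)
  })
  ref <- stressEEG:::.bpTrain(Xs, Y, pop[which.max(fit), ], bp)
  expect_equal(m$trainLoss, ref$loss, tolerance = 1e-12)
})

test_that("GA-initialized training matches or beats the median random start", {
  # overlapping 5-class problem at the study's 36-iteration budget: the
  # regime where the starting point matters
  mkData <- function(seed) {
    withr::local_seed(seed)
    x <- do.call(rbind, lapply(0:4, function(k)
      matrix(rnorm(24 * 5, k * 0.8, 1), 24, 5)))
    colnames(x) <- stressEEG:::.FEATURE_NAMES
    list(x = x, y = rep(stressEEG:::.STATE_NAMES, each = 24))
  }
  for (ds in c(100, 300)) {
    d <- mkData(ds)
    gaM <- trainGaBpnn(d$x, d$y, bpnnConfig(epochs = 36, seed = 1),
                       gaConfig(popSize = 30, nGenerations = 15, seed = 4))
    losses <- vapply(1:10, function(s)
      trainBpnn(d$x, d$y, bpnnConfig(epochs = 36, seed = s))$trainLoss,
      numeric(1))
    expect_lte(gaM$trainLoss, median(losses))
  }
})

test_that("evaluation reports are internally consistent", {
  withr::local_seed(22)
  x <- rbind(matrix(rnorm(40 * 5, 0), 40, 5), matrix(rnorm(40 * 5, 1.2), 40, 5),
             matrix(rnorm(40 * 5, 2.4), 40, 5))
  y <- rep(c("calm", "slight", "severe"), each = 40)
  for (mdl in c("knn", "nb", "bpnn")) {
    rp <- evaluateModel(x, y, model = mdl, split = "holdout", seed = 8,
                        bpCfg = bpnnConfig(epochs = 60))
    expect_equal(sum(confusionMatrix(rp)), rp@nTest)
    m <- metricOracle(confusionMatrix(rp))
    expect_equal(unname(metrics(rp)),
                 unname(unlist(m[c("accuracy", "precision", "recall", "f1")])))
  }
  loo <- evaluateModel(x[seq(1, 120, by = 6), ], y[seq(1, 120, by = 6)],
                       model = "knn", split = "loo", seed = 8)
  expect_equal(loo@nTest, 20L)
  expect_equal(sum(confusionMatrix(loo)), 20)
})

test_that("region comparison handles restricted rosters and null signals", {
  withr::local_seed(23)
  oneRegion <- data.frame(subject_id = sprintf("s%02d", 1:40),
                          label = rep(c("calm", "severe"), each = 20),
                          condition = "baseline",
                          matrix(rnorm(40 * 5), 40, 5))
  names(oneRegion)[4:8] <- stressEEG:::.FEATURE_NAMES
  ft <- do.call(rbind, lapply(c("Fp", "F", "C", "P", "O"), function(r) {
    d <- oneRegion; d$region <- r; d
  }))
  cmp <- compareModelsByRegion(ft, models = "knn", seed = 3)
  expect_length(cmp$reports, 5)
  # identical features in every region -> identical reports per region
  accs <- vapply(cmp$reports, function(r) r@accuracy, numeric(1))
  expect_equal(unname(diff(range(accs))), 0)
  expect_error(evaluateModel(matrix(rnorm(20), 4, 5), rep("calm", 4)),
               "at least 2 classes|need")
})
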