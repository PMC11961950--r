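#' Metrics from a confusion matrix
#'
#' Computes the evaluation metrics from a square confusion matrix (rows =
#' true class, columns = predicted).  Accuracy is the overall fraction of
#' correct predictions, (TP + TN) / (TP + TN + FP + FN) in the binary case;
#' precision TP / (TP + FP), recall TP / (TP + FN) and F1 (their harmonic
#' mean) are computed one-vs-rest per class and macro-averaged over the
#' classes present in the truth.  A class never predicted gets precision 0
#' by convention.
#'
#' @param confusion Square count matrix with identical row/column order.
#' @return List: accuracy, precision, recall, f1, and a perClass data.frame
#'   of TP/TN/FP/FN and per-class precision/recall/f1.
#' @examples
#' cm <- matrix(c(3, 1, 2, 4), 2, 2, byrow = TRUE,
#'              dimnames = list(c("pos", "neg"), c("pos", "neg")))
#' metricsFromConfusion(cm)$accuracy  # 0.7
#' @export
metricsFromConfusion <- function(confusion) {
  if (nrow(confusion) != ncol(confusion)) .stopf("confusion matrix must be square")
  n <- sum(confusion)
  if (n == 0) .stopf("empty confusion matrix")
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(confusion) > 0
  perClass <- data.frame(class = rownames(confusion) %||% as.character(seq_along(tp)),
                         TP = tp, TN = tn, FP = fp, FN = fn,
                         precision = prec, recall = rec, f1 = f1,
                         row.names = NULL)
  list(accuracy = sum(tp) / n,
       precision = mean(prec[present]),
       recall = mean(rec[present]),
       f1 = mean(f1[present]),
       perClass = perClass)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified holdout split
#'
#' Splits sample indices into train/test per class, preserving class
#' proportions within one sample per class and guaranteeing every class
#' appears in both sets.
#'
#' @param y Class labels.
#' @param trainFrac Training fraction in (0,1).
#' @param seed Integer seed.
#' @return List with integer vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(y, trainFrac = 0.7, seed = 1L) {
  if (trainFrac <= 0 || trainFrac >= 1) .stopf("trainFrac must lie in (0,1)")
  withSeed(seed, {
    tr <- integer(0)
    for (cl in unique(y)) {
      i <- which(y == cl)
      if (length(i) < 2)
        .stopf("class '%s' has %d sample(s); need >= 2 for a stratified holdout",
               cl, length(i))
      k <- max(1L, min(length(i) - 1L, round(trainFrac * length(i))))
      tr <- c(tr, sample(i)[seq_len(k)])
    }
    tr <- sort(tr)
    list(train = tr, test = setdiff(seq_along(y), tr))
  })
}

.MODEL_ROSTER <- c("ga_bpnn", "bpnn", "knn", "svm", "nb", "lr")

# unified fit/predict over the six-model roster; x is the feature matrix,
# y state names.  Seed covers every stochastic step of a model.
.fitModel <- function(model, x, y, seed, bpCfg, gaCfg, knnK = 5) {
  x <- as.matrix(x)
  switch(model,
    ga_bpnn = {
      m <- trainGaBpnn(x, y, .reseed(bpCfg, seed), .reseedGa(gaCfg, seed + 1))
      list(predict = function(nx) predict(m, nx), fit = m)
    },
    bpnn = {
      m <- trainBpnn(x, y, .reseed(bpCfg, seed))
      list(predict = function(nx) predict(m, nx), fit = m)
    },
    knn = {
      std <- .standardizer(x); Xs <- .applyStd(x, std)
      list(predict = function(nx) withSeed(seed,
        as.character(class::knn(Xs, .applyStd(as.matrix(nx), std),
                                cl = factor(y), k = knnK))))
    },
    svm = {
      std <- .standardizer(x); Xs <- .applyStd(x, std)
      m <- withSeed(seed, e1071::svm(Xs, factor(y), kernel = "radial", scale = FALSE))
      list(predict = function(nx) as.character(predict(m, .applyStd(as.matrix(nx), std))),
           fit = m)
    },
    nb = {
      m <- e1071::naiveBayes(as.data.frame(x), factor(y))
      # floor degenerate within-class SDs (zero or NA for single-sample
      # classes) with the pooled feature SD so densities stay defined
      pooled <- apply(x, 2, stats::sd)
      for (j in seq_along(m$tables)) {
        s <- m$tables[[j]][, 2]
        bad <- !is.finite(s) | s <= 0
        m$tables[[j]][bad, 2] <- max(pooled[j], 1e-8)
      }
      list(predict = function(nx) as.character(predict(m, as.data.frame(as.matrix(nx)))),
           fit = m)
    },
    lr = {
      std <- .standardizer(x); Xs <- .applyStd(x, std)
      df <- data.frame(y = factor(y), Xs)
      m <- withSeed(seed, nnet::multinom(y ~ ., data = df, decay = 1e-3,
                                         maxit = 200, trace = FALSE))
      list(predict = function(nx) {
        nd <- as.data.frame(.applyStd(as.matrix(nx), std))
        as.character(predict(m, nd))
      }, fit = m)
    },
    .stopf("unknown model: %s (roster: %s)", model,
           paste(.MODEL_ROSTER, collapse = ", ")))
}

.reseed <- function(cfg, seed) { cfg$seed <- as.integer(seed %% 2147483647); cfg }
.reseedGa <- .reseed

#' Train and evaluate one classifier
#'
#' Fits one of the six roster models (\code{ga_bpnn}, \code{bpnn},
#' \code{knn}, \code{svm}, \code{nb}, \code{lr}) and evaluates it either on
#' a stratified 70/30 holdout or by leave-one-out cross-validation, in
#' which every sample is predicted by a model trained on all others.
#' Features are z-scored on training statistics only.
#'
#' @param x Feature matrix (rows = recordings, columns = the 5 features).
#' @param y Stress-state names aligned with rows of \code{x}.
#' @param model Model name from the roster.
#' @param split "holdout" or "loo".
#' @param trainFrac Training fraction for the holdout split.
#' @param seed Integer seed shared by split and model fitting.
#' @param bpCfg,gaCfg Network / GA configurations for the neural models.
#' @param region Optional region tag stored in the report.
#' @return A \linkS4class{ClassifierReport}.
#' @export
evaluateModel <- function(x, y, model = "ga_bpnn",
                          split = c("holdout", "loo"), trainFrac = 0.7,
                          seed = 1L, bpCfg = bpnnConfig(), gaCfg = gaConfig(),
                          region = NA_character_) {
  split <- match.arg(split)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) .stopf("x and y must align")
  classes <- .STATE_NAMES[.STATE_NAMES %in% unique(y)]
  if (split == "holdout") {
    sp <- stratifiedSplit(y, trainFrac, seed)
    fit <- .fitModel(model, x[sp$train, , drop = FALSE], y[sp$train],
                     seed, bpCfg, gaCfg)
    pred <- fit$predict(x[sp$test, , drop = FALSE])
    truth <- y[sp$test]
    nTrain <- length(sp$train); nTest <- length(sp$test)
  } else {
    pred <- character(length(y))
    for (i in seq_along(y)) {
      fit <- .fitModel(model, x[-i, , drop = FALSE], y[-i], seed, bpCfg, gaCfg)
      pred[i] <- fit$predict(x[i, , drop = FALSE])
    }
    truth <- y
    nTrain <- length(y) - 1L; nTest <- length(y)
  }
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(classes, classes)
  met <- metricsFromConfusion(cm)
  new("ClassifierReport", model = model, region = region,
      accuracy = met$accuracy, precision = met$precision,
      recall = met$recall, f1 = met$f1, confusion = cm,
      perClass = met$perClass, nTrain = as.integer(nTrain),
      nTest = as.integer(nTest), split = split)
}

#' Compare the model roster across brain regions
#'
#' Trains and evaluates every requested model on every region's feature
#' vectors with a shared split seed, returning all reports plus a summary
#' ranked by accuracy and the best region x model cell.
#'
#' @param featureTable Region feature table from
#'   \code{\link{extractRegionFeatures}} (baseline recordings only are
#'   selected automatically).
#' @param models Model names (default: the full six-model roster).
#' @param split,trainFrac,seed,bpCfg,gaCfg Passed to
#'   \code{\link{evaluateModel}}.
#' @return List of class \code{"regionComparison"}: \code{reports} (list of
#'   \linkS4class{ClassifierReport}), \code{summary} (ranked data.frame),
#'   \code{best} (model/region/accuracy of the top cell).
#' @export
compareModelsByRegion <- function(featureTable, models = .MODEL_ROSTER,
                                  split = "holdout", trainFrac = 0.7,
                                  seed = 1L, bpCfg = bpnnConfig(),
                                  gaCfg = gaConfig()) {
  stopifnot(all(c("region", "label", "condition", .FEATURE_NAMES) %in%
                  names(featureTable)))
  ft <- featureTable[featureTable$condition %in% c("baseline", "none"), ]
  regions <- unique(ft$region)
  reports <- list()
  for (m in models) {
    for (r in regions) {
      sub <- ft[ft$region == r, ]
      sub <- sub[order(sub$subject_id), ]
      rep <- evaluateModel(as.matrix(sub[, .FEATURE_NAMES]), sub$label,
                           model = m, split = split, trainFrac = trainFrac,
                           seed = seed, bpCfg = bpCfg, gaCfg = gaCfg,
                           region = r)
      reports[[paste(m, r, sep = ".")]] <- rep
    }
  }
  summary <- do.call(rbind, lapply(reports, function(rp)
    data.frame(model = rp@model, region = rp@region,
               accuracy = rp@accuracy, precision = rp@precision,
               recall = rp@recall, f1 = rp@f1, stringsAsFactors = FALSE)))
  summary <- summary[order(-summary$accuracy, -summary$f1), ]
  rownames(summary) <- NULL
  best <- as.list(summary[1, c("model", "region", "accuracy")])
  structure(list(reports = reports, summary = summary, best = best),
            class = "regionComparison")
}

#' @export
print.regionComparison <- function(x, ...) {
  cat(sprintf("Model x region comparison: %d cells; best %s on %s (accuracy %.3f)\n",
              nrow(x$summary), x$best$model, x$best$region, x$best$accuracy))
  print(utils::head(x$summary, 10))
  invisible(x)
}
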