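#' Backpropagation network configuration
#'
#' Architecture and training parameters of the fully connected 5-5-5
#' stress classifier: five input neurons (one per feature), five hidden
#' neurons, five output neurons (one per stress state), trained by
#' full-batch gradient backpropagation on one-hot targets with a
#' softmax/cross-entropy output layer over 36 iterations by default.
#'
#' @param nHidden Hidden-layer size.
#' @param epochs Training iterations (>= 1).
#' @param learningRate Positive gradient step size.
#' @param activation Hidden activation, "sigmoid" or "tanh".
#' @param seed Integer seed for weight initialization.
#' @return List of class \code{"BPNNConfig"}.
#' @export
bpnnConfig <- function(nHidden = 5, epochs = 36, learningRate = 1.0,
                       activation = c("sigmoid", "tanh"), seed = 1L) {
  activation <- match.arg(activation)
  if (nHidden < 1) .stopf("nHidden must be >= 1")
  if (epochs < 1) .stopf("epochs must be >= 1")
  if (learningRate <= 0) .stopf("learningRate must be positive")
  structure(list(nHidden = as.integer(nHidden), epochs = as.integer(epochs),
                 learningRate = learningRate, activation = activation,
                 seed = as.integer(seed)),
            class = "BPNNConfig")
}

.act <- function(z, type) if (type == "tanh") tanh(z) else 1 / (1 + exp(-z))
.actGrad <- function(a, type) if (type == "tanh") 1 - a^2 else a * (1 - a)

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# weight vector <-> layer matrices
.nWeights <- function(nIn, nHidden, nOut) nIn * nHidden + nHidden + nHidden * nOut + nOut

.decodeWeights <- function(v, nIn, nHidden, nOut) {
  i <- 0
  W1 <- matrix(v[i + seq_len(nIn * nHidden)], nIn, nHidden); i <- i + nIn * nHidden
  b1 <- v[i + seq_len(nHidden)]; i <- i + nHidden
  W2 <- matrix(v[i + seq_len(nHidden * nOut)], nHidden, nOut); i <- i + nHidden * nOut
  b2 <- v[i + seq_len(nOut)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.forward <- function(wts, X, activation) {
  H <- .act(sweep(X %*% wts$W1, 2, wts$b1, "+"), activation)
  P <- .softmax(sweep(H %*% wts$W2, 2, wts$b2, "+"))
  list(H = H, P = P)
}

.xent <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))
.mse <- function(P, Y) mean((P - Y)^2)

# z-score statistics on training data; zero-variance columns are left
# unscaled (with a warning) rather than producing NaN
.standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    warning("zero-variance feature column(s): ",
            paste(colnames(X)[scl == 0], collapse = ", "),
            "; left unscaled")
    scl[scl == 0] <- 1
  }
  list(center = ctr, scale = scl)
}

.applyStd <- function(X, std) scale(X, center = std$center, scale = std$scale)

# gradient refinement from a given weight vector; returns the weights with
# the lowest training loss seen during the run (the loss trajectory of
# plain full-batch descent is not guaranteed monotone)
.bpTrain <- function(X, Y, w0, cfg) {
  nIn <- ncol(X); nOut <- ncol(Y); nH <- cfg$nHidden
  wts <- .decodeWeights(w0, nIn, nH, nOut)
  n <- nrow(X)
  best <- wts
  fw <- .forward(wts, X, cfg$activation)
  bestLoss <- .xent(fw$P, Y)
  trace <- numeric(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    fw <- .forward(wts, X, cfg$activation)
    dZ2 <- (fw$P - Y) / n                       # softmax + cross-entropy
    gW2 <- t(fw$H) %*% dZ2
    gb2 <- colSums(dZ2)
    dH <- dZ2 %*% t(wts$W2) * .actGrad(fw$H, cfg$activation)
    gW1 <- t(X) %*% dH
    gb1 <- colSums(dH)
    wts$W1 <- wts$W1 - cfg$learningRate * gW1
    wts$b1 <- wts$b1 - cfg$learningRate * gb1
    wts$W2 <- wts$W2 - cfg$learningRate * gW2
    wts$b2 <- wts$b2 - cfg$learningRate * gb2
    loss <- .xent(.forward(wts, X, cfg$activation)$P, Y)
    trace[e] <- loss
    if (loss < bestLoss) { bestLoss <- loss; best <- wts }
  }
  list(weights = best, loss = bestLoss, trace = trace)
}

.oneHot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

.randomWeights <- function(nw) stats::runif(nw, -0.5, 0.5)

.newBpnn <- function(fit, std, classes, cfg, ga = NULL) {
  structure(list(weights = fit$weights, trainLoss = fit$loss,
                 trace = fit$trace, standardizer = std, classes = classes,
                 config = cfg, ga = ga),
            class = "bpnn")
}

#' Train the backpropagation stress classifier
#'
#' Trains the fully connected 5-5-5 network: features are z-scored on
#' training statistics, targets one-hot encoded, and the weights updated by
#' full-batch gradient descent on the softmax cross-entropy for
#' \code{cfg$epochs} iterations.  The returned model carries the weights
#' with the lowest training loss observed.  Deterministic given
#' \code{cfg$seed}.
#'
#' @param x Numeric feature matrix (rows = samples, columns = features).
#' @param y Stress labels (state names), at least two distinct classes.
#' @param cfg A \code{\link{bpnnConfig}}.
#' @return Object of class \code{"bpnn"} with \code{predict} support.
#' @export
trainBpnn <- function(x, y, cfg = bpnnConfig()) {
  x <- as.matrix(x)
  classes <- .STATE_NAMES[.STATE_NAMES %in% unique(y)]
  if (length(classes) < 2) .stopf("need at least 2 classes to train")
  std <- .standardizer(x)
  Xs <- .applyStd(x, std)
  Y <- .oneHot(y, classes)
  nw <- .nWeights(ncol(x), cfg$nHidden, length(classes))
  fit <- withSeed(cfg$seed, .bpTrain(Xs, Y, .randomWeights(nw), cfg))
  .newBpnn(fit, std, classes, cfg)
}

#' Predict stress states from a trained network
#'
#' @param object A \code{"bpnn"} model.
#' @param newdata Feature matrix with the training columns.
#' @param type "class" for state names, "prob" for the softmax matrix,
#'   "level" for the probability-weighted expected stress level in [1,5].
#' @param ... Ignored.
#' @return Character vector of state names, a probability matrix, or a
#'   numeric vector of expected levels.
#' @export
predict.bpnn <- function(object, newdata, type = c("class", "prob", "level"), ...) {
  type <- match.arg(type)
  Xs <- .applyStd(as.matrix(newdata), object$standardizer)
  P <- .forward(object$weights, Xs, object$config$activation)$P
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  if (type == "level") return(drop(P %*% stressLevel(object$classes)))
  object$classes[max.col(P, ties.method = "first")]
}

# continuous model-predicted stress level: probability-weighted for models
# exposing class probabilities, the predicted class's level otherwise
.predictLevel <- function(model, X) {
  if (inherits(model, "bpnn")) predict(model, X, type = "level")
  else stressLevel(predict(model, X))
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("BPNN %d-%d-%d (%s), %d epochs, train loss %.4f%s\n",
              nrow(x$weights$W1), x$config$nHidden, length(x$classes),
              x$config$activation, x$config$epochs, x$trainLoss,
              if (!is.null(x$ga)) " [GA-initialized]" else ""))
  invisible(x)
}
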