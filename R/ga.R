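#' Genetic-algorithm configuration
#'
#' Parameters of the genetic algorithm that selects the initial weights of
#' the GA-BPNN: population of real-valued flat weight vectors evolved by
#' tournament selection, blend (BLX) crossover and Gaussian mutation, with
#' elitism.  Fitness is the negative training MSE of the decoded network
#' (\code{"neg_train_mse"}, cheap and deterministic) or the accuracy on an
#' internal stratified validation split (\code{"val_accuracy"}).
#'
#' @param popSize Population size (>= 2).
#' @param nGenerations Number of generations.
#' @param crossoverProb Per-pair crossover probability in [0,1].
#' @param mutationProb Per-gene mutation probability in [0,1].
#' @param mutationSd SD of Gaussian mutation noise.
#' @param fitness "neg_train_mse" or "val_accuracy".
#' @param seed Integer seed for the evolutionary run.
#' @return List of class \code{"GAConfig"}.
#' @export
gaConfig <- function(popSize = 40, nGenerations = 30, crossoverProb = 0.8,
                     mutationProb = 0.1, mutationSd = 0.3,
                     fitness = c("neg_train_mse", "val_accuracy"), seed = 1L) {
  fitness <- match.arg(fitness)
  if (popSize < 2) .stopf("popSize must be >= 2")
  p <- c(crossoverProb, mutationProb)
  if (any(p < 0 | p > 1)) .stopf("probabilities must lie in [0,1]")
  structure(list(popSize = as.integer(popSize),
                 nGenerations = as.integer(nGenerations),
                 crossoverProb = crossoverProb, mutationProb = mutationProb,
                 mutationSd = mutationSd, fitness = fitness,
                 seed = as.integer(seed)),
            class = "GAConfig")
}

# internal stratified split for the val_accuracy fitness
.valSplit <- function(y, frac = 0.8) {
  tr <- integer(0)
  for (cl in unique(y)) {
    i <- which(y == cl)
    k <- max(1L, min(length(i) - 1L, round(frac * length(i))))
    tr <- c(tr, sample(i)[seq_len(k)])
  }
  sort(tr)
}

#' Train the GA-optimized backpropagation classifier
#'
#' Evolves a population of candidate weight vectors for the 5-5-5 network
#' (tournament selection of size 3 with one elite, per-gene blend
#' crossover, Gaussian mutation), then refines the best individual by
#' gradient backpropagation exactly as \code{\link{trainBpnn}} does.  The
#' evolutionary search replaces the single random initialization of the
#' plain network, guarding against poor local optima.  Deterministic given
#' both seeds.
#'
#' @inheritParams trainBpnn
#' @param bpCfg A \code{\link{bpnnConfig}} for the refinement run.
#' @param gaCfg A \code{\link{gaConfig}}.
#' @return Object of class \code{"bpnn"}; its \code{ga} element records the
#'   best fitness per generation and the GA-best individual's pre- and
#'   post-refinement training loss.
#' @export
trainGaBpnn <- function(x, y, bpCfg = bpnnConfig(), gaCfg = gaConfig()) {
  x <- as.matrix(x)
  classes <- .STATE_NAMES[.STATE_NAMES %in% unique(y)]
  if (length(classes) < 2) .stopf("need at least 2 classes to train")
  std <- .standardizer(x)
  Xs <- .applyStd(x, std)
  Y <- .oneHot(y, classes)
  nw <- .nWeights(ncol(x), bpCfg$nHidden, length(classes))

  gaOut <- withSeed(gaCfg$seed, {
    if (gaCfg$fitness == "val_accuracy") {
      tr <- .valSplit(y)
      va <- setdiff(seq_len(nrow(Xs)), tr)
      if (!length(va)) .stopf("too few samples for val_accuracy fitness")
      fitFun <- function(v) {
        wts <- .decodeWeights(v, ncol(Xs), bpCfg$nHidden, length(classes))
        P <- .forward(wts, Xs[va, , drop = FALSE], bpCfg$activation)$P
        mean(classes[max.col(P, ties.method = "first")] == y[va])
      }
    } else {
      fitFun <- function(v) {
        wts <- .decodeWeights(v, ncol(Xs), bpCfg$nHidden, length(classes))
        -.mse(.forward(wts, Xs, bpCfg$activation)$P, Y)
      }
    }
    pop <- matrix(stats::runif(gaCfg$popSize * nw, -0.5, 0.5), gaCfg$popSize, nw)
    fit <- apply(pop, 1, fitFun)
    bestPerGen <- numeric(gaCfg$nGenerations)
    for (gen in seq_len(gaCfg$nGenerations)) {
      elite <- pop[which.max(fit), ]
      tournament <- function() {
        cand <- sample.int(gaCfg$popSize, 3, replace = TRUE)
        pop[cand[which.max(fit[cand])], ]
      }
      newPop <- matrix(0, gaCfg$popSize, nw)
      newPop[1, ] <- elite
      j <- 2L
      while (j <= gaCfg$popSize) {
        p1 <- tournament(); p2 <- tournament()
        if (stats::runif(1) < gaCfg$crossoverProb) {
          # per-gene blend: child = u*p1 + (1-u)*p2, u ~ U(-0.25, 1.25)
          u <- stats::runif(nw, -0.25, 1.25)
          c1 <- u * p1 + (1 - u) * p2
          c2 <- (1 - u) * p1 + u * p2
        } else {
          c1 <- p1; c2 <- p2
        }
        mutate <- function(v) {
          hit <- stats::runif(nw) < gaCfg$mutationProb
          v[hit] <- v[hit] + stats::rnorm(sum(hit), 0, gaCfg$mutationSd)
          v
        }
        newPop[j, ] <- mutate(c1)
        if (j + 1L <= gaCfg$popSize) newPop[j + 1L, ] <- mutate(c2)
        j <- j + 2L
      }
      pop <- newPop
      fit <- apply(pop, 1, fitFun)
      bestPerGen[gen] <- max(fit)
    }
    list(best = pop[which.max(fit), ], bestPerGen = bestPerGen)
  })

  initLoss <- .xent(.forward(
    .decodeWeights(gaOut$best, ncol(Xs), bpCfg$nHidden, length(classes)),
    Xs, bpCfg$activation)$P, Y)
  fitRes <- .bpTrain(Xs, Y, gaOut$best, bpCfg)
  # refinement keeps the best-loss weights, so it can never end worse than
  # the GA-best individual it started from
  if (initLoss < fitRes$loss) {
    fitRes$weights <- .decodeWeights(gaOut$best, ncol(Xs), bpCfg$nHidden,
                                     length(classes))
    fitRes$loss <- initLoss
  }
  .newBpnn(fitRes, std, classes, bpCfg,
           ga = list(config = gaCfg, bestPerGen = gaOut$bestPerGen,
                     initialLoss = initLoss, finalLoss = fitRes$loss))
}
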