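## Five-class window classifier: a small convolutional network over the
## 12 x k feature matrix (one channel; a 3x3 convolution sees how each
## statistic co-varies with its neighbours across adjacent subwindows),
## followed by a dense ReLU layer and a 5-way softmax.  Implemented with
## plain matrix algebra: inputs are tiny (132 values) and training sets are
## a few thousand rows, so vectorized R with Adam updates trains in
## seconds and keeps the package dependency-free.

#' SweepClassifier: a trained five-class window classifier
#'
#' @slot weights List of layer weight matrices and biases.
#' @slot config Architecture and optimizer configuration.
#' @slot center,scale Per-feature standardization learned on the training
#'   set.
#' @slot classes Class labels in posterior-column order.
#' @slot history data.frame of per-epoch training and validation losses.
#' @slot seed The training seed.
#' @export
setClass("SweepClassifier",
  representation(weights = "list", config = "list", center = "numeric",
                 scale = "numeric", classes = "character",
                 history = "data.frame", seed = "numeric"))

setMethod("show", "SweepClassifier", function(object) {
  cat("SweepClassifier: conv(", object@config$filters, " x ",
      paste(object@config$kernel, collapse = "x"), ") -> dense(",
      object@config$hidden, ") -> softmax(5); trained ",
      nrow(object@history), " epochs, best val loss ",
      signif(min(object@history$val_loss), 4), "\n", sep = "")
})

## ---- architecture helpers ------------------------------------------------

## feature vectors are stat-major: element (stat-1)*k + sw + 1.
## im2col index for a 3x3 valid convolution over the 12 x k grid.
.convIndex <- function(nStat, k, kernel) {
  kr <- kernel[1]; kc <- kernel[2]
  outR <- nStat - kr + 1
  outC <- k - kc + 1
  idx <- integer(outR * outC * kr * kc)
  pos <- 1L
  for (a in seq_len(outR)) {
    for (b in seq_len(outC)) {
      for (da in seq_len(kr) - 1) {
        for (db in seq_len(kc) - 1) {
          idx[pos] <- (a + da - 1) * k + (b + db)
          pos <- pos + 1L
        }
      }
    }
  }
  list(idx = idx, nPatch = outR * outC, patchLen = kr * kc)
}

.relu <- function(x) { x[x < 0] <- 0; x }

.softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## forward pass; returns intermediates when `full` (for backprop)
.nnForward <- function(W, X, ci, full = FALSE) {
  n <- nrow(X)
  nF <- ncol(W$W1)
  P <- X[, ci$idx, drop = FALSE]
  Pmat <- t(matrix(t(P), nrow = ci$patchLen))        # (n*nPatch) x patchLen
  Z1 <- sweep(Pmat %*% W$W1, 2, W$b1, "+")
  A1 <- .relu(Z1)
  H <- t(matrix(aperm(array(A1, c(ci$nPatch, n, nF)), c(1, 3, 2)),
                nrow = ci$nPatch * nF))              # n x (nPatch*nF)
  Z2 <- sweep(H %*% W$W2, 2, W$b2, "+")
  A2 <- .relu(Z2)
  Z3 <- sweep(A2 %*% W$W3, 2, W$b3, "+")
  probs <- .softmaxRows(Z3)
  if (!full) return(probs)
  list(probs = probs, Pmat = Pmat, Z1 = Z1, H = H, Z2 = Z2, A2 = A2, n = n)
}

.crossEntropy <- function(probs, yIdx) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), yIdx)], 1e-12)))
}

## column permutation that reverses subwindow order within every statistic
## row.  The generative process is mirror-symmetric (sweep placement is
## uniform over subwindows, and each non-central placement has its mirror
## image in the same class), so flipped feature rows are equally valid
## training examples of the same class.
.mirrorIndex <- function(nStat, k) {
  as.integer(sapply(seq_len(nStat) - 1, function(s) s * k + rev(seq_len(k))))
}

## gradient of the mean cross-entropy w.r.t. all weights
.nnGradient <- function(W, fw, yIdx, ci) {
  n <- fw$n
  nF <- ncol(W$W1)
  dZ3 <- fw$probs
  dZ3[cbind(seq_len(n), yIdx)] <- dZ3[cbind(seq_len(n), yIdx)] - 1
  dZ3 <- dZ3 / n
  dW3 <- crossprod(fw$A2, dZ3); db3 <- colSums(dZ3)
  dA2 <- tcrossprod(dZ3, W$W3)
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$H, dZ2); db2 <- colSums(dZ2)
  dH <- tcrossprod(dZ2, W$W2)                        # n x (nPatch*nF)
  dA1 <- matrix(aperm(array(t(dH), c(ci$nPatch, nF, n)), c(1, 3, 2)),
                ncol = nF)                           # (n*nPatch) x nF
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$Pmat, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Train the sweep classifier
#'
#' Trains the convolutional softmax network on a balanced labeled feature
#' table with mini-batch Adam, holding out `valFraction` of the training
#' examples (stratified by class) as a validation set for early stopping:
#' when `patience` consecutive epochs fail to improve the best validation
#' cross-entropy by at least `minDelta`, training stops and the weights
#' with the lowest validation loss seen so far are returned.
#'
#' @param features n x (12 k) numeric matrix (see [featureTable()]).
#' @param labels Character vector of true classes ([sweepClasses()]).
#' @param valFraction Fraction held out for validation (default 0.1).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param minDelta Minimum validation-loss improvement (default 0.001).
#' @param filters,kernel,hidden Architecture: number of 2-D convolution
#'   filters, kernel size, dense-layer width.
#' @param epochs Maximum number of epochs.
#' @param batchSize Mini-batch size.
#' @param learningRate Adam step size.
#' @param weightDecay Decoupled L2 penalty applied to the weight matrices
#'   (not the biases) at each update.
#' @param augmentMirror Augment the training split (never the validation
#'   split) with subwindow-order-reversed copies; the simulation process is
#'   mirror-symmetric, so flips are label-preserving.
#' @param nSubwindows Number of subwindows per statistic row.
#' @param seed Training seed (weight init, validation split, shuffling).
#' @return A [SweepClassifier-class].
#' @export
trainSweepClassifier <- function(features, labels, valFraction = 0.1,
                                 patience = 5, minDelta = 0.001,
                                 filters = 16, kernel = c(3, 3), hidden = 64,
                                 epochs = 200, batchSize = 32,
                                 learningRate = 1e-3, weightDecay = 1e-2,
                                 augmentMirror = TRUE, nSubwindows = 11,
                                 seed = 1) {
  if (length(unique(labels)) < 2)
    stop("need at least two classes to train")
  if (!all(labels %in% sweepClasses()))
    stop("unknown class labels: ",
         paste(setdiff(labels, sweepClasses()), collapse = ", "))
  if (valFraction <= 0 || valFraction >= 1)
    stop("valFraction must be in (0, 1)")
  classes <- sweepClasses()
  yIdx <- match(labels, classes)
  nStat <- ncol(features) / nSubwindows
  ci <- .convIndex(nStat, nSubwindows, kernel)

  center <- colMeans(features)
  scl <- apply(features, 2, sd)
  scl[scl == 0] <- 1
  X <- sweep(sweep(features, 2, center), 2, scl, "/")

  .withSeed(seed, {
    ## stratified validation split
    valIdx <- unlist(lapply(unique(yIdx), function(c) {
      pool <- which(yIdx == c)
      sample(pool, max(1, round(valFraction * length(pool))))
    }))
    trIdx <- setdiff(seq_len(nrow(X)), valIdx)
    Xtr <- X[trIdx, , drop = FALSE]; ytr <- yIdx[trIdx]
    Xva <- X[valIdx, , drop = FALSE]; yva <- yIdx[valIdx]
    if (augmentMirror) {
      mi <- .mirrorIndex(nStat, nSubwindows)
      Xtr <- rbind(Xtr, Xtr[, mi, drop = FALSE])
      ytr <- c(ytr, ytr)
    }

    nF <- filters
    W <- list(
      W1 = matrix(rnorm(ci$patchLen * nF, sd = sqrt(2 / ci$patchLen)),
                  ci$patchLen, nF),
      b1 = numeric(nF),
      W2 = matrix(rnorm(ci$nPatch * nF * hidden,
                        sd = sqrt(2 / (ci$nPatch * nF))),
                  ci$nPatch * nF, hidden),
      b2 = numeric(hidden),
      W3 = matrix(rnorm(hidden * 5, sd = sqrt(2 / hidden)), hidden, 5),
      b3 = numeric(5))
    mAdam <- lapply(W, function(w) w * 0)
    vAdam <- lapply(W, function(w) w * 0)
    beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8
    step <- 0

    best <- list(loss = Inf, W = W, epoch = 0)
    badEpochs <- 0
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample(nrow(Xtr))
      batches <- split(ord, ceiling(seq_along(ord) / batchSize))
      for (b in batches) {
        fw <- .nnForward(W, Xtr[b, , drop = FALSE], ci, full = TRUE)
        g <- .nnGradient(W, fw, ytr[b], ci)
        step <- step + 1
        for (nm in names(W)) {
          mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g[[nm]]
          vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g[[nm]]^2
          mh <- mAdam[[nm]] / (1 - beta1^step)
          vh <- vAdam[[nm]] / (1 - beta2^step)
          upd <- learningRate * mh / (sqrt(vh) + epsAdam)
          if (weightDecay > 0 && is.matrix(W[[nm]]))
            upd <- upd + learningRate * weightDecay * W[[nm]]
          W[[nm]] <- W[[nm]] - upd
        }
      }
      trLoss <- .crossEntropy(.nnForward(W, Xtr, ci), ytr)
      vaLoss <- .crossEntropy(.nnForward(W, Xva, ci), yva)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = trLoss,
                                     val_loss = vaLoss))
      if (vaLoss < best$loss - minDelta) {
        badEpochs <- 0
      } else {
        badEpochs <- badEpochs + 1
      }
      if (vaLoss < best$loss)
        best <- list(loss = vaLoss, W = W, epoch = ep)
      if (badEpochs >= patience) break
    }
    new("SweepClassifier", weights = best$W,
        config = list(filters = filters, kernel = kernel, hidden = hidden,
                      nSubwindows = nSubwindows, nStat = nStat,
                      batchSize = batchSize, learningRate = learningRate,
                      weightDecay = weightDecay,
                      augmentMirror = augmentMirror,
                      valFraction = valFraction, patience = patience,
                      minDelta = minDelta, bestEpoch = best$epoch),
        center = center, scale = scl, classes = classes, history = hist,
        seed = as.numeric(seed))
  })
}

#' Predict class posteriors
#'
#' Applies the trained network to one [FeatureMatrix-class] or to a feature
#' table; the softmax output is the five-class posterior. Deterministic
#' given fixed weights. A list of classifiers (an ensemble trained with
#' different seeds) yields the average of the members' posteriors, which
#' smooths seed-to-seed variability of single small networks.
#'
#' @param model A [SweepClassifier-class], or a list of them.
#' @param features A [FeatureMatrix-class] or an n x (12 k) matrix.
#' @return n x 5 matrix of class probabilities (columns [sweepClasses()]),
#'   rows summing to 1.
#' @export
predictPosterior <- function(model, features) {
  if (is.list(model) && !is(model, "SweepClassifier")) {
    posts <- lapply(model, predictPosterior, features = features)
    return(Reduce(`+`, posts) / length(posts))
  }
  if (is(features, "FeatureMatrix"))
    features <- matrix(as.numeric(t(featureValues(features))), nrow = 1)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model@center))
    stop("feature dimension ", ncol(features), " does not match the model (",
         length(model@center), ")")
  X <- sweep(sweep(features, 2, model@center), 2, model@scale, "/")
  ci <- .convIndex(model@config$nStat, model@config$nSubwindows,
                   model@config$kernel)
  probs <- .nnForward(model@weights, X, ci)
  colnames(probs) <- model@classes
  probs
}

#' Training history accessor
#' @param x A SweepClassifier.
#' @return data.frame with per-epoch train and validation loss.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "SweepClassifier", function(x) x@history)

#' Serialize / restore a trained classifier
#'
#' Saves weights, configuration, standardization and training history to
#' JSON so a scan can be reproduced with the exact trained model.
#'
#' @param model A [SweepClassifier-class].
#' @param path Output (input) path.
#' @return `path` (or the restored [SweepClassifier-class]).
#' @export
saveSweepClassifier <- function(model, path) {
  obj <- list(weights = lapply(model@weights, function(w)
                if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
                else list(dim = NULL, data = as.numeric(w))),
              config = model@config, center = model@center,
              scale = model@scale, classes = model@classes,
              history = model@history, seed = model@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSweepClassifier
#' @export
readSweepClassifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  W <- lapply(obj$weights, function(w) {
    data <- as.numeric(unlist(w$data))
    if (!is.null(w$dim) && length(w$dim) == 2)
      matrix(data, as.integer(w$dim[[1]]), as.integer(w$dim[[2]]))
    else data
  })
  cfg <- lapply(obj$config, function(x)
    if (is.list(x)) unlist(x) else x)
  cfg$kernel <- as.numeric(cfg$kernel)
  hist <- do.call(rbind, lapply(obj$history, as.data.frame))
  new("SweepClassifier", weights = W, config = cfg,
      center = as.numeric(unlist(obj$center)),
      scale = as.numeric(unlist(obj$scale)),
      classes = as.character(unlist(obj$classes)), history = hist,
      seed = as.numeric(obj$seed))
}
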