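## synthetic feature generators for classifier tests
separableFeatures <- function(nPer, seed, noise = 0.005) {
  set.seed(seed)
  classes <- sweepClasses()
  X <- NULL; y <- character(0)
  for (ci in seq_along(classes)) {
    shift <- matrix(0, nPer, 132)
    shift[, ((ci - 1) * 22 + 1):(ci * 22)] <- 0.05
    X <- rbind(X, matrix(1 / 11, nPer, 132) + shift +
                 matrix(rnorm(nPer * 132, sd = noise), nPer, 132))
    y <- c(y, rep(classes[ci], nPer))
  }
  list(x = X, y = y)
}

noiseFeatures <- function(n, seed) {
  set.seed(seed)
  list(x = matrix(rnorm(n * 132), n, 132),
       y = sample(sweepClasses(), n, replace = TRUE))
}

test_that("returned weights achieve the best logged validation loss", {
  d <- separableFeatures(30, seed = 41)
  m <- trainSweepClassifier(d$x, d$y, epochs = 30, seed = 42)
  h <- trainingHistory(m)
  expect_equal(h$val_loss[m@config$bestEpoch], min(h$val_loss))
  ## early stopping: no more than patience epochs after the best one
  ## improved on it
  expect_lte(nrow(h), m@config$bestEpoch + m@config$patience +
                      m@config$patience)
})

test_that("training is reproducible given a fixed seed", {
  d <- separableFeatures(20, seed = 43)
  m1 <- trainSweepClassifier(d$x, d$y, epochs = 10, seed = 44)
  m2 <- trainSweepClassifier(d$x, d$y, epochs = 10, seed = 44)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@weights, m2@weights)
})

test_that("label-shuffled training yields chance-level accuracy", {
  tr <- noiseFeatures(600, seed = 45)
  te <- noiseFeatures(500, seed = 46)
  m <- trainSweepClassifier(tr$x, tr$y, epochs = 15, seed = 47)
  post <- predictPosterior(m, te$x)
  acc <- mean(sweepClasses()[max.col(post, "first")] == te$y)
  se <- sqrt(0.2 * 0.8 / 500)
  expect_lt(acc, 0.2 + 3 * se)
  expect_gt(acc, 0.2 - 3 * se)
})

test_that("separable classes are learned nearly perfectly", {
  tr <- separableFeatures(60, seed = 48)
  te <- separableFeatures(30, seed = 49)
  m <- trainSweepClassifier(tr$x, tr$y, epochs = 60, seed = 50)
  post <- predictPosterior(m, te$x)
  pred <- sweepClasses()[max.col(post, "first")]
  expect_gt(mean(pred == te$y), 0.95)
  ## held-out hard examples are called a sweep type nearly always
  hardRows <- te$y == "hard"
  expect_gte(mean(pred[hardRows] %in% c("hard", "soft")), 0.9)
})

test_that("posteriors are valid probabilities and prediction is pure", {
  d <- separableFeatures(20, seed = 51)
  m <- trainSweepClassifier(d$x, d$y, epochs = 10, seed = 52)
  set.seed(53)
  X <- matrix(runif(100 * 132), 100, 132)
  p1 <- predictPosterior(m, X)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(unname(rowSums(p1)), rep(1, 100), tolerance = 1e-6)
  expect_identical(p1, predictPosterior(m, X))
  expect_error(predictPosterior(m, X[, 1:50]), "dimension")
})

test_that("classifier serialization round-trips exactly", {
  d <- separableFeatures(20, seed = 54)
  m <- trainSweepClassifier(d$x, d$y, epochs = 8, seed = 55)
  path <- withr::local_tempfile(fileext = ".json")
  saveSweepClassifier(m, path)
  m2 <- readSweepClassifier(path)
  X <- d$x[1:10, ]
  expect_equal(predictPosterior(m2, X), predictPosterior(m, X))
})

test_that("fewer than two classes is an error", {
  X <- matrix(runif(20 * 132), 20, 132)
  expect_error(trainSweepClassifier(X, rep("neutral", 20)), "two classes")
})

test_that("threshold-conditional confusion matrices conserve class sizes", {
  classes <- sweepClasses()
  post <- rbind(c(0.05, 0.05, 0.1, 0.5, 0.3),    # combined 0.8 -> assigned
                c(0.1, 0.1, 0.1, 0.4, 0.3),      # combined 0.7 -> omitted
                c(0.6, 0.1, 0.1, 0.1, 0.1))      # argmax neutral
  colnames(post) <- classes
  truths <- c("hard", "hard", "neutral")
  cm <- confusionAtThreshold(post, truths, 0.8)
  expect_equal(cm$counts["hard", "hard"], 1L)
  expect_equal(cm$omitted[["hard"]], 1L)
  expect_equal(cm$counts["neutral", "neutral"], 1L)
  ## no threshold: pure argmax, no omissions
  cm0 <- confusionAtThreshold(post, truths, NULL)
  expect_true(all(cm0$omitted == 0))
  ## conservation: assigned + omitted = class size, on random data
  set.seed(56)
  n <- 200
  rp <- matrix(runif(n * 5), n, 5); rp <- rp / rowSums(rp)
  colnames(rp) <- classes
  rt <- sample(classes, n, replace = TRUE)
  cmr <- confusionAtThreshold(rp, rt, 0.6)
  expect_equal(unname(rowSums(cmr$counts) + cmr$omitted),
               unname(as.integer(table(factor(rt, classes)))))
})

test_that("ROC/PR summaries match rank-statistic oracles", {
  classes <- sweepClasses()
  mk <- function(scorePos, scoreNeg) {
    n <- length(scorePos) + length(scoreNeg)
    post <- matrix(0, n, 5, dimnames = list(NULL, classes))
    post[, "hard"] <- c(scorePos, scoreNeg)
    post[, "neutral"] <- 1 - post[, "hard"]
    list(post = post,
         truth = c(rep("hard", length(scorePos)),
                   rep("neutral", length(scoreNeg))))
  }
  ## perfect separation
  d <- mk(c(0.9, 0.8, 0.95), c(0.1, 0.2, 0.3))
  cv <- binarySweepCurves(d$post, d$truth)
  expect_equal(cv$auc, 1)
  expect_equal(cv$averagePrecision, 1)

  ## random scores, large n: AUC near 0.5
  set.seed(57)
  d2 <- mk(runif(1000), runif(1000))
  cv2 <- binarySweepCurves(d2$post, d2$truth)
  seAuc <- sqrt((1000 + 1000 + 1) / (12 * 1000 * 1000))
  expect_lt(abs(cv2$auc - 0.5), 3 * seAuc)

  ## AUC equals Mann-Whitney U / (n+ n-) including ties
  set.seed(58)
  for (i in 1:10) {
    sp <- round(runif(12), 1); sn <- round(runif(15), 1)
    d3 <- mk(sp, sn)
    cv3 <- binarySweepCurves(d3$post, d3$truth)
    expect_equal(cv3$auc,
                 oracleAucMannWhitney(c(sp, sn),
                                      d3$truth == "hard"),
                 tolerance = 1e-12)
  }

  ## invariant under strictly monotone score transforms
  sp <- runif(20); sn <- runif(25)
  a1 <- binarySweepCurves(mk(sp, sn)$post, mk(sp, sn)$truth)$auc
  a2 <- binarySweepCurves(mk(plogis(5 * sp), plogis(5 * sn))$post,
                          mk(sp, sn)$truth)$auc
  expect_equal(a1, a2)
  expect_error(binarySweepCurves(mk(numeric(0), c(0.1))$post[0, , drop = FALSE],
                                 character(0)), "examples")
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(59)
  classes <- sweepClasses()
  post <- matrix(runif(300 * 5), 300, 5)
  post <- post / rowSums(post)
  colnames(post) <- classes
  truth <- sample(classes, 300, replace = TRUE)
  cv <- binarySweepCurves(post, truth)
  score <- post[, "hard"] + post[, "soft"]
  ref <- suppressMessages(
    pROC::auc(pROC::roc(truth %in% c("hard", "soft"), score, quiet = TRUE)))
  expect_equal(cv$auc, as.numeric(ref), tolerance = 1e-12)
})
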