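# Benign/malignant nucleus classification on the key-parameter vectors.
# SVM and KNN come from e1071/class; discrete AdaBoost over depth-1
# stumps is implemented here (no AdaBoost-family package in the stack).

.adaboostFit <- function(X, y, nRounds = 100) {
  # y in {-1, +1}
  n <- nrow(X); p <- ncol(X)
  w <- rep(1 / n, n)
  ords <- lapply(seq_len(p), function(j) order(X[, j]))
  stumps <- vector("list", nRounds)
  for (m in seq_len(nRounds)) {
    best <- list(err = Inf)
    for (j in seq_len(p)) {
      o <- ords[[j]]
      xv <- X[o, j]; yv <- y[o]; wv <- w[o]
      # stump sign(x > t): error as threshold moves between sorted points
      swPos <- cumsum(wv * (yv == 1))   # positives at or below i
      swNeg <- cumsum(wv * (yv == -1))
      totPos <- swPos[n]; totNeg <- swNeg[n]
      # predict +1 above threshold i: errors = positives below + negatives above
      errAbove <- swPos + (totNeg - swNeg)
      cand <- which(diff(xv) > 0)
      if (!length(cand)) next
      eA <- errAbove[cand]
      # polarity -1 (predict +1 below) has error 1 - errAbove
      iBest <- cand[which.min(pmin(eA, (totPos + totNeg) - eA))]
      thr <- (xv[iBest] + xv[iBest + 1]) / 2
      errA <- errAbove[iBest]
      pol <- if (errA <= (totPos + totNeg) - errA) 1 else -1
      err <- min(errA, (totPos + totNeg) - errA)
      if (err < best$err)
        best <- list(err = err, feature = j, threshold = thr,
                     polarity = pol)
    }
    if (!is.finite(best$err)) break
    err <- max(best$err, 1e-10)
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    pred <- best$polarity * ifelse(X[, best$feature] > best$threshold, 1, -1)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    best$alpha <- alpha
    stumps[[m]] <- best
    if (err <= 1e-9) break
  }
  stumps[!vapply(stumps, is.null, TRUE)]
}

.adaboostScore <- function(stumps, X) {
  s <- numeric(nrow(X))
  for (st in stumps)
    s <- s + st$alpha * st$polarity *
      ifelse(X[, st$feature] > st$threshold, 1, -1)
  s
}

.checkManifest <- function(table, manifest) {
  missing <- setdiff(manifest, names(table))
  if (length(missing))
    stop("schema error: feature table lacks columns: ",
         paste(missing, collapse = ", "))
}

.standardize <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, "/")
}

.fitAlgorithm <- function(algorithm, X, yf, seed, hyper) {
  switch(algorithm,
    svm = {
      g <- if (!is.null(hyper$gamma)) hyper$gamma else 1 / ncol(X)
      C <- if (!is.null(hyper$cost)) hyper$cost else 1
      .withSeed(seed, e1071::svm(X, yf, kernel = "radial", cost = C,
                                 gamma = g, scale = FALSE))
    },
    knn = list(X = X, y = yf,
               k = if (!is.null(hyper$k)) hyper$k else 5),
    adaboost = {
      y <- ifelse(yf == "malignant", 1, -1)
      nr <- if (!is.null(hyper$nRounds)) hyper$nRounds else 100
      .adaboostFit(X, y, nr)
    })
}

.scoreAlgorithm <- function(algorithm, fit, X) {
  switch(algorithm,
    svm = {
      pr <- stats::predict(fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")[, 1]
      # orient the decision value so larger means malignant
      if (grepl("^malignant", colnames(attr(pr, "decision.values"))[1]))
        dv else -dv
    },
    knn = {
      pr <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "malignant", p, 1 - p)
    },
    adaboost = .adaboostScore(fit, X))
}

.classFromScore <- function(algorithm, score) {
  thr <- if (algorithm == "adaboost") 0 else if (algorithm == "knn") 0.5 else 0
  ifelse(score > thr, "malignant", "benign")
}

#' Train a benign/malignant nucleus classifier
#'
#' Fits one of three algorithms on the manifest feature columns of a
#' feature table, z-scored with the training statistics: an RBF-kernel
#' SVM (`cost = 1`, `gamma = 1/p`), K-nearest neighbours (`k = 5`,
#' Euclidean on the z-scored features) or discrete AdaBoost over 100
#' depth-1 stumps. Training metrics (accuracy, TPR on the malignant
#' class, ROC AUC and seeded 5-fold cross-validated accuracy) are
#' stored in the model.
#'
#' @param table feature table covering the manifest columns.
#' @param labels per-row class labels (`"benign"`/`"malignant"`).
#' @param algorithm `"svm"`, `"knn"` or `"adaboost"`.
#' @param seed integer seed (CV folds and any algorithmic randomness).
#' @param manifest ordered feature names (default [keyParameterSet()]).
#' @param hyper named list of hyperparameter overrides
#'   (`cost`/`gamma` for svm, `k` for knn, `nRounds` for adaboost).
#' @param cvFolds folds of the cross-validated accuracy estimate
#'   (0 skips it).
#' @return a [ClassifierModel].
#' @export
trainClassifier <- function(table, labels,
                            algorithm = c("svm", "knn", "adaboost"),
                            seed = 0, manifest = keyParameterSet(),
                            hyper = list(), cvFolds = 5) {
  algorithm <- match.arg(algorithm)
  .checkManifest(table, manifest)
  yf <- factor(as.character(labels), levels = c("benign", "malignant"))
  if (anyNA(yf)) stop("labels must be benign or malignant")
  if (length(unique(yf)) < 2)
    stop("degenerate training: only one class present")
  X0 <- as.matrix(table[, manifest, drop = FALSE])
  center <- colMeans(X0)
  scl <- apply(X0, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  X <- .standardize(X0, center, scl)
  fit <- .fitAlgorithm(algorithm, X, yf, seed, hyper)
  score <- .scoreAlgorithm(algorithm, fit, X)
  cls <- .classFromScore(algorithm, score)
  acc <- mean(cls == as.character(yf))
  tpr <- mean(cls[yf == "malignant"] == "malignant")
  roc <- rocCurve(score, yf == "malignant")
  cvAcc <- NA_real_
  if (cvFolds > 1) {
    foldid <- .withSeed(seed + 1,
                        sample(rep(seq_len(cvFolds),
                                   length.out = nrow(X))))
    hits <- 0
    for (f in seq_len(cvFolds)) {
      tr <- foldid != f
      if (length(unique(yf[tr])) < 2) next
      ffit <- .fitAlgorithm(algorithm, X[tr, , drop = FALSE], yf[tr],
                            seed, hyper)
      sc <- .scoreAlgorithm(algorithm, ffit, X[!tr, , drop = FALSE])
      hits <- hits + sum(.classFromScore(algorithm, sc) ==
                           as.character(yf[!tr]))
    }
    cvAcc <- hits / nrow(X)
  }
  new("ClassifierModel", algorithm = algorithm, manifest = manifest,
      fit = fit, center = center, scale = scl, seed = as.integer(seed),
      metrics = list(accuracy = acc, tpr = tpr, auc = roc$auc,
                     cvAccuracy = cvAcc, roc = roc[c("fpr", "tpr")]))
}

#' Classify the nuclei of a feature table
#'
#' Applies a trained model to each row, returning the predicted class
#' and a monotone malignancy score (SVM decision value, KNN malignant
#' vote fraction, AdaBoost margin). Deterministic.
#'
#' @param model a [ClassifierModel].
#' @param table feature table covering the model's manifest.
#' @return data.frame with columns `class` and `score`; an empty table
#'   yields an empty prediction.
#' @export
predictNuclei <- function(model, table) {
  stopifnot(is(model, "ClassifierModel"))
  .checkManifest(table, model@manifest)
  if (nrow(table) == 0)
    return(data.frame(class = character(), score = numeric()))
  X <- .standardize(as.matrix(table[, model@manifest, drop = FALSE]),
                    model@center, model@scale)
  score <- .scoreAlgorithm(model@algorithm, model@fit, X)
  data.frame(class = .classFromScore(model@algorithm, score),
             score = score)
}

#' ROC curve and AUC
#'
#' Standard threshold sweep over the scores, with ties grouped; the AUC
#' is the trapezoidal integral of TPR over FPR, which equals the
#' pairwise concordance probability (ties counted half).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or coercible) positive-class indicators.
#' @return list with `fpr`, `tpr` (including the (0,0) and (1,1)
#'   endpoints) and `auc`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("undefined ROC: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- c(diff(s) != 0, TRUE)   # group tied scores
  tpr <- c(0, tp[last] / nPos)
  fpr <- c(0, fp[last] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}
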