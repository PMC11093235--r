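# CPAP-responder prediction: median-split labeling of annual delta-BAI,
# diagonal neighborhood component analysis (NCA) feature importance, the
# eight canonical feature sets, and a five-classifier battery evaluated with
# stratified 5-fold cross-validation.

#' Median-split responder labeling
#'
#' Good responders are subjects with annual delta-BAI at or below the cohort
#' median; poor responders lie above it. Ties at the cutoff are labeled good,
#' so a cohort where every value equals the median is labeled all good
#' (documented degenerate case). With an even number of distinct values this
#' yields exactly equal halves.
#'
#' @param annualDeltaBai numeric vector (n >= 2).
#' @return list of class `responder_labeling` with `cutoff` (the median) and
#'   `labels` (factor with levels `good`, `poor`).
#' @export
medianSplit <- function(annualDeltaBai) {
  stopifnot(length(annualDeltaBai) >= 2, !anyNA(annualDeltaBai))
  cutoff <- median(annualDeltaBai)
  labels <- factor(ifelse(annualDeltaBai <= cutoff, "good", "poor"),
                   levels = c("good", "poor"))
  structure(list(cutoff = cutoff, labels = labels), class = "responder_labeling")
}

#' @export
print.responder_labeling <- function(x, ...) {
  cat(sprintf("Responder labeling: cutoff %.3f y/y; good %d, poor %d\n",
              x$cutoff, sum(x$labels == "good"), sum(x$labels == "poor")))
  invisible(x)
}

#' Diagonal NCA feature weights
#'
#' Feature-selection variant of neighborhood component analysis: one
#' non-negative weight per feature, learned by maximizing the regularized
#' leave-one-out expected correct-classification probability under
#' softmax-distance neighbor assignment. Distances are
#' `d_ij = sum_k w_k^2 (x_ik - x_jk)^2`; the objective is
#' `mean_i p_i - lambda * sum_k w_k^2` with
#' `p_i = sum_{j != i, y_j = y_i} exp(-d_ij) / sum_{l != i} exp(-d_il)`.
#' Gradient ascent starts from `w = 1` with an adaptive step (accepted steps
#' never decrease the objective) and stops when the accepted objective change
#' falls below `tol` or after `maxIter` iterations. The optimization is
#' deterministic; `seed` is accepted for interface symmetry.
#'
#' @param X n x p matrix of standardized features (columns named).
#' @param y class labels (length n, two classes).
#' @param lambda regularization weight (default `1 / n`).
#' @param seed unused placeholder (deterministic algorithm).
#' @param maxIter,tol stopping controls.
#' @return list of class `nca_weights`: `w` (named non-negative weights),
#'   `lambda`, `objective` (accepted-step trace), `converged`.
#' @export
ncaFeatureWeights <- function(X, y, lambda = NULL, seed = 1L,
                              maxIter = 500, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 4, length(y) == n)
  sds <- apply(X, 2, sd)
  if (any(sds < .Machine$double.eps)) {
    stop(sprintf("constant feature: %s",
                 paste(colnames(X)[sds < .Machine$double.eps], collapse = ", ")))
  }
  lambda <- lambda %||% (1 / n)
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  sqD <- lapply(seq_len(p), function(k) outer(X[, k], X[, k], "-")^2)
  objGrad <- function(w) .ncaObjGrad(X, y, w, lambda, sqD = sqD, same = same)

  w <- rep(1, p)
  og <- objGrad(w)
  trace_ <- og$obj
  eta <- 0.1
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    stepped <- FALSE
    for (tries in 1:40) {
      wNew <- pmax(w + eta * og$grad, 0)
      ogNew <- objGrad(wNew)
      if (ogNew$obj >= og$obj - 1e-12) {
        delta <- ogNew$obj - og$obj
        w <- wNew; og <- ogNew
        trace_ <- c(trace_, og$obj)
        eta <- eta * 1.05
        stepped <- TRUE
        if (delta < tol) converged <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!stepped || converged) { converged <- TRUE; break }
  }
  names(w) <- colnames(X) %||% paste0("f", seq_len(p))
  structure(list(w = w, lambda = lambda, objective = trace_,
                 converged = converged), class = "nca_weights")
}

#' Rank features by NCA weight
#'
#' Descending by weight; ties broken by the canonical feature order (the
#' order of the columns passed to [ncaFeatureWeights()]).
#'
#' @param weights an `nca_weights` object (or a named numeric vector).
#' @return character vector of feature names, most important first.
#' @export
rankFeatures <- function(weights) {
  w <- if (inherits(weights, "nca_weights")) weights$w else weights
  names(w)[order(-w, seq_along(w))]
}

#' The eight canonical feature sets
#'
#' Built from an importance ranking over the 11 baseline features:
#' the full set, top 1/3/5 by rank, the EEG-derived pair (BAI and arousal
#' index), the non-EEG complement, everything except BAI, and BAI alone.
#'
#' @param ranking character vector from [rankFeatures()] covering the
#'   feature universe.
#' @return named list of 8 character vectors with sizes 11, 1, 3, 5, 2, 9,
#'   10, 1.
#' @export
buildFeatureSets <- function(ranking) {
  all_ <- if (setequal(ranking, FEATURES_CANONICAL)) FEATURES_CANONICAL else ranking
  eeg <- intersect(c("bai", "ai"), all_)
  list(all = all_,
       top1 = ranking[1],
       top3 = ranking[1:3],
       top5 = ranking[1:5],
       eeg = eeg,
       non_eeg = setdiff(all_, eeg),
       no_bai = setdiff(all_, "bai"),
       bai_only = intersect("bai", all_))
}

# Regularized leave-one-out NCA objective and its analytic gradient.
# Validated against central finite differences in the test suite.
.ncaObjGrad <- function(X, y, w, lambda, sqD = NULL, same = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(sqD)) sqD <- lapply(seq_len(p), function(k) outer(X[, k], X[, k], "-")^2)
  if (is.null(same)) { same <- outer(y, y, "=="); diag(same) <- FALSE }
  d <- Reduce(`+`, Map(function(S, wk) wk^2 * S, sqD, as.list(w)))
  Kmat <- exp(-d)
  diag(Kmat) <- 0
  S <- pmax(rowSums(Kmat), .Machine$double.xmin)
  P <- Kmat / S
  pi_ <- rowSums(P * same)
  grad <- vapply(seq_len(p), function(k) {
    inAll <- sum(pi_ * rowSums(P * sqD[[k]]))
    inSame <- sum((P * same) * sqD[[k]])
    (2 * w[k] / n) * (inAll - inSame) - 2 * lambda * w[k]
  }, numeric(1))
  list(obj = mean(pi_) - lambda * sum(w^2), grad = grad)
}

# One classifier fit + prediction. Returns labels and P(good) scores.
.fitPredict <- function(clf, Ztrain, yTrain, Ztest, seed) {
  Ztrain <- as.matrix(Ztrain); Ztest <- as.matrix(Ztest)
  withr::with_seed(seed, switch(clf,
    KNN = {
      k <- max(1, min(5, min(table(yTrain)) - 1))
      pr <- class::knn(Ztrain, Ztest, yTrain, k = k, prob = TRUE)
      pwin <- attr(pr, "prob")
      list(labels = pr, scores = ifelse(pr == "good", pwin, 1 - pwin))
    },
    NN = {
      m <- nnet::nnet(Ztrain, as.numeric(yTrain == "good"), size = 16,
                      decay = 0.5, maxit = 300, trace = FALSE)
      sc <- as.numeric(predict(m, Ztest))
      list(labels = factor(ifelse(sc >= 0.5, "good", "poor"),
                           levels = levels(yTrain)), scores = sc)
    },
    DT = {
      df <- data.frame(.y = yTrain, Ztrain)
      m <- rpart::rpart(.y ~ ., data = df, method = "class")
      pr <- predict(m, data.frame(Ztest), type = "prob")[, "good"]
      list(labels = factor(ifelse(pr >= 0.5, "good", "poor"),
                           levels = levels(yTrain)), scores = pr)
    },
    RF = {
      m <- randomForest::randomForest(Ztrain, yTrain, ntree = 200)
      pr <- predict(m, Ztest, type = "prob")[, "good"]
      list(labels = predict(m, Ztest), scores = pr)
    },
    SVM = {
      m <- e1071::svm(Ztrain, yTrain, kernel = "polynomial", degree = 3,
                      probability = TRUE, scale = FALSE)
      pred <- predict(m, Ztest, probability = TRUE)
      pr <- attr(pred, "probabilities")[, "good"]
      list(labels = pred, scores = pr)
    },
    stop(sprintf("unknown classifier '%s'", clf))))
}

#' Pooled confusion-matrix metrics
#'
#' Accuracy, rank-statistic AUC, sensitivity and specificity with the good
#' responder as the positive class.
#'
#' @param y true labels (factor, positive class `"good"`).
#' @param yhat predicted labels.
#' @param scores numeric scores for the positive class (used for AUC).
#' @param positive positive-class label.
#' @return list with `accuracy`, `auc`, `sensitivity`, `specificity`.
#' @export
confusionMetrics <- function(y, yhat, scores = NULL, positive = "good") {
  pos <- y == positive
  tp <- sum(yhat == positive & pos); fn <- sum(yhat != positive & pos)
  tn <- sum(yhat != positive & !pos); fp <- sum(yhat == positive & !pos)
  auc <- if (is.null(scores) || sum(pos) == 0 || sum(!pos) == 0) NA_real_ else {
    r <- rank(scores)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }
  list(accuracy = (tp + tn) / length(y), auc = auc,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Evaluate the classifier battery over the eight feature sets
#'
#' Stratified 5-fold cross-validation (80 percent training, 20 percent
#' testing per fold). Inside each fold, standardization parameters and the
#' NCA importance ranking are fitted on the training portion only (no
#' leakage); `paperFaithful = TRUE` instead uses a single NCA ranking fitted
#' once on all data. Metrics are computed on the pooled out-of-fold
#' predictions (per-fold metrics are attached as an attribute).
#'
#' @param X n x p feature matrix or data.frame (columns named with the 11
#'   canonical features).
#' @param y responder labels (factor or character, `good`/`poor`; both
#'   classes need >= 5 members).
#' @param seed integer seed driving fold assignment and stochastic fits.
#' @param classifiers subset of `c("KNN", "NN", "DT", "RF", "SVM")`.
#' @param featureSetNames subset of the eight canonical set names (default
#'   all).
#' @param nFolds number of folds (5).
#' @param paperFaithful use one global NCA ranking instead of per-fold
#'   rankings.
#' @param folds optional explicit fold assignment (integer vector in
#'   `1..nFolds`), overriding the stratified draw.
#' @return data.frame of class `evaluation_grid` with one row per
#'   classifier x feature set (`accuracy`, `auc`, `sensitivity`,
#'   `specificity`), with attributes `folds`, `seed`, `fold_artifacts`
#'   (per-fold scaler means and NCA weights) and `per_fold` metrics.
#' @export
evaluateGrid <- function(X, y, seed = 1L,
                         classifiers = c("KNN", "NN", "DT", "RF", "SVM"),
                         featureSetNames = c("all", "top1", "top3", "top5",
                                             "eeg", "non_eeg", "no_bai",
                                             "bai_only"),
                         nFolds = 5, paperFaithful = FALSE, folds = NULL) {
  X <- as.data.frame(X)
  y <- factor(as.character(y), levels = c("good", "poor"))
  stopifnot(nrow(X) == length(y))
  if (min(table(y)) < 5) stop("both classes need at least 5 members")

  if (is.null(folds)) {
    folds <- integer(length(y))
    withr::with_seed(.deriveSeed(seed, 11), {
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(seq_len(nFolds), length(idx))
      }
    })
  }

  globalRanking <- NULL
  if (paperFaithful) {
    Zall <- scale(as.matrix(X))
    globalRanking <- rankFeatures(ncaFeatureWeights(Zall, y))
  }

  cells <- expand.grid(classifier = classifiers, feature_set = featureSetNames,
                       stringsAsFactors = FALSE)
  pooledLab <- replicate(nrow(cells), factor(rep(NA, length(y)),
                                             levels = levels(y)),
                         simplify = FALSE)
  pooledSc <- replicate(nrow(cells), rep(NA_real_, length(y)), simplify = FALSE)
  artifacts <- list()

  for (f in seq_len(nFolds)) {
    test <- which(folds == f); train <- which(folds != f)
    mu <- colMeans(X[train, , drop = FALSE])
    sdv <- pmax(apply(X[train, , drop = FALSE], 2, sd), 1e-12)
    Ztrain <- scale(as.matrix(X[train, , drop = FALSE]), mu, sdv)
    Ztest <- scale(as.matrix(X[test, , drop = FALSE]), mu, sdv)
    ranking <- globalRanking %||% {
      # features constant within the training fold carry no information:
      # rank the rest, append the degenerate ones last in canonical order
      informative <- apply(X[train, , drop = FALSE], 2, sd) > .Machine$double.eps
      r <- rankFeatures(ncaFeatureWeights(Ztrain[, informative, drop = FALSE],
                                          y[train]))
      c(r, names(X)[!informative])
    }
    sets <- buildFeatureSets(ranking)
    artifacts[[f]] <- list(scaler_mu = mu, scaler_sd = sdv, ranking = ranking)
    for (ci in seq_len(nrow(cells))) {
      cols <- sets[[cells$feature_set[ci]]]
      fp <- .fitPredict(cells$classifier[ci],
                        Ztrain[, cols, drop = FALSE], y[train],
                        Ztest[, cols, drop = FALSE],
                        seed = .deriveSeed(seed, 100 * f + ci))
      pooledLab[[ci]][test] <- fp$labels
      pooledSc[[ci]][test] <- fp$scores
    }
  }

  perFold <- NULL
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    cm <- confusionMetrics(y, pooledLab[[ci]], pooledSc[[ci]])
    data.frame(classifier = cells$classifier[ci],
               feature_set = cells$feature_set[ci],
               accuracy = cm$accuracy, auc = cm$auc,
               sensitivity = cm$sensitivity, specificity = cm$specificity)
  })
  grid <- do.call(rbind, rows)
  perFold <- lapply(seq_len(nFolds), function(f) {
    test <- which(folds == f)
    do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
      cm <- confusionMetrics(y[test], pooledLab[[ci]][test], pooledSc[[ci]][test])
      data.frame(fold = f, classifier = cells$classifier[ci],
                 feature_set = cells$feature_set[ci], accuracy = cm$accuracy)
    }))
  })
  attr(grid, "folds") <- folds
  attr(grid, "seed") <- seed
  attr(grid, "fold_artifacts") <- artifacts
  attr(grid, "per_fold") <- do.call(rbind, perFold)
  class(grid) <- c("evaluation_grid", "data.frame")
  grid
}
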