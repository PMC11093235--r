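# Responder prediction: median split, NCA weights and gradient, feature
# sets, classifier grid, confusion metrics, leakage control.

test_that("median split halves the cohort with ties labeled good", {
  withr::with_seed(31, vals <- rnorm(98))
  lab <- medianSplit(vals)
  expect_equal(sum(lab$labels == "good"), 49)
  expect_equal(sum(lab$labels == "poor"), 49)
  expect_true(all(vals[lab$labels == "good"] <= lab$cutoff))

  s <- medianSplit(c(1, 2, 3))
  expect_equal(s$cutoff, 2)
  expect_identical(as.character(s$labels), c("good", "good", "poor"))

  tied <- medianSplit(rep(5, 8))
  expect_true(all(tied$labels == "good"))
})

test_that("NCA analytic gradient matches central finite differences", {
  numGrad <- function(X, y, w, lambda, eps = 1e-6) {
    objOf <- function(wv) {
      d <- matrix(0, nrow(X), nrow(X))
      for (k in seq_len(ncol(X))) d <- d + wv[k]^2 * outer(X[, k], X[, k], "-")^2
      K <- exp(-d); diag(K) <- 0
      P <- K / rowSums(K)
      same <- outer(y, y, "=="); diag(same) <- FALSE
      mean(rowSums(P * same)) - lambda * sum(wv^2)
    }
    vapply(seq_along(w), function(k) {
      wp <- w; wm <- w
      wp[k] <- w[k] + eps; wm[k] <- w[k] - eps
      (objOf(wp) - objOf(wm)) / (2 * eps)
    }, numeric(1))
  }
  withr::with_seed(32, {
    for (r in 1:5) {
      X <- scale(matrix(rnorm(20 * 5), 20, 5))
      colnames(X) <- paste0("f", 1:5)
      y <- rep(c("good", "poor"), 10)
      w <- runif(5, 0.3, 1.5)
      lambda <- 0.05
      grad <- somnage:::.ncaObjGrad(X, y, w, lambda)$grad
      num <- numGrad(X, y, w, lambda)
      expect_lt(max(abs(grad - num)) / max(abs(num)), 1e-4)
    }
  })
})

test_that("NCA weights promote the separating feature and obey lambda", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(400 + s, {
      y <- rep(c("good", "poor"), each = 15)
      X <- cbind(sep = rnorm(30, ifelse(y == "good", 1.2, -1.2), 0.6),
                 matrix(rnorm(30 * 4), 30, 4,
                        dimnames = list(NULL, paste0("n", 1:4))))
    })
    w <- ncaFeatureWeights(scale(X), y, lambda = 1 / 30)$w
    names(which.max(w)) == "sep"
  }, logical(1))
  expect_gt(mean(hits), 0.5)  # 20-seed majority

  withr::with_seed(33, {
    X <- scale(matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c"))))
    y <- rep(c("good", "poor"), 20)
  })
  wBig <- ncaFeatureWeights(X, y, lambda = 1000)$w
  expect_lt(max(wBig), 1e-2)
  # objective trace is nondecreasing over accepted steps
  fit <- ncaFeatureWeights(X, y, lambda = 0.05)
  expect_true(all(diff(fit$objective) >= -1e-12))
  expect_true(all(fit$w >= 0))
  # constant features are rejected up front
  Xc <- cbind(X, konst = rep(1, 40))
  expect_error(ncaFeatureWeights(Xc, y), "constant feature")
})

test_that("feature ranking sorts by weight with canonical tie-breaks", {
  w <- structure(list(w = c(a = 0.2, b = 0.9, c = 0.2), lambda = 1,
                      objective = 1, converged = TRUE), class = "nca_weights")
  expect_identical(rankFeatures(w), c("b", "a", "c"))
  expect_identical(rankFeatures(c(x = 1)), "x")
})

test_that("the eight feature sets have the documented composition", {
  ranking <- c("ai", "bai", "hb_total", "apnea_index", "ahi", "hb_apnea",
               "sex", "age", "odi", "hb_hypopnea", "hypopnea_index")
  sets <- buildFeatureSets(ranking)
  expect_named(sets, c("all", "top1", "top3", "top5", "eeg", "non_eeg",
                       "no_bai", "bai_only"))
  expect_equal(unname(lengths(sets)), c(11, 1, 3, 5, 2, 9, 10, 1))
  expect_setequal(sets$eeg, c("bai", "ai"))
  expect_false(any(c("bai", "ai") %in% sets$non_eeg))
  expect_false("bai" %in% sets$no_bai)
  expect_identical(sets$bai_only, "bai")
  expect_true(all(sets$top3 %in% sets$top5))
  expect_true(all(sets$top5 %in% sets$all))
})

test_that("confusion metrics match the published-orientation arithmetic", {
  y <- factor(rep(c("good", "poor"), c(49, 49)), levels = c("good", "poor"))
  yhat <- y
  yhat[1:5] <- "poor"   # 5 false negatives
  yhat[50:58] <- "good" # 9 false positives
  m <- confusionMetrics(y, yhat)
  expect_equal(m$sensitivity, 44 / 49, tolerance = 1e-9)  # 0.898
  expect_equal(m$specificity, 40 / 49, tolerance = 1e-9)  # 0.816
  expect_equal(m$accuracy, 84 / 98)
  perfect <- confusionMetrics(y, y, scores = as.numeric(y == "good"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  withr::with_seed(34, sc <- runif(98))
  expect_equal(confusionMetrics(y, yhat, sc)$auc,
               1 - confusionMetrics(y, yhat, -sc)$auc, tolerance = 1e-12)
})

test_that("the grid is deterministic and aces separable data", {
  withr::with_seed(35, {
    n <- 40
    y <- rep(c("good", "poor"), each = n / 2)
    X <- as.data.frame(matrix(rnorm(n * 11), n, 11) +
                         ifelse(y == "good", 3, -3))  # separable in every feature
    names(X) <- somnage:::FEATURES_CANONICAL
  })
  g1 <- evaluateGrid(X, y, seed = 9, classifiers = c("SVM", "RF"),
                     featureSetNames = c("all", "bai_only"))
  expect_s3_class(g1, "evaluation_grid")
  expect_true(all(g1$accuracy[g1$feature_set == "all"] == 1))
  expect_true(all(g1$accuracy >= 0 & g1$accuracy <= 1))
  g2 <- evaluateGrid(X, y, seed = 9, classifiers = c("SVM", "RF"),
                     featureSetNames = c("all", "bai_only"))
  expect_identical(as.data.frame(g1), as.data.frame(g2))
})

test_that("randomized labels hover at chance accuracy", {
  accs <- vapply(1:30, function(r) {
    withr::with_seed(500 + r, {
      n <- 40
      X <- as.data.frame(matrix(rnorm(n * 11), n, 11))
      names(X) <- somnage:::FEATURES_CANONICAL
      y <- sample(rep(c("good", "poor"), each = n / 2))
    })
    g <- evaluateGrid(X, y, seed = r, classifiers = "DT",
                      featureSetNames = "top3")
    g$accuracy[1]
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("test-fold labels cannot influence training artifacts", {
  withr::with_seed(36, {
    n <- 50
    X <- as.data.frame(matrix(rnorm(n * 11), n, 11))
    names(X) <- somnage:::FEATURES_CANONICAL
    y <- factor(rep(c("good", "poor"), each = 25), levels = c("good", "poor"))
  })
  folds <- rep_len(1:5, n)
  g1 <- evaluateGrid(X, y, seed = 4, classifiers = "DT",
                     featureSetNames = "top1", folds = folds)
  # permute the labels inside each test fold, keep training labels intact:
  # per-fold scalers and NCA rankings must be byte-identical
  for (f in 1:5) {
    yPerm <- y
    idx <- which(folds == f)
    yPerm[idx] <- withr::with_seed(600 + f, sample(y[idx]))
    gP <- evaluateGrid(X, yPerm, seed = 4, classifiers = "DT",
                       featureSetNames = "top1", folds = folds)
    a1 <- attr(g1, "fold_artifacts")[[f]]
    a2 <- attr(gP, "fold_artifacts")[[f]]
    expect_identical(a1$scaler_mu, a2$scaler_mu)
    expect_identical(a1$scaler_sd, a2$scaler_sd)
    expect_identical(a1$ranking, a2$ranking)
  }
})

test_that("severity-coupled responders are learnable above the null", {
  co <- generateCohort(cohortConfig("smc_treated", nSubjects = 98, seed = 37))
  co$bai <- co$bai_true_baseline
  adb <- oracleAnnualDeltaBAI(co, modelSeed = 11, sigma = 0.3)
  lab <- medianSplit(adb)
  X <- co[, somnage:::FEATURES_CANONICAL]
  g <- evaluateGrid(X, lab$labels, seed = 5, classifiers = c("SVM", "RF"))
  best <- max(g$accuracy)
  # top-5 NCA features on the full data include >= 3 severity features
  wAll <- ncaFeatureWeights(scale(as.matrix(X)), lab$labels)
  top5 <- rankFeatures(wAll)[1:5]
  severity <- c("ahi", "ai", "odi", "apnea_index", "hypopnea_index",
                "hb_total", "hb_apnea", "hb_hypopnea", "bai")
  expect_gte(sum(top5 %in% severity), 3)
  # permutation null for the best cell
  nullAcc <- vapply(1:30, function(r) {
    yN <- withr::with_seed(700 + r, sample(lab$labels))
    gN <- evaluateGrid(X, yN, seed = 5, classifiers = "SVM",
                       featureSetNames = "top5")
    gN$accuracy[1]
  }, numeric(1))
  expect_gt(best, quantile(nullAcc, 0.95))
})
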