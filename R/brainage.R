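# Brain-age regressor contract and BAI arithmetic.
#
# Three interchangeable model kinds share the fit/predict contract:
#   ridge  - ridge regression (glmnet, alpha = 0) on band-power summary
#            features; the fast, deterministic default.
#   mlp    - single-hidden-layer perceptron (nnet) on the same features.
#   oracle - returns the generator's ground-truth brain age plus seeded
#            Gaussian noise; requires ground-truth metadata on the input and
#            exists for pipeline validation only.

# Band-power summary features from a ModelInput: mean log10 power per
# (band, channel) over time bins (96 features) plus the five stage fractions.
.bandpowerFeatures <- function(input) {
  tensor <- input@tensor
  bp <- apply(tensor[, , 1:6], c(2, 3), mean)
  stage <- tensor[, 1, 7]
  fracs <- vapply(STAGE_CODES, function(v) mean(abs(stage - v) < 1e-9), numeric(1))
  c(as.vector(bp), fracs)
}

.featureMatrix <- function(inputs) {
  t(vapply(inputs, .bandpowerFeatures, numeric(101)))
}

#' Fit a brain-age regressor
#'
#' Trains the requested model kind on a list of model inputs with known
#' chronological ages. An internal 80/20 split (seeded) provides the
#' reported train/validation MAE. Fitting is deterministic under `seed`.
#'
#' @param modelConfig list with `kind` (`"ridge"`, `"mlp"`, or `"oracle"`)
#'   and kind-specific hyperparameters: `lambda` (ridge penalty; `NULL` for
#'   internal cross-validation), `hidden` and `decay` (mlp), `sigma`
#'   (oracle prediction noise SD in years, default 0.5).
#' @param inputs list of [ModelInput-class] objects (>= 20 for trainable
#'   kinds).
#' @param ages numeric vector of chronological ages (years), one per input.
#' @param seed integer training seed.
#' @return a trained [BrainAgeModel-class].
#' @export
fitBrainAge <- function(modelConfig = list(kind = "ridge"), inputs = NULL,
                        ages = NULL, seed = 1L) {
  kind <- modelConfig$kind %||% "ridge"
  if (kind == "oracle") {
    return(new("BrainAgeModel", kind = "oracle",
               fit = list(sigma = modelConfig$sigma %||% 0.5),
               config = modelConfig, seed = as.numeric(seed), trained = TRUE))
  }
  stopifnot(is.list(inputs), length(inputs) == length(ages))
  if (length(inputs) < 20) stop("need at least 20 training subjects")
  if (diff(range(ages)) < 5) stop("degenerate age range: span must be >= 5 years")

  X <- .featureMatrix(inputs)
  y <- as.numeric(ages)
  fit <- withr::with_seed(seed, {
    nVal <- max(2, round(0.2 * length(y)))
    valIdx <- sample.int(length(y), nVal)
    if (kind == "ridge") {
      lambda <- modelConfig$lambda
      if (is.null(lambda)) {
        cv <- glmnet::cv.glmnet(X[-valIdx, , drop = FALSE], y[-valIdx],
                                alpha = 0, nfolds = 5)
        lambda <- cv$lambda.min
      }
      m <- glmnet::glmnet(X[-valIdx, , drop = FALSE], y[-valIdx], alpha = 0,
                          lambda = lambda)
      predFun <- function(model, newX) as.numeric(predict(model, newX))
      final <- glmnet::glmnet(X, y, alpha = 0, lambda = lambda)
    } else if (kind == "mlp") {
      scaleFit <- list(mu = colMeans(X), sd = pmax(apply(X, 2, sd), 1e-12))
      Z <- scale(X, scaleFit$mu, scaleFit$sd)
      m <- nnet::nnet(Z[-valIdx, , drop = FALSE], y[-valIdx],
                      size = modelConfig$hidden %||% 16,
                      decay = modelConfig$decay %||% 0.1,
                      linout = TRUE, maxit = 500, trace = FALSE)
      predFun <- function(model, newX) as.numeric(predict(model, newX))
      final <- nnet::nnet(Z, y, size = modelConfig$hidden %||% 16,
                          decay = modelConfig$decay %||% 0.1,
                          linout = TRUE, maxit = 500, trace = FALSE)
      attr(final, "scale") <- scaleFit
    } else {
      stop(sprintf("unknown model kind '%s'", kind))
    }
    trainPred <- if (kind == "mlp") {
      predFun(m, scale(X, scaleFit$mu, scaleFit$sd)[-valIdx, , drop = FALSE])
    } else predFun(m, X[-valIdx, , drop = FALSE])
    valPred <- if (kind == "mlp") {
      predFun(m, scale(X, scaleFit$mu, scaleFit$sd)[valIdx, , drop = FALSE])
    } else predFun(m, X[valIdx, , drop = FALSE])
    list(model = final,
         train_mae = mean(abs(trainPred - y[-valIdx])),
         val_mae = mean(abs(valPred - y[valIdx])))
  })
  new("BrainAgeModel", kind = kind, fit = fit, config = modelConfig,
      seed = as.numeric(seed), trained = TRUE)
}

#' Predict brain age for one model input
#'
#' Deterministic for a fitted model; the result is clamped to `[0, 120]`
#' years. The oracle kind reads `meta$true_brain_age` from the input and
#' adds Gaussian noise whose seed derives from the model seed and the
#' subject/visit identity, so repeated calls agree.
#'
#' @param model a trained [BrainAgeModel-class].
#' @param input a [ModelInput-class].
#' @return predicted brain age in years (finite scalar).
#' @export
predictAge <- function(model, input) {
  stopifnot(is(model, "BrainAgeModel"), model@trained)
  if (model@kind == "oracle") {
    truth <- input@meta$true_brain_age
    if (is.null(truth)) {
      stop("oracle model requires ground-truth metadata ('true_brain_age') on the input")
    }
    key <- paste(input@meta$subject_id %||% "x", input@meta$visit %||% "v", sep = "|")
    noise <- withr::with_seed(.deriveSeed(model@seed, .hashString(key)),
                              rnorm(1, 0, model@fit$sigma))
    return(.clamp(truth + noise, 0, 120))
  }
  x <- matrix(.bandpowerFeatures(input), nrow = 1)
  pred <- if (model@kind == "mlp") {
    sc <- attr(model@fit$model, "scale")
    as.numeric(predict(model@fit$model, scale(x, sc$mu, sc$sd)))
  } else {
    as.numeric(predict(model@fit$model, x))
  }
  .clamp(pred, 0, 120)
}

#' Brain age index
#'
#' `BAI = predicted brain age - chronological age`: a positive value means
#' the sleep EEG looks older than the subject.
#'
#' @param predicted predicted brain age, years.
#' @param chron chronological age, years.
#' @return BAI in years.
#' @examples
#' computeBAI(54.1, 50)  # 4.1
#' @export
computeBAI <- function(predicted, chron) {
  predicted - chron
}

#' Annualized change in BAI
#'
#' `(BAI_followup - BAI_baseline) / interval`. Negative values mean brain
#' aging decelerated over the interval.
#'
#' @param baiBase baseline BAI, years.
#' @param baiFu follow-up BAI, years.
#' @param intervalYears interval between assessments, years (> 0); a warning
#'   is logged below 1 year (the design enrolls >= 12-month follow-ups).
#' @return annual change in BAI, years per year.
#' @export
annualDeltaBAI <- function(baiBase, baiFu, intervalYears) {
  if (any(intervalYears <= 0)) stop("interval must be positive")
  if (any(intervalYears < 1)) {
    warning("interval below 1 year: the longitudinal design assumes >= 12-month follow-up")
  }
  (baiFu - baiBase) / intervalYears
}
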