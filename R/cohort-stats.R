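# Longitudinal cohort statistics: paired tests on BAI, covariate-adjusted
# group comparison of (annual) delta-BAI, and FDR-controlled univariable
# association scans against baseline characteristics.

#' Paired t-test on before/after measurements
#'
#' Classical paired t on the within-subject differences (`after - before`),
#' two-sided.
#'
#' @param before,after numeric vectors of equal length (n >= 3, no missing).
#' @return list with `mean_diff`, `t`, `p`, `n`.
#' @export
pairedTTest <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 3,
            !anyNA(before), !anyNA(after))
  d <- after - before
  if (sd(d) == 0) {
    # degenerate: identical differences everywhere
    return(list(mean_diff = mean(d), t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0, n = length(before)))
  }
  tt <- t.test(after, before, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       p = tt$p.value, n = length(before))
}

#' Covariate-adjusted group comparison
#'
#' Ordinary least squares of the outcome on a treated-vs-untreated indicator
#' plus covariates; reports the group coefficient (treated minus untreated),
#' its t statistic and two-sided p value. With no covariates this reduces to
#' the two-sample (pooled-variance) t-test.
#'
#' @param table feature table with a `group` column (`treated`/`untreated`)
#'   and the outcome/covariate columns.
#' @param outcome outcome column name (`"delta_bai"` or
#'   `"annual_delta_bai"`).
#' @param covariates character vector of covariate column names (default:
#'   sex, age, BMI, AHI, arousal index).
#' @return list with `group_coef`, `t`, `p`, `n`.
#' @export
adjustedGroupComparison <- function(table, outcome = "annual_delta_bai",
                                    covariates = c("sex", "age", "bmi",
                                                   "ahi", "ai")) {
  stopifnot(outcome %in% names(table))
  if (length(unique(table$group)) < 2) stop("both groups must be present")
  missingCov <- setdiff(covariates, names(table))
  if (length(missingCov) > 0) {
    stop(sprintf("covariate(s) not in table: %s", paste(missingCov, collapse = ", ")))
  }
  df <- table
  df$.group <- as.integer(df$group == "treated")
  rhs <- paste(c(".group", covariates), collapse = " + ")
  X <- model.matrix(stats::as.formula(paste("~", rhs)), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("collinear design: column(s) %s", paste(dropped, collapse = ", ")))
  }
  fit <- lm(stats::as.formula(paste(outcome, "~", rhs)), data = df)
  sm <- summary(fit)$coefficients
  list(group_coef = sm[".group", "Estimate"], t = sm[".group", "t value"],
       p = sm[".group", "Pr(>|t|)"], n = nrow(df))
}

#' Univariable association scan with FDR control
#'
#' One univariable linear model of the outcome per baseline feature; t and p
#' per feature, with Benjamini-Hochberg q-values across the scanned set.
#'
#' @param table feature table.
#' @param outcome outcome column (default `annual_delta_bai`).
#' @param features character vector of feature columns to scan (default: the
#'   11 baseline prediction features plus ESS).
#' @return data.frame of class `association_scan`: `feature, t, p, q, n`,
#'   ordered as scanned.
#' @export
associationScan <- function(table, outcome = "annual_delta_bai",
                            features = c(FEATURES_CANONICAL, "ess")) {
  features <- setdiff(features, outcome)
  missingF <- setdiff(features, names(table))
  if (length(missingF) > 0) {
    stop(sprintf("feature(s) not in table: %s", paste(missingF, collapse = ", ")))
  }
  res <- do.call(rbind, lapply(features, function(f) {
    fit <- lm(stats::reformulate(f, outcome), data = table)
    sm <- summary(fit)$coefficients
    if (!f %in% rownames(sm)) {
      # constant / aliased feature: no estimable slope
      return(data.frame(feature = f, t = NA_real_, p = NA_real_,
                        n = nrow(table)))
    }
    data.frame(feature = f, t = sm[f, "t value"], p = sm[f, "Pr(>|t|)"],
               n = nrow(table))
  }))
  res$q <- fdrBH(res$p)
  res <- res[, c("feature", "t", "p", "q", "n")]
  class(res) <- c("association_scan", "data.frame")
  res
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param p vector of p-values.
#' @return q-values, same order as `p`.
#' @export
fdrBH <- function(p) {
  p.adjust(p, method = "BH")
}
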