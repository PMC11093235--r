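# Cohort-level benchmark computations: the quantities the package is
# validated on, recomputed from scratch from the generator through the
# estimation pipeline.

# Minimal model input carrying ground-truth metadata for the oracle kind.
.oracleInput <- function(subject, visit) {
  tensor <- array(0, dim = c(2000, 16, 7))
  tensor[, , 7] <- 0.5
  new("ModelInput", tensor = tensor, bandCentersHz = defaultBandCenters(),
      meta = list(true_brain_age = trueBrainAge(subject, visit),
                  subject_id = subject$subject_id, visit = visit))
}

#' Replicated cohort-level annual delta-BAI estimate
#'
#' Simulates `replicates` cohorts from a preset, estimates every subject's
#' BAI at baseline and follow-up with the oracle brain-age model (ground
#' truth plus `sigma` years of prediction noise), forms per-subject annual
#' delta-BAI, and averages the per-cohort means. This is the package's
#' parameter-recovery benchmark: with the `smc_treated` preset the result
#' converges on -0.6 BAI-years/year, with `smc_untreated` on +0.3.
#'
#' @param preset cohort preset name for [cohortConfig()].
#' @param nSubjects subjects per replicate (98 treated / 88 untreated in the
#'   reference configuration).
#' @param replicates number of seeded replicates (default 20).
#' @param seed master seed.
#' @param sigma oracle prediction noise SD, years.
#' @return list with `mean` (grand mean annual delta-BAI), `se` (standard
#'   error over replicates), `per_replicate` means, `n`.
#' @export
cohortDriftBenchmark <- function(preset, nSubjects, replicates = 20, seed = 1L,
                                 sigma = 0.5) {
  perRep <- vapply(seq_len(replicates), function(r) {
    co <- generateCohort(cohortConfig(preset, nSubjects = nSubjects,
                                      seed = .deriveSeed(seed, r)))
    model <- fitBrainAge(list(kind = "oracle", sigma = sigma),
                         seed = .deriveSeed(seed, 1000 + r))
    adb <- vapply(seq_len(nrow(co)), function(i) {
      sub <- co[i, ]
      baiB <- computeBAI(predictAge(model, .oracleInput(sub, "baseline")),
                         sub$age)
      baiF <- computeBAI(predictAge(model, .oracleInput(sub, "followup")),
                         sub$age + sub$interval_years)
      annualDeltaBAI(baiB, baiF, sub$interval_years)
    }, numeric(1))
    mean(adb)
  }, numeric(1))
  list(mean = mean(perRep), se = sd(perRep) / sqrt(replicates),
       per_replicate = perRep, n = nSubjects)
}

#' Held-out MAE of the trainable brain-age regressor
#'
#' Generates a model-development cohort (ages uniform over 20-80), runs
#' every subject's baseline night through the full preprocessing and
#' scalogram chain, trains the requested regressor kind on 80 percent of
#' subjects and reports the mean absolute error on the held-out 20 percent.
#'
#' @param nSubjects cohort size (default 200: 160 train / 40 test).
#' @param seed master seed.
#' @param kind trainable model kind (`"ridge"` default).
#' @param tstMin sleep duration per simulated night, minutes. Short nights
#'   keep the benchmark desk-scale; the spectral age signal is unaffected.
#' @return list with `mae` (held-out years), `train_mae`, `n`, `n_test`.
#' @export
brainAgeMAEBenchmark <- function(nSubjects = 200, seed = 1L, kind = "ridge",
                                 tstMin = 10) {
  co <- generateCohort(cohortConfig("model_dev", nSubjects = nSubjects,
                                    seed = .deriveSeed(seed, 77)))
  inputs <- lapply(seq_len(nSubjects), function(i) {
    rec <- generatePSG(co[i, ], "baseline", seed = .deriveSeed(seed, 2000 + i),
                       tstMin = tstMin, latencyEpochs = 2)
    pp <- preprocessPSG(rec)
    buildModelInput(pp$eeg, pp$hypnogram, fs = rec@fsEEG, meta = psgMeta(rec))
  })
  nTest <- max(1, round(0.2 * nSubjects))
  testIdx <- withr::with_seed(.deriveSeed(seed, 78),
                              sample.int(nSubjects, nTest))
  model <- fitBrainAge(list(kind = kind), inputs[-testIdx], co$age[-testIdx],
                       seed = .deriveSeed(seed, 79))
  pred <- vapply(inputs[testIdx], function(x) predictAge(model, x), numeric(1))
  list(mae = mean(abs(pred - co$age[testIdx])),
       train_mae = model@fit$train_mae, n = nSubjects, n_test = nTest)
}
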