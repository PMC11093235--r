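# Shared fixtures, all generated in code at test time.

# One-row subject data.frame without running the full cohort generator.
quickSubject <- function(subject_id = "S001", age = 50, bai = 2, drift = -0.5,
                         interval = 3, ahi = 30, ai = 25) {
  data.frame(subject_id = subject_id, group = "treated", age = age, sex = 1,
             bmi = 26, ess = 10, interval_years = interval,
             bai_true_baseline = bai, annual_drift = drift, ahi = ahi,
             ai = ai, odi = 0.75 * ahi, apnea_index = 0.6 * ahi,
             hypopnea_index = 0.4 * ahi, hb_total = 60, hb_apnea = 40,
             hb_hypopnea = 20, adherence_pct_days_4h = 80,
             adherence_mean_hours = 6, tst_min = 10,
             latent_severity = 0, stringsAsFactors = FALSE)
}

# Minimal valid ModelInput carrying oracle ground truth.
makeOracleInput <- function(subject, visit = "baseline") {
  tensor <- array(0, dim = c(2000, 16, 7))
  tensor[, , 7] <- 0.5
  new("ModelInput", tensor = tensor, bandCentersHz = defaultBandCenters(),
      meta = list(true_brain_age = trueBrainAge(subject, visit),
                  subject_id = subject$subject_id, visit = visit))
}

# Synthetic ModelInput whose band-power features encode age linearly, for
# fast regressor-contract tests that skip the signal chain.
makeFakeInput <- function(age, seed, noiseSd = 0.05) {
  withr::with_seed(seed, {
    tensor <- array(0, dim = c(2000, 16, 7))
    slopes <- seq(-0.02, 0.02, length.out = 16)
    for (ch in 1:6) {
      base <- matrix(rnorm(2000 * 16, 0, noiseSd), 2000, 16)
      tensor[, , ch] <- base + matrix(slopes * (age - 50), 2000, 16, byrow = TRUE)
    }
    tensor[, , 7] <- 0.5
    new("ModelInput", tensor = tensor, bandCentersHz = defaultBandCenters(),
        meta = list(chron_age = age))
  })
}

# Small PSG night for end-to-end fixtures (about 0.2 s to build).
smallPSG <- function(seed = 7, visit = "baseline", tstMin = 6,
                     artifactRate = 0, subject = NULL) {
  sub <- subject %||% generateCohort(cohortConfig("custom", nSubjects = 1,
                                                  seed = seed))[1, ]
  generatePSG(sub, visit = visit, seed = seed, tstMin = tstMin,
              latencyEpochs = 2, artifactRate = artifactRate)
}

`%||%` <- somnage:::`%||%`

# Annual delta-BAI of every subject in a cohort through the oracle model,
# exercising the BAI arithmetic end to end without signal processing.
oracleAnnualDeltaBAI <- function(cohort, modelSeed, sigma = 0.5) {
  m <- fitBrainAge(list(kind = "oracle", sigma = sigma), seed = modelSeed)
  vapply(seq_len(nrow(cohort)), function(i) {
    sub <- cohort[i, ]
    baiB <- computeBAI(predictAge(m, makeOracleInput(sub, "baseline")), sub$age)
    baiF <- computeBAI(predictAge(m, makeOracleInput(sub, "followup")),
                       sub$age + sub$interval_years)
    annualDeltaBAI(baiB, baiF, sub$interval_years)
  }, numeric(1))
}
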