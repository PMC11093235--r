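# Cohort/night generator: determinism, preset calibration, severity
# couplings, the age signal in the EEG spectra, and planted-event accounting.

test_that("cohort generation is deterministic and matches preset moments", {
  cfg <- cohortConfig("smc_treated", seed = 101,
                      slopes = list(severity = 0, bai = 0, age = 0, residual = 1))
  co1 <- generateCohort(cfg)
  co2 <- generateCohort(cfg)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 98)
  # mean drift within 3 SE of the configured -0.6 y/y
  se <- 2.7 / sqrt(98)
  expect_lt(abs(mean(co1$annual_drift) - (-0.6)), 3 * se)
  expect_lt(abs(mean(co1$age) - 53.3), 3 * 9.5 / sqrt(98))
  # severity couplings: AHI correlates with AI, ODI, HB
  expect_gt(cor(co1$ahi, co1$odi), 0.5)
  expect_gt(cor(co1$ahi, co1$hb_total), 0.5)
  expect_true(all(co1$ahi >= 5))
  expect_equal(co1$apnea_index + co1$hypopnea_index, co1$ahi)
  expect_equal(co1$hb_apnea + co1$hb_hypopnea, co1$hb_total)
})

test_that("degenerate drift config gives exactly the mean", {
  cfg <- cohortConfig("smc_treated", nSubjects = 12, seed = 5, drift_sd = 0,
                      slopes = list(severity = 0, bai = 0, age = 0, residual = 0))
  co <- generateCohort(cfg)
  expect_true(all(co$annual_drift == -0.6))
})

test_that("effect modification couples drift to severity with preset signs", {
  coU <- generateCohort(cohortConfig("smc_untreated", nSubjects = 400, seed = 9))
  expect_gt(cor(coU$annual_drift, coU$latent_severity), 0.2)
  expect_gt(cor(coU$annual_drift, coU$bai_true_baseline), 0.15)
  coT <- generateCohort(cohortConfig("smc_treated", nSubjects = 400, seed = 9))
  expect_lt(cor(coT$annual_drift, coT$latent_severity), -0.2)
  expect_lt(cor(coT$annual_drift, coT$bai_true_baseline), -0.2)
  # centered modifiers leave the mean at the preset value
  expect_lt(abs(mean(coU$annual_drift) - 0.3), 3 * 2.6 / sqrt(400))
})

test_that("hypnograms are deterministic with plausible stage structure", {
  sub <- quickSubject(ahi = 0)
  h1 <- generateHypnogram(sub, tstMin = 30, seed = 4, latencyEpochs = 3)
  h2 <- generateHypnogram(sub, tstMin = 30, seed = 4, latencyEpochs = 3)
  expect_identical(stages(h1), stages(h2))
  expect_equal(nEpochs(h1), 60 + 3)
  expect_equal(totalSleepTime(h1) * 60, 30)
  # at zero severity N1 stays below N2 (50-seed aggregate)
  fr <- rowMeans(vapply(1:50, function(s) {
    st <- stages(generateHypnogram(sub, tstMin = 20, seed = s))
    c(mean(st == "N1"), mean(st == "N2"))
  }, numeric(2)))
  expect_lt(fr[1], fr[2])
})

test_that("EEG slow/delta log-power declines with true brain age", {
  youngSub <- quickSubject(subject_id = "young", age = 40, bai = 0)
  oldSub <- quickSubject(subject_id = "old", age = 60, bai = 0)
  hyp <- Hypnogram(rep("N2", 4))
  deltaPower <- function(sub, s) {
    eeg <- generateEEG(sub, hyp, seed = s)
    ch <- rereference(eeg)["C3", ]
    sp <- spec.pgram(ch, taper = 0, plot = FALSE, detrend = TRUE)
    f <- sp$freq * 200
    mean(log10(sp$spec[f >= 0.5 & f <= 4]))
  }
  dy <- vapply(1:50, function(s) deltaPower(youngSub, s), numeric(1))
  do <- vapply(1:50, function(s) deltaPower(oldSub, s + 500), numeric(1))
  expect_lt(mean(do), mean(dy))
  # determinism
  e1 <- generateEEG(youngSub, hyp, seed = 11)
  e2 <- generateEEG(youngSub, hyp, seed = 11)
  expect_identical(e1, e2)
})

test_that("slope zero decouples delta power from age", {
  hyp <- Hypnogram(rep("N2", 4))
  ages <- seq(25, 75, length.out = 60)
  dp <- vapply(seq_along(ages), function(i) {
    sub <- quickSubject(subject_id = sprintf("s%03d", i), age = ages[i], bai = 0)
    eeg <- generateEEG(sub, hyp, seed = i, ageSlope = 0, subjectSd = 0)
    ch <- rereference(eeg)["C3", ]
    sp <- spec.pgram(ch, taper = 0, plot = FALSE, detrend = TRUE)
    f <- sp$freq * 200
    mean(log10(sp$spec[f >= 0.5 & f <= 4]))
  }, numeric(1))
  tval <- summary(lm(dp ~ ages))$coefficients["ages", "t value"]
  expect_lt(abs(tval), 2)
})

test_that("respiration plants the configured events with coupled SpO2", {
  sub <- quickSubject(ahi = 42, ai = 35)
  hyp <- generateHypnogram(sub, tstMin = 20, seed = 3, latencyEpochs = 2)
  r1 <- generateRespiration(sub, hyp, seed = 8)
  r2 <- generateRespiration(sub, hyp, seed = 8)
  expect_identical(r1$airflow_thermal, r2$airflow_thermal)
  expect_identical(r1$spo2, r2$spo2)
  ev <- eventTable(r1$events)
  # event count per hour matches the subject's AHI within rounding
  expect_lt(abs(nrow(ev) / totalSleepTime(hyp) - sub$ahi), 3.1)
  expect_true(all(ev$end_s - ev$start_s >= 10))
  # every hypopnea carries desaturation or arousal evidence
  hyp_ev <- ev[ev$type == "hypopnea", ]
  expect_true(all(hyp_ev$desat_matched | hyp_ev$arousal_matched))
  # artifact-free nights never dip below the 60 percent floor
  r0 <- generateRespiration(sub, hyp, seed = 12, artifactRate = 0)
  expect_gte(min(r0$spo2), 60)
})

test_that("generated PSG records are valid and carry ground truth", {
  co <- generateCohort(cohortConfig("smc_treated", nSubjects = 2, seed = 31))
  rec <- generatePSG(co[1, ], "followup", seed = 9, tstMin = 8,
                     latencyEpochs = 2)
  expect_s4_class(rec, "PSGRecord")
  expect_true(validObject(rec))
  expect_identical(rec@visit, "followup")
  m <- psgMeta(rec)
  expect_equal(m$true_brain_age, trueBrainAge(co[1, ], "followup"))
  # scoring the ground-truth events reproduces the planted AHI within 1/h
  idx <- computeIndices(respiratoryEvents(rec), arousalIntervals(rec),
                        cleanSpo2(spo2Trace(rec))$spo2, hypnogram(rec))
  expect_lt(abs(idx$ahi - m$planted_ahi), 1)
  # same seed twice gives a byte-identical record
  rec2 <- generatePSG(co[1, ], "followup", seed = 9, tstMin = 8,
                      latencyEpochs = 2)
  expect_identical(rec@eeg, rec2@eeg)
  expect_identical(rec@spo2, rec2@spo2)
})
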