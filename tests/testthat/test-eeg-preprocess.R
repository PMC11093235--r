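# Preprocessing chain: referencing algebra, latency trimming, filter
# response, artifact regression, spike repair, bad-channel policy, z-score.

test_that("contralateral re-referencing subtracts the correct mastoid", {
  n <- 1000
  withr::with_seed(2, {
    eeg <- matrix(rnorm(8 * n), 8, n, dimnames = list(somnage:::EEG_CHANNELS, NULL))
  })
  eeg["F3", ] <- eeg["A2", ]  # identical to its reference
  ref <- rereference(eeg)
  expect_equal(ref["F3", ], rep(0, n))
  expect_equal(ref["C4", ], eeg["C4", ] - eeg["A1", ])
  # zero mastoids leave channels unchanged
  eeg0 <- eeg; eeg0["A1", ] <- 0; eeg0["A2", ] <- 0
  expect_equal(rereference(eeg0)["O1", ], eeg0["O1", ])
  # shared mastoid noise is removed: referenced output decorrelates from it
  withr::with_seed(3, {
    common <- rnorm(n)
    brain <- matrix(rnorm(8 * n), 8, n, dimnames = list(somnage:::EEG_CHANNELS, NULL))
  })
  noisy <- sweep(brain, 2, common, "+")
  refd <- rereference(noisy)
  expect_lt(abs(cor(refd["F3", ], common)), 0.1)
  expect_error(rereference(eeg[1:6, ]), "missing")
})

test_that("sleep-latency trimming crops signals and shifts annotations", {
  rec <- smallPSG(seed = 41)  # two leading W epochs
  expect_identical(stages(hypnogram(rec))[1:2], c("W", "W"))
  ar <- matrix(c(70, 80), 1, 2)
  rec2 <- PSGRecord(rec@subjectID, rec@visit, rec@eeg, rec@airflowThermal,
                    rec@airflowNasal, rec@spo2, rec@hypnogram,
                    arousals = ar, meta = rec@meta)
  tr <- trimSleepLatency(rec2)
  expect_equal(ncol(tr@eeg), ncol(rec@eeg) - 60 * 200)
  expect_equal(length(tr@spo2), length(rec@spo2) - 60)
  expect_equal(unname(arousalIntervals(tr)[1, ]), c(10, 20))
  expect_false(stages(hypnogram(tr))[1] == "W")
  # already-asleep record is the identity
  expect_identical(trimSleepLatency(tr)@eeg, tr@eeg)
  # all-wake hypnogram is an error
  allW <- PSGRecord("x", "baseline",
                    matrix(rnorm(8 * 60 * 200), 8, 60 * 200,
                           dimnames = list(somnage:::EEG_CHANNELS, NULL)),
                    rnorm(60 * 25), rnorm(60 * 25), rep(95, 60),
                    Hypnogram(c("W", "W")))
  expect_error(trimSleepLatency(allW), "no sleep onset")
})

test_that("band limiting passes 10 Hz, kills 70 Hz, preserves constants", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  ampAt <- function(f) {
    y <- bandlimit(sin(2 * pi * f * t), fs = fs)
    core <- y[(2 * fs):(8 * fs)]  # avoid edges
    sqrt(2 * mean(core^2))
  }
  expect_gt(ampAt(10), 0.95)
  expect_lt(ampAt(10), 1.05)
  expect_lt(ampAt(70), 0.01)
  expect_lt(ampAt(60) , 0.01)  # >= 40 dB by 60 Hz
  cst <- bandlimit(rep(3, 1000), fs = fs)
  expect_lt(max(abs(cst[100:900] - 3)), 1e-6)
})

test_that("artifact regression recovers the orthogonal component", {
  withr::with_seed(5, {
    n <- 5000
    eog <- rnorm(n)
    s <- rnorm(n)
  })
  s <- s - eog * sum(s * eog) / sum(eog^2)  # exactly orthogonal
  chan <- 0.5 * eog + s
  out <- regressOutArtifacts(chan, eog)
  expect_lt(sqrt(mean((out - s)^2)) / sd(s), 0.01)
  # zero references: identity
  expect_identical(regressOutArtifacts(chan, rep(0, n)), chan)
  # reference orthogonal to the channel: change under 1 percent
  out2 <- regressOutArtifacts(s, eog)
  expect_lt(sqrt(mean((out2 - s)^2)) / sd(s), 0.01)
  expect_warning(regressOutArtifacts(chan, NULL), "skipped")
})

test_that("spike interpolation flags 5-SD excursions and repairs them", {
  withr::with_seed(6, x <- rnorm(20000))
  x[777] <- 10  # ~10 SD spike
  rep_ <- interpolateSpikes(x)
  expect_true(rep_$mask[777])
  expect_gte(rep_$channel[777], min(x[776], x[778]))
  expect_lte(rep_$channel[777], max(x[776], x[778]))
  # clean Gaussian data flags (essentially) nothing
  withr::with_seed(7, y <- rnorm(50000))
  expect_lt(mean(interpolateSpikes(y)$mask), 0.01)
  # idempotence on the repaired signal
  again <- interpolateSpikes(rep_$channel)
  expect_false(any(again$mask))
  # zero variance: identity, no flags
  z <- interpolateSpikes(rep(1, 100))
  expect_false(any(z$mask))
  expect_identical(z$channel, rep(1, 100))
  # run of spikes is bridged linearly between the flanking good samples
  w <- rnorm(1000)
  w[500:503] <- 50
  rw <- interpolateSpikes(w)
  expect_true(all(rw$channel[500:503] >= min(w[499], w[504]) - 1e-12 &
                    rw$channel[500:503] <= max(w[499], w[504]) + 1e-12))
})

test_that("bad channels are replaced by their homologue above 30 percent", {
  n <- 1000
  withr::with_seed(8, {
    eeg <- matrix(rnorm(6 * n), 6, n,
                  dimnames = list(somnage:::SCALP_CHANNELS, NULL))
  })
  masks <- list(F3 = rep(c(TRUE, FALSE), c(400, 600)),
                C3 = rep(FALSE, n), O1 = rep(FALSE, n),
                F4 = rep(c(TRUE, FALSE), c(50, 950)),
                C4 = rep(FALSE, n), O2 = rep(FALSE, n))
  out <- replaceBadChannels(eeg, masks)
  expect_equal(out$eeg["F3", ], eeg["F4", ])
  expect_identical(out$replaced$bad, "F3")
  expect_identical(out$replaced$donor, "F4")
  # all under threshold: identity
  ok <- replaceBadChannels(eeg, lapply(masks, function(m) m & FALSE))
  expect_identical(ok$eeg, eeg)
  expect_equal(nrow(ok$replaced), 0)
  # both partners bad: pair unusable
  masks$F4 <- rep(c(TRUE, FALSE), c(400, 600))
  expect_error(replaceBadChannels(eeg, masks), "pair unusable")
})

test_that("z-scoring standardizes and is affine invariant", {
  withr::with_seed(9, x <- rnorm(10000, 3, 2))
  z <- zscoreChannel(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_equal(zscoreChannel(5 * x + 7), z)
  expect_error(zscoreChannel(rep(2, 50)), "zero variance")
})

test_that("the full chain is deterministic, ordered, and well-reported", {
  rec <- smallPSG(seed = 44)
  p1 <- preprocessPSG(rec)
  p2 <- preprocessPSG(rec)
  expect_identical(p1$eeg, p2$eeg)
  expect_equal(nrow(p1$eeg), 6)
  expect_equal(ncol(p1$eeg), recordingDuration(p1$hypnogram) * 200)
  # every channel exactly standardized
  expect_true(all(abs(apply(p1$eeg, 1, mean)) < 1e-9))
  expect_true(all(abs(apply(p1$eeg, 1, sd) - 1) < 1e-9))
  expect_identical(p1$report$steps_applied[1], "rereference")
  expect_identical(tail(p1$report$steps_applied, 1), "zscore")
  expect_true("artifact_regression_skipped_no_refs" %in% p1$report$steps_applied)
  # clean generator output: minimal flagging, no replacement
  expect_lt(p1$report$interpolated_fraction_overall, 0.01)
  expect_equal(nrow(p1$report$channels_replaced), 0)
  expect_true(all(p1$report$flagged_fraction >= 0 &
                    p1$report$flagged_fraction <= 1))
})
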