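# SpO2 cleaning, envelopes, event detection, hypoxic burden, indices.

test_that("SpO2 cleaning carries forward, flags exclusion, is idempotent", {
  out <- cleanSpo2(c(96, 95, 40, 40, 95))
  expect_equal(out$spo2, c(96, 95, 95, 95, 95))
  expect_equal(out$low_fraction, 0.4)
  expect_false(out$usable)  # 40 percent low exceeds the 20 percent rule

  ok <- cleanSpo2(c(97, 96, 98))
  expect_identical(ok$spo2, c(97, 96, 98))
  expect_true(ok$usable)
  expect_equal(ok$low_fraction, 0)

  # exactly at 20 percent stays usable; just above is excluded
  x20 <- c(rep(50, 20), rep(95, 80))
  expect_true(cleanSpo2(x20)$usable)
  x21 <- c(rep(50, 21), rep(95, 79))
  expect_false(cleanSpo2(x21)$usable)
  # replacement still applied in the excluded case
  expect_true(all(cleanSpo2(x21)$spo2 >= 60))

  # leading low run takes the first valid value
  lead <- cleanSpo2(c(30, 30, 92, 91))
  expect_equal(lead$spo2, c(92, 92, 92, 91))

  # idempotence and the >= 60 postcondition
  withr::with_seed(14, tr <- 96 - 40 * rbinom(200, 1, 0.1) + rnorm(200))
  c1 <- cleanSpo2(tr)
  expect_identical(cleanSpo2(c1$spo2)$spo2, c1$spo2)
  expect_gte(min(c1$spo2), 60)

  expect_warning(allLow <- cleanSpo2(c(40, 50, 45)), "unmodified")
  expect_false(allLow$usable)
  expect_identical(allLow$spo2, c(40, 50, 45))
})

test_that("breathing envelope tracks amplitude and scales linearly", {
  fs <- 25
  t <- (0:(300 * fs - 1)) / fs
  x <- sin(2 * pi * 0.25 * t)
  env <- breathEnvelope(x, fs)
  core <- env[(10 * fs):(290 * fs)]
  expect_lt(max(abs(core - sqrt(0.5))) / sqrt(0.5), 0.05)
  env2 <- breathEnvelope(x / 2, fs)
  expect_equal(env2, env / 2, tolerance = 1e-12)
  expect_true(all(breathEnvelope(rep(0, 5000), fs) == 0))
})

test_that("detector recovers planted events with correct typing", {
  sub <- quickSubject(ahi = 36, ai = 30)
  hyp <- generateHypnogram(sub, tstMin = 20, seed = 61, latencyEpochs = 0)
  r <- generateRespiration(sub, hyp, seed = 62, artifactRate = 0)
  cl <- cleanSpo2(r$spo2)
  ev <- detectEvents(breathEnvelope(r$airflow_thermal, 25),
                     breathEnvelope(r$airflow_nasal, 25),
                     cl$spo2, r$arousals, fs = 25)
  gt <- eventTable(r$events)
  det <- eventTable(ev)
  # >= 90 percent of planted events recovered with >= 90 percent type accuracy
  matched <- vapply(seq_len(nrow(gt)), function(i) {
    hit <- det$start_s < gt$end_s[i] & det$end_s > gt$start_s[i]
    if (!any(hit)) return(NA_character_)
    det$type[which(hit)[1]]
  }, character(1))
  expect_gte(mean(!is.na(matched)), 0.9)
  expect_gte(mean(matched == gt$type, na.rm = TRUE), 0.9)
})

test_that("sub-threshold reductions and unsupported hypopneas do not score", {
  fs <- 25
  dur <- 400
  t <- (0:(dur * fs - 1)) / fs
  base <- sin(2 * pi * 0.25 * t)
  spo2 <- rep(95, dur)

  # 9-s 95 percent reduction: too short for any event
  g <- rep(1, length(t)); g[t >= 200 & t < 209] <- 0.05
  ev <- detectEvents(breathEnvelope(base * g, fs), breathEnvelope(base * g, fs),
                     spo2, NULL, fs = fs)
  expect_equal(length(ev), 0)

  # 15-s 50 percent nasal reduction, no desaturation, no arousal: no hypopnea
  g2 <- rep(1, length(t)); g2[t >= 200 & t < 215] <- 0.5
  ev2 <- detectEvents(breathEnvelope(base, fs), breathEnvelope(base * g2, fs),
                      spo2, NULL, fs = fs)
  expect_equal(length(ev2), 0)

  # same reduction with a terminating arousal scores as hypopnea
  ev3 <- detectEvents(breathEnvelope(base, fs), breathEnvelope(base * g2, fs),
                      spo2, matrix(c(214, 217), 1, 2), fs = fs)
  expect_equal(eventTable(ev3)$type, "hypopnea")
  expect_true(eventTable(ev3)$arousal_matched)

  # same reduction with a >= 3 percent desaturation scores as hypopnea
  spo2d <- spo2; spo2d[220:235] <- 91
  ev4 <- detectEvents(breathEnvelope(base, fs), breathEnvelope(base * g2, fs),
                      spo2d, NULL, fs = fs)
  expect_equal(eventTable(ev4)$type, "hypopnea")
  expect_true(eventTable(ev4)$desat_matched)

  # a 95 percent thermal drop >= 10 s is an apnea even without evidence
  g3 <- rep(1, length(t)); g3[t >= 200 & t < 218] <- 0.05
  ev5 <- detectEvents(breathEnvelope(base * g3, fs), breathEnvelope(base * g3, fs),
                      spo2, NULL, fs = fs)
  expect_equal(eventTable(ev5)$type, "apnea")

  expect_error(detectEvents(rep(1, 100), rep(1, 100), spo2, NULL, fs = fs),
               "120 s")
})

test_that("detector is scale invariant in the airflow units", {
  sub <- quickSubject(ahi = 24)
  hyp <- generateHypnogram(sub, tstMin = 15, seed = 63, latencyEpochs = 0)
  r <- generateRespiration(sub, hyp, seed = 64, artifactRate = 0)
  cl <- cleanSpo2(r$spo2)
  e1 <- detectEvents(breathEnvelope(r$airflow_thermal, 25),
                     breathEnvelope(r$airflow_nasal, 25), cl$spo2, r$arousals, 25)
  e2 <- detectEvents(breathEnvelope(1000 * r$airflow_thermal, 25),
                     breathEnvelope(1000 * r$airflow_nasal, 25), cl$spo2,
                     r$arousals, 25)
  expect_equal(eventTable(e1)$start_s, eventTable(e2)$start_s)
  expect_identical(eventTable(e1)$type, eventTable(e2)$type)
})

test_that("a rectangular 4 percent desaturation integrates to 4 percent-minutes", {
  spo2 <- rep(96, 200)
  spo2[11:70] <- 92  # 60 samples at -4, instant edges
  area <- eventHypoxicArea(spo2, startS = 5, endS = 40, nextEventStart = Inf)
  expect_equal(area, 4.0, tolerance = 1e-9)
  # constant trace: zero
  expect_equal(eventHypoxicArea(rep(95, 200), 5, 40), 0)
})

test_that("hypoxic area equals brute-force trapezoid integration (fuzz)", {
  bruteForce <- function(spo2, st, en, nx) {
    times <- 0:(length(spo2) - 1)
    pre <- spo2[times >= en - 100 & times < en]
    base <- max(pre)
    wEnd <- min(en + 45, nx)
    idx <- which(times >= st & times < wEnd)
    if (length(idx) < 2) return(0)
    acc <- 0
    for (k in seq_len(length(idx) - 1)) {
      d1 <- max(0, base - spo2[idx[k]]); d2 <- max(0, base - spo2[idx[k + 1]])
      acc <- acc + (d1 + d2) / 2 * (times[idx[k + 1]] - times[idx[k]])
    }
    acc / 60
  }
  withr::with_seed(15, {
    for (rep_ in 1:1000) {
      n <- sample(150:400, 1)
      spo2 <- pmin(pmax(96 - cumsum(rnorm(n, 0, 0.8)) * 0.2, 60), 100)
      st <- runif(1, 0, n - 120)
      en <- st + runif(1, 10, 60)
      nx <- if (runif(1) < 0.5) en + runif(1, 1, 50) else Inf
      expect_equal(eventHypoxicArea(spo2, st, en, nx),
                   bruteForce(spo2, st, en, nx), tolerance = 1e-9)
    }
  })
})

test_that("hypoxic burden partitions exactly by event type", {
  sub <- quickSubject(ahi = 40)
  for (s in 1:5) {
    hyp <- generateHypnogram(sub, tstMin = 15, seed = 70 + s, latencyEpochs = 0)
    r <- generateRespiration(sub, hyp, seed = 80 + s, artifactRate = 0)
    cl <- cleanSpo2(r$spo2)
    tst <- totalSleepTime(hyp)
    total <- hypoxicBurden(cl$spo2, r$events, tst, "all")
    ap <- hypoxicBurden(cl$spo2, r$events, tst, "apnea")
    hy <- hypoxicBurden(cl$spo2, r$events, tst, "hypopnea")
    expect_equal(total, ap + hy, tolerance = 1e-9)
    expect_gte(total, 0)
  }
  # no events -> 0; unusable SpO2 -> NA
  expect_equal(hypoxicBurden(rep(95, 600), EventList(), 1, "all"), 0)
  expect_true(is.na(hypoxicBurden(rep(95, 600), EventList(), 1, "all",
                                  usable = FALSE)))
  # single event with a known area over one hour of sleep
  spo2 <- rep(96, 3600)
  spo2[101:160] <- 92
  evs <- EventList("apnea", 95, 130)
  expect_equal(hypoxicBurden(spo2, evs, 1, "all"), 4.0, tolerance = 1e-9)
})

test_that("indices count events per hour of sleep with consistent sums", {
  hyp <- Hypnogram(c(rep("W", 2), rep("N2", 720)))  # TST exactly 6 h
  starts <- seq(100, by = 500, length.out = 42)
  evs <- EventList(type = rep(c("apnea", "hypopnea"), c(30, 12)),
                   start_s = starts, end_s = starts + 20)
  spo2 <- rep(95, recordingDuration(hyp))
  idx <- computeIndices(evs, NULL, spo2, hyp)
  expect_equal(idx$ahi, 7.0)
  expect_equal(idx$apnea_index, 5.0)
  expect_equal(idx$hypopnea_index, 2.0)
  expect_equal(idx$ai, 0)
  expect_equal(idx$ahi, idx$apnea_index + idx$hypopnea_index)
  expect_equal(idx$hb_total, idx$hb_apnea + idx$hb_hypopnea)
  expect_equal(idx$odi, 0)  # flat trace: no desaturations
})

test_that("computed AHI matches the generator's configuration on average", {
  sub <- quickSubject(ahi = 42)
  ahis <- vapply(1:50, function(s) {
    hyp <- generateHypnogram(sub, tstMin = 30, seed = 900 + s, latencyEpochs = 0)
    r <- generateRespiration(sub, hyp, seed = 950 + s, artifactRate = 0)
    idx <- computeIndices(r$events, r$arousals, cleanSpo2(r$spo2)$spo2, hyp)
    idx$ahi
  }, numeric(1))
  expect_lt(abs(mean(ahis) - 42), 2)
})

test_that("ODI counts sustained desaturations and merges close ones", {
  spo2 <- rep(96, 1200)
  spo2[200:210] <- 92    # one sustained episode
  spo2[215:222] <- 91.5  # within 10 s: merges with the previous
  spo2[500:507] <- 92    # separate episode
  spo2[800:801] <- 90    # too short (2 s)
  hyp <- Hypnogram(rep("N2", 40))  # TST 1200 s
  idx <- computeIndices(EventList(), NULL, spo2, hyp)
  expect_equal(idx$odi, 2 / (1200 / 3600))
})
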