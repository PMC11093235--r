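# Synthetic PSG cohort generator.
#
# Generates cohorts with the statistical structure the downstream analysis
# assumes: a latent true brain age per subject with group-specific annual
# drift, correlated OSA severity features (AHI, HB, AI, ODI), stage-dependent
# EEG spectra whose slow/delta power declines with true brain age, and
# airflow/SpO2 traces with planted apnea/hypopnea events. Everything is
# deterministic under the configured seed.

#' Cohort generator configuration
#'
#' Builds a configuration for [generateCohort()]. Two presets encode the
#' published baseline characteristics of the clinical cohorts this package's
#' statistics are designed for: `"smc_treated"` (n-nominal 98, age 53.3 (9.5),
#' AHI median 42.1, annual brain-age drift -0.6 (2.7) y/y) and
#' `"smc_untreated"` (n 88, age 48.8 (11.4), AHI median 23.4, drift
#' +0.3 (2.6) y/y). Severity couplings and effect-modification weights
#' default to the observed sign pattern: in untreated subjects drift grows
#' with baseline severity and baseline BAI; under treatment it falls with
#' them (and with age).
#'
#' Effect modification is parameterized on the latent standard-normal scale:
#' `slopes` gives weights on the severity latent, the baseline-BAI latent and
#' the age latent plus a residual weight; the weighted sum is normalized to
#' unit variance, so `drift_sd` is always the total drift SD. Setting all
#' three structural weights to 0 gives pure noise drift.
#'
#' A third preset, `"model_dev"`, describes a brain-age model development
#' population: ages drawn uniformly over 20-80 years, a small true
#' brain-age offset dispersion (reference sleepers rather than severe OSA),
#' moderate severity, and no drift. It is the default training population
#' for the trainable regressor kinds.
#'
#' @param preset `"smc_treated"`, `"smc_untreated"`, `"model_dev"`, or
#'   `"custom"`.
#' @param nSubjects number of subjects (default: the preset's cohort size).
#' @param seed integer seed.
#' @param ... named overrides of any configuration field (see Details).
#' @return a list of class `cohort_config`.
#' @export
cohortConfig <- function(preset = c("smc_treated", "smc_untreated",
                                    "model_dev", "custom"),
                         nSubjects = NULL, seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    model_dev = list(
      group = "untreated", n_subjects = 200L,
      age_mean = 50, age_sd = 17.3, age_dist = "uniform", age_range = c(20, 80),
      male_frac = 0.6, bmi_mean = 25, bmi_sd = 3.5, ess_mean = 8, ess_sd = 4,
      drift_mean = 0, drift_sd = 1,
      interval_mean = 2, interval_sd = 1, interval_range = c(1, 9),
      ahi_median = 15, ahi_sdlog = 0.6, ai_mean = 20, ai_sd = 10,
      bai_mean = 0, bai_sd = 3,
      slopes = list(severity = 0, bai = 0, age = 0, residual = 1),
      adherence = FALSE, tst_mean = 400, tst_sd = 50),
    smc_treated = list(
      group = "treated", n_subjects = 98L,
      age_mean = 53.3, age_sd = 9.5, male_frac = 0.908,
      bmi_mean = 26.4, bmi_sd = 2.8, ess_mean = 10.4, ess_sd = 4.9,
      drift_mean = -0.6, drift_sd = 2.7,
      interval_mean = 4.7, interval_sd = 2.5, interval_range = c(1, 9),
      ahi_median = 42.1, ahi_sdlog = 0.49, ai_mean = 37.7, ai_sd = 17.4,
      bai_mean = 0.6, bai_sd = 6.4,
      slopes = list(severity = -1, bai = -1.15, age = -0.5, residual = 1.0),
      adherence = TRUE, tst_mean = 364, tst_sd = 57),
    smc_untreated = list(
      group = "untreated", n_subjects = 88L,
      age_mean = 48.8, age_sd = 11.4, male_frac = 0.807,
      bmi_mean = 25.7, bmi_sd = 4.2, ess_mean = 9.7, ess_sd = 5.3,
      drift_mean = 0.3, drift_sd = 2.6,
      interval_mean = 4.2, interval_sd = 2.4, interval_range = c(1, 9),
      ahi_median = 23.4, ahi_sdlog = 0.63, ai_mean = 30.1, ai_sd = 20,
      bai_mean = 0.6, bai_sd = 6.9,
      slopes = list(severity = 1, bai = 0.8, age = 0, residual = 1.85),
      adherence = FALSE, tst_mean = 370, tst_sd = 58),
    custom = list(
      group = "untreated", n_subjects = 50L,
      age_mean = 50, age_sd = 10, male_frac = 0.85,
      bmi_mean = 26, bmi_sd = 3.5, ess_mean = 10, ess_sd = 5,
      drift_mean = 0, drift_sd = 2.5,
      interval_mean = 4.5, interval_sd = 2.5, interval_range = c(1, 9),
      ahi_median = 30, ahi_sdlog = 0.55, ai_mean = 33, ai_sd = 18,
      bai_mean = 0.6, bai_sd = 6.5,
      slopes = list(severity = 0, bai = 0, age = 0, residual = 1),
      adherence = FALSE, tst_mean = 364, tst_sd = 57))
  cfg$age_dist <- cfg$age_dist %||% "normal"
  cfg$age_range <- cfg$age_range %||% c(20, 85)
  cfg$hb_coef <- 0.38
  cfg$hb_exp <- 1.5
  cfg$seed <- as.integer(seed)
  dots <- list(...)
  if (!is.null(nSubjects)) cfg$n_subjects <- as.integer(nSubjects)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop(sprintf("unknown cohort config field '%s'", nm))
    cfg[[nm]] <- dots[[nm]]
  }
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1")
  if (cfg$age_sd < 0 || cfg$drift_sd < 0) stop("standard deviations must be >= 0")
  if (any(cfg$interval_range <= 0)) stop("intervals must be positive")
  class(cfg) <- "cohort_config"
  cfg
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  for (i in bad) {
    for (k in 1:50) {
      x[i] <- rnorm(1, mean, sd)
      if (x[i] >= lo && x[i] <= hi) break
    }
    x[i] <- .clamp(x[i], lo, hi)
  }
  x
}

#' Generate a latent subject cohort
#'
#' Draws per-subject latent quantities: chronological age, the true baseline
#' brain-age offset (the quantity whose estimate is BAI), the annual drift of
#' that offset, correlated severity features (AHI, AI, ODI, apnea/hypopnea
#' split, total/apnea-/hypopnea-specific hypoxic burden), anthropometrics,
#' the assessment interval, and (for treated cohorts) CPAP adherence.
#' The true follow-up offset is `bai_true_baseline + annual_drift * interval`.
#'
#' @param config a `cohort_config` from [cohortConfig()].
#' @return data.frame, one row per subject, with attribute `"config"`.
#' @examples
#' cohort <- generateCohort(cohortConfig("smc_treated", seed = 7))
#' mean(cohort$annual_drift)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_subjects
  withr::with_seed(cfg$seed, {
    zSev <- rnorm(n); zBai <- rnorm(n); zAge <- rnorm(n)
    age <- if (identical(cfg$age_dist, "uniform")) {
      u <- pnorm(zAge)  # keep zAge as the age latent for effect modification
      cfg$age_range[1] + u * diff(cfg$age_range)
    } else {
      .clamp(cfg$age_mean + cfg$age_sd * zAge, cfg$age_range[1], cfg$age_range[2])
    }
    sex <- rbinom(n, 1, cfg$male_frac)
    bmi <- .rtruncnorm(n, cfg$bmi_mean, cfg$bmi_sd, 17, 45)
    ess <- .rtruncnorm(n, cfg$ess_mean, cfg$ess_sd, 0, 24)
    baiTrue <- cfg$bai_mean + cfg$bai_sd * zBai

    zAhi <- 0.9 * zSev + sqrt(1 - 0.81) * rnorm(n)
    ahi <- .clamp(exp(log(cfg$ahi_median) + cfg$ahi_sdlog * zAhi), 5, 130)
    ai <- .clamp(cfg$ai_mean + cfg$ai_sd * (0.8 * zSev + 0.6 * rnorm(n)), 5, 130)
    odi <- pmax(0.75 * ahi + 6 * rnorm(n), 0.5)
    apneaShare <- stats::plogis(0.1 + 0.9 * zSev + 0.5 * rnorm(n))
    apneaIndex <- apneaShare * ahi
    hypopneaIndex <- ahi - apneaIndex
    hbTotal <- cfg$hb_coef * ahi^cfg$hb_exp * exp(0.4 * rnorm(n))
    hbApneaShare <- stats::plogis(1.0 * zSev + 0.5 * rnorm(n))
    hbApnea <- hbApneaShare * hbTotal
    hbHypopnea <- hbTotal - hbApnea

    s <- cfg$slopes
    w <- c(s$severity, s$bai, s$age, s$residual)
    norm <- sqrt(sum(w^2))
    driftZ <- if (norm == 0) rep(0, n) else {
      (s$severity * zSev + s$bai * zBai + s$age * zAge + s$residual * rnorm(n)) / norm
    }
    drift <- cfg$drift_mean + cfg$drift_sd * driftZ

    interval <- .rtruncnorm(n, cfg$interval_mean, cfg$interval_sd,
                            cfg$interval_range[1], cfg$interval_range[2])
    tst <- .rtruncnorm(n, cfg$tst_mean, cfg$tst_sd, 240, 520)
    adherencePct <- if (cfg$adherence) .rtruncnorm(n, 77.6, 18.7, 20, 100) else rep(NA_real_, n)
    adherenceHrs <- if (cfg$adherence) .rtruncnorm(n, 5.9, 1.0, 4, 10) else rep(NA_real_, n)

    cohort <- data.frame(
      subject_id = sprintf("%s%03d", if (cfg$group == "treated") "T" else "U", seq_len(n)),
      group = cfg$group, age = age, sex = sex, bmi = bmi, ess = ess,
      interval_years = interval, bai_true_baseline = baiTrue,
      annual_drift = drift, ahi = ahi, ai = ai, odi = odi,
      apnea_index = apneaIndex, hypopnea_index = hypopneaIndex,
      hb_total = hbTotal, hb_apnea = hbApnea, hb_hypopnea = hbHypopnea,
      adherence_pct_days_4h = adherencePct, adherence_mean_hours = adherenceHrs,
      tst_min = tst, latent_severity = zSev,
      stringsAsFactors = FALSE)
  })
  attr(cohort, "config") <- cfg
  cohort
}

#' True brain age of a latent subject at a visit
#'
#' Baseline: `age + bai_true_baseline`. Follow-up: chronological age advances
#' by the interval and the offset by `annual_drift * interval`.
#'
#' @param subject one-row data.frame from [generateCohort()].
#' @param visit `"baseline"` or `"followup"`.
#' @return true brain age in years.
#' @export
trueBrainAge <- function(subject, visit = c("baseline", "followup")) {
  visit <- match.arg(visit)
  offset <- subject$bai_true_baseline
  if (visit == "followup") {
    offset <- offset + subject$annual_drift * subject$interval_years
    return(subject$age + subject$interval_years + offset)
  }
  subject$age + offset
}

#' Generate a hypnogram for one night
#'
#' A run of wake epochs (sleep latency) followed by a sticky Markov chain over
#' the sleep stages whose stationary stage mix matches clinical PSG in OSA:
#' the N1 fraction increases with the subject's AHI (sleep fragmentation),
#' N2 dominates, N3 is scarce. There is no wake after sleep onset, so the
#' total sleep time equals `tstMin` exactly.
#'
#' @param subject one-row cohort data.frame (uses `ahi`).
#' @param tstMin total sleep time in minutes.
#' @param seed integer seed.
#' @param latencyEpochs number of initial wake epochs; default Poisson with
#'   mean 18 (9 min median sleep latency).
#' @return a [Hypnogram-class].
#' @export
generateHypnogram <- function(subject, tstMin, seed, latencyEpochs = NULL) {
  stopifnot(tstMin > 0)
  withr::with_seed(seed, {
    lat <- latencyEpochs %||% rpois(1, 18)
    nSleep <- ceiling(tstMin * 60 / 30)
    n1 <- .clamp(0.22 + 0.0017 * (subject$ahi %||% 0), 0.05, 0.6)
    rest <- 1 - n1
    targets <- c(N1 = n1, N2 = rest * 0.68, N3 = rest * 0.04, REM = rest * 0.28)
    stick <- 0.75
    P <- stick * diag(4) + (1 - stick) * matrix(targets, 4, 4, byrow = TRUE)
    states <- names(targets)
    st <- integer(nSleep)
    st[1] <- 1L  # sleep onset through N1
    for (i in seq_len(nSleep - 1)) {
      st[i + 1] <- sample.int(4, 1, prob = P[st[i], ])
    }
    Hypnogram(c(rep("W", lat), states[st]))
  })
}

# Spectral components: log-frequency Gaussian bumps (delta/slow, theta,
# alpha, sigma, beta, gamma) plus a 1/f floor. Stage rows give base power
# weights; aging multiplies the delta (and half the theta) weight down.
.EEG_COMP_CENTERS <- c(1.5, 6, 10, 14, 24, 40)
.EEG_COMP_WIDTHS <- c(0.80, 0.35, 0.25, 0.18, 0.35, 0.25)
.EEG_STAGE_WEIGHTS <- rbind(
  W   = c(0.35, 0.30, 1.00, 0.25, 0.50, 0.15),
  N1  = c(0.60, 1.00, 0.50, 0.30, 0.35, 0.10),
  N2  = c(1.20, 0.80, 0.40, 0.80, 0.30, 0.08),
  N3  = c(2.50, 0.70, 0.30, 0.40, 0.20, 0.05),
  REM = c(0.50, 0.90, 0.45, 0.30, 0.45, 0.12))

.shapedNoise <- function(n, envSqrt) {
  z <- fft(rnorm(n))
  Re(fft(z * envSqrt, inverse = TRUE)) / n
}

#' Generate 8-channel sleep EEG for one night
#'
#' Per-epoch colored noise with stage-dependent spectra (N3 delta-dominant,
#' wake alpha-dominant). The log10 power of the slow/delta component declines
#' linearly with the subject's true brain age at the visit at `ageSlope`
#' log10-power units per year (theta at half that slope), on top of a
#' per-subject spectral trait (`subjectSd`, log10 units) and per-epoch,
#' per-component jitter (`epochJitterSd`). The mastoids carry a shared noise
#' trace that also leaks into every scalp channel, emulating the common
#' reference component removed by contralateral re-referencing.
#'
#' @param subject one-row cohort data.frame.
#' @param hypnogram a [Hypnogram-class].
#' @param visit `"baseline"` or `"followup"` (sets the true brain age).
#' @param seed integer seed.
#' @param fs sampling rate, Hz.
#' @param ageSlope log10-power decline of the delta component per year of
#'   true brain age.
#' @param subjectSd SD of the stable per-subject delta-power trait
#'   (log10 units); this is the floor on how well any regressor can read age
#'   back off the spectra.
#' @param epochJitterSd per-epoch log10 jitter of each spectral component.
#' @return 8 x N matrix (volts), rows `F3,F4,C3,C4,O1,O2,A1,A2`.
#' @export
generateEEG <- function(subject, hypnogram, visit = "baseline", seed = 1L,
                        fs = 200, ageSlope = 0.01, subjectSd = 0.02,
                        epochJitterSd = 0.1) {
  stopifnot(is(hypnogram, "Hypnogram"))
  ba <- trueBrainAge(subject, visit)
  # the spectral trait is a stable subject characteristic: same across visits
  trait <- withr::with_seed(.hashString(paste0("trait", subject$subject_id)),
                            rnorm(1, 0, subjectSd))
  ne <- nEpochs(hypnogram)
  nes <- 30 * fs
  n <- ne * nes
  freqs <- fs * (0:(nes - 1)) / nes
  ffold <- pmin(freqs, fs - freqs)  # two-sided spectrum frequencies
  bumps <- vapply(seq_along(.EEG_COMP_CENTERS), function(k) {
    exp(-(log(pmax(ffold, 0.05) / .EEG_COMP_CENTERS[k]))^2 / (2 * .EEG_COMP_WIDTHS[k]^2))
  }, numeric(nes))
  floorEnv <- 0.02 / pmax(ffold, 0.3)
  ageMult <- c(10^(-(ageSlope) * (ba - 50) + trait),
               10^(-(0.5 * ageSlope) * (ba - 50) + 0.5 * trait), 1, 1, 1, 1)

  withr::with_seed(seed, {
    eeg <- matrix(0, 8, n, dimnames = list(EEG_CHANNELS, NULL))
    stageIdx <- match(stages(hypnogram), rownames(.EEG_STAGE_WEIGHTS))
    for (ch in seq_along(SCALP_CHANNELS)) {
      x <- numeric(n)
      for (e in seq_len(ne)) {
        w <- .EEG_STAGE_WEIGHTS[stageIdx[e], ] * ageMult *
          10^rnorm(6, 0, epochJitterSd)
        env <- as.numeric(bumps %*% w) + floorEnv
        x[((e - 1) * nes + 1):(e * nes)] <- .shapedNoise(nes, sqrt(env))
      }
      eeg[SCALP_CHANNELS[ch], ] <- x
    }
    # shared mastoid/reference noise: pink, common to A1, A2 and all scalp
    fAll <- fs * (0:(n - 1)) / n
    common <- .shapedNoise(n, sqrt(0.15 / pmax(pmin(fAll, fs - fAll), 0.3)))
    eeg[SCALP_CHANNELS, ] <- sweep(eeg[SCALP_CHANNELS, ], 2, common, "+")
    eeg["A1", ] <- common + 0.15 * rnorm(n)
    eeg["A2", ] <- common + 0.15 * rnorm(n)
  })
  eeg * 25e-6
}

#' Generate airflow, SpO2, events and arousals for one night
#'
#' Breathing is an amplitude-modulated ~0.25 Hz oscillation on both sensors.
#' Planted apneas reduce the envelope by >= 90 percent for >= 10 s; hypopneas
#' reduce the nasal envelope by 35-75 percent and carry a >= 3 percent SpO2
#' desaturation and/or a terminating arousal. Desaturations fall linearly
#' from event start to a nadir `desatLag` seconds after event end, then
#' recover exponentially with time constant `desatTau`. Event count per hour
#' of sleep matches the subject's AHI (up to rounding); the apnea/hypopnea
#' split matches the subject's apnea index share. The ground-truth
#' [EventList-class] is returned for detector validation.
#'
#' @param subject one-row cohort data.frame.
#' @param hypnogram a [Hypnogram-class].
#' @param seed integer seed.
#' @param fs airflow sampling rate (Hz).
#' @param artifactRate expected SpO2 artifact spikes (sub-60 percent drops)
#'   per hour; 0 disables artifacts.
#' @param desatLag seconds from event end to desaturation nadir.
#' @param desatTau recovery time constant, seconds.
#' @return list with `airflow_thermal`, `airflow_nasal`, `spo2`, `events`
#'   (ground truth [EventList-class]), `arousals` (n x 2 matrix).
#' @export
generateRespiration <- function(subject, hypnogram, seed, fs = 25,
                                artifactRate = 0.5, desatLag = 20,
                                desatTau = 10) {
  stopifnot(is(hypnogram, "Hypnogram"))
  dur <- recordingDuration(hypnogram)
  tstH <- totalSleepTime(hypnogram)
  latEnd <- 30 * sum(cumprod(stages(hypnogram) == "W"))
  withr::with_seed(seed, {
    nEv <- round((subject$ahi %||% 0) * tstH)
    apShare <- if (!is.null(subject$apnea_index) && subject$ahi > 0) {
      subject$apnea_index / subject$ahi
    } else 0.5
    nAp <- round(nEv * apShare)
    types <- c(rep("apnea", nAp), rep("hypopnea", nEv - nAp))
    if (nEv > 0) types <- sample(types)
    durs <- ifelse(types == "apnea", runif(nEv, 12, 35), runif(nEv, 15, 40))
    sleepSec <- dur - latEnd
    # shrink the event count if the night physically cannot hold them
    while (nEv > 0 && sum(durs + 10) > 0.9 * sleepSec) {
      nEv <- nEv - 1; types <- types[-1]; durs <- durs[-1]
    }
    if (nEv > 0) {
      gaps <- runif(nEv + 1)
      gaps <- gaps / sum(gaps) * (sleepSec - sum(durs + 10))
      starts <- latEnd + cumsum(gaps[seq_len(nEv)] + c(0, durs[-nEv] + 10)) + 10
      ends <- starts + durs
    } else {
      starts <- ends <- numeric(0)
    }

    desat <- ifelse(types == "apnea", TRUE, runif(nEv) < 0.75)
    arous <- ifelse(types == "apnea", runif(nEv) < 0.5, runif(nEv) < 0.6)
    arous[types == "hypopnea" & !desat] <- TRUE
    depths <- ifelse(types == "apnea", runif(nEv, 4, 10),
                     ifelse(desat, runif(nEv, 3.2, 7), 0))

    # airflow with per-event envelope suppression
    tt <- (0:(dur * fs - 1)) / fs
    slow <- .movavg(rnorm(length(tt), 0, 1), 20 * fs)
    base <- (1 + 0.15 * slow / max(sd(slow), 1e-12) * 0.5) * sin(2 * pi * 0.25 * tt + runif(1, 0, 2 * pi))
    gainT <- rep(1, length(tt)); gainN <- rep(1, length(tt))
    for (i in seq_len(nEv)) {
      idx <- which(tt >= starts[i] & tt < ends[i])
      if (types[i] == "apnea") {
        g <- runif(1, 0.02, 0.08)
        gainT[idx] <- g; gainN[idx] <- min(g * runif(1, 0.8, 1.2), 0.1)
      } else {
        gainN[idx] <- runif(1, 0.25, 0.65)
        gainT[idx] <- runif(1, 0.45, 0.70)
      }
    }
    gainT <- .movavg(gainT, fs); gainN <- .movavg(gainN, fs)
    thermal <- base * gainT + 0.02 * rnorm(length(tt))
    nasal <- base * gainN + 0.02 * rnorm(length(tt))

    # SpO2 at 1 Hz with event-coupled desaturations
    ts <- 0:(dur - 1)
    spo2 <- 96 + 0.4 * sin(2 * pi * ts / 1800 + runif(1, 0, 2 * pi)) + 0.15 * rnorm(dur)
    for (i in seq_len(nEv)) {
      if (depths[i] <= 0) next
      nadirT <- ends[i] + desatLag
      dip <- numeric(dur)
      ramp <- ts >= starts[i] & ts <= nadirT
      dip[ramp] <- depths[i] * (ts[ramp] - starts[i]) / (nadirT - starts[i])
      rec <- ts > nadirT
      dip[rec] <- depths[i] * exp(-(ts[rec] - nadirT) / desatTau)
      spo2 <- spo2 - dip
    }
    nArt <- if (artifactRate > 0) rpois(1, artifactRate * dur / 3600) else 0
    for (k in seq_len(nArt)) {
      a0 <- sample.int(dur - 5, 1)
      spo2[a0:(a0 + sample(2:4, 1))] <- runif(1, 40, 55)
    }
    spo2 <- .clamp(spo2, 0, 100)

    # arousals: event-terminating plus spontaneous, to the subject's AI
    arStarts <- ends[arous]
    nSpont <- max(0, round((subject$ai %||% 0) * tstH) - length(arStarts))
    if (nSpont > 0) {
      arStarts <- c(arStarts, sort(runif(nSpont, latEnd, dur - 5)))
    }
    arStarts <- sort(arStarts)
    if (length(arStarts) > 1) {  # drop overlapping arousals
      keep <- c(TRUE, diff(arStarts) >= 3)
      arStarts <- arStarts[keep]
    }
    arousals <- if (length(arStarts) > 0) cbind(arStarts, arStarts + 3) else NULL

    events <- if (nEv > 0) {
      EventList(type = types, start_s = starts, end_s = ends,
                desat_matched = desat, arousal_matched = arous)
    } else EventList()
  })
  list(airflow_thermal = thermal, airflow_nasal = nasal, spo2 = spo2,
       events = events, arousals = arousals)
}

#' Generate a complete synthetic PSG night
#'
#' Composes [generateHypnogram()], [generateEEG()] and
#' [generateRespiration()] into a validated [PSGRecord-class]. The record's
#' metadata carries the generator's ground truth (true brain age at the
#' visit, annual drift, configured severity) so downstream estimates can be
#' checked against it.
#'
#' @param subject one-row cohort data.frame from [generateCohort()].
#' @param visit `"baseline"` or `"followup"`.
#' @param seed integer seed; every sub-generator derives from it.
#' @param tstMin total sleep time in minutes (default: the subject's drawn
#'   `tst_min`).
#' @param latencyEpochs initial wake epochs (default: Poisson, mean 18).
#' @param artifactRate SpO2 artifact rate per hour (see
#'   [generateRespiration()]).
#' @param ... passed to [generateEEG()] (e.g. `ageSlope`).
#' @return a [PSGRecord-class].
#' @export
generatePSG <- function(subject, visit = "baseline", seed = 1L, tstMin = NULL,
                        latencyEpochs = NULL, artifactRate = 0.5, ...) {
  tstMin <- tstMin %||% subject$tst_min %||% 364
  hyp <- generateHypnogram(subject, tstMin, seed = .deriveSeed(seed, 1),
                           latencyEpochs = latencyEpochs)
  eeg <- generateEEG(subject, hyp, visit = visit, seed = .deriveSeed(seed, 2), ...)
  resp <- generateRespiration(subject, hyp, seed = .deriveSeed(seed, 3),
                              artifactRate = artifactRate)
  meta <- as.list(subject)
  meta$true_brain_age <- trueBrainAge(subject, visit)
  meta$planted_ahi <- length(resp$events) / totalSleepTime(hyp)
  PSGRecord(subjectID = subject$subject_id, visit = visit, eeg = eeg,
            airflowThermal = resp$airflow_thermal,
            airflowNasal = resp$airflow_nasal, spo2 = resp$spo2,
            hypnogram = hyp, fsEEG = 200, fsAirflow = 25,
            arousals = resp$arousals, events = resp$events, meta = meta)
}
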