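# SpO2 cleaning, respiratory event detection from airflow envelopes,
# per-event hypoxic areas, apnea-/hypopnea-specific hypoxic burden, and the
# standard per-hour sleep/respiratory indices.

#' Clean an SpO2 trace
#'
#' Samples below 60 percent are treated as sensor artifact and replaced by
#' the most recent preceding value >= 60 (leading low samples take the first
#' valid value). A night with more than 20 percent of samples below 60 is
#' flagged unusable for hypoxic-burden calculation; the replacement is still
#' applied. An all-low trace is returned unmodified with a warning.
#'
#' Idempotent: cleaning a cleaned trace changes nothing.
#'
#' @param spo2 1-Hz SpO2 trace, percent.
#' @param floorPct artifact floor (60).
#' @param maxLowFrac exclusion threshold on the low fraction (0.20).
#' @return list with `spo2` (cleaned trace), `usable` (logical), and
#'   `low_fraction` (fraction of samples below the floor).
#' @export
cleanSpo2 <- function(spo2, floorPct = 60, maxLowFrac = 0.20) {
  stopifnot(length(spo2) > 0)
  low <- spo2 < floorPct
  lowFrac <- mean(low)
  usable <- lowFrac <= maxLowFrac
  if (all(low)) {
    warning("all SpO2 samples below the artifact floor; trace returned unmodified")
    return(list(spo2 = spo2, usable = FALSE, low_fraction = 1))
  }
  cleaned <- spo2
  if (any(low)) {
    idx <- seq_along(spo2)
    validIdx <- ifelse(low, NA_integer_, idx)
    lastValid <- cummax(ifelse(is.na(validIdx), 0L, validIdx))
    firstValid <- which(!low)[1]
    lastValid[lastValid == 0L] <- firstValid  # leading low run
    cleaned[low] <- spo2[lastValid[low]]
  }
  list(spo2 = cleaned, usable = usable, low_fraction = lowFrac)
}

#' Breathing amplitude envelope
#'
#' Moving RMS over a 4-s window followed by a 1-s moving-average smooth.
#' Scale-equivariant: halving the airflow amplitude halves the envelope.
#'
#' @param airflow airflow trace (arbitrary units).
#' @param fs sampling rate, Hz.
#' @param rmsWin RMS window, seconds.
#' @return positive envelope at the input rate.
#' @export
breathEnvelope <- function(airflow, fs, rmsWin = 4) {
  n <- max(3, round(rmsWin * fs))
  env <- sqrt(pmax(.movavg(airflow^2, n), 0))
  .movavg(env, max(3, round(fs)))
}

#' Detect apneas and hypopneas from airflow envelopes
#'
#' The breathing baseline at each instant is the mean envelope over the
#' preceding 100 s of non-suppressed breathing (samples where either sensor
#' drops below 70 percent of its running baseline are excluded from the
#' baseline buffer). An apnea is a >= 90 percent drop of the thermal
#' envelope (ratio <= 0.10) lasting >= 10 s; because the moving-RMS envelope
#' smears the edges of a deep drop, the deep core marks the event and its
#' duration is measured over the enclosing suppression span (thermal ratio
#' <= 0.70), which tracks the true airflow-reduction interval. A hypopnea
#' is a >= 30 percent drop of the nasal-pressure envelope (ratio <= 0.70)
#' lasting >= 10 s, corroborated by a >= 3 percent SpO2 fall from the
#' pre-event 100-s maximum within 45 s after event end, or by an arousal
#' overlapping `[start, end + 5)`. Contiguous criterion spans merge into a
#' single event, and apneas take precedence where both criteria fire on
#' overlapping spans.
#'
#' @param thermalEnv,nasalEnv envelopes from [breathEnvelope()], same rate.
#' @param spo2Clean cleaned 1-Hz SpO2 trace ([cleanSpo2()]).
#' @param arousals n x 2 matrix of arousal intervals (seconds, half-open).
#' @param fs envelope sampling rate, Hz.
#' @param baselineWin baseline memory, seconds (100).
#' @param minDur minimum event duration, seconds (10).
#' @param desatWin post-event desaturation search window, seconds (45).
#' @param desatMin minimum qualifying desaturation, percent (3).
#' @return an [EventList-class] with evidence flags.
#' @export
detectEvents <- function(thermalEnv, nasalEnv, spo2Clean, arousals = NULL,
                         fs = 25, baselineWin = 100, minDur = 10,
                         desatWin = 45, desatMin = 3) {
  stopifnot(length(thermalEnv) == length(nasalEnv))
  if (length(thermalEnv) < 120 * fs) stop("traces shorter than 120 s")
  # decimate to 5 Hz for the sequential baseline logic; envelopes are smooth
  dec <- max(1, round(fs / 5))
  fsD <- fs / dec
  th <- thermalEnv[seq(1, length(thermalEnv), by = dec)]
  na_ <- nasalEnv[seq(1, length(nasalEnv), by = dec)]
  n <- length(th)
  K <- round(baselineWin * fsD)

  apneaC <- logical(n); suppT <- logical(n); hypoC <- logical(n)
  # prefix sums over the clean-sample buffer give O(1) rolling baselines
  csT <- numeric(n + 1); csN <- numeric(n + 1); m <- 0L
  for (i in seq_len(n)) {
    if (m == 0L) { bT <- th[i]; bN <- na_[i] } else {
      lo <- max(1L, m - K + 1L)
      bT <- (csT[m + 1L] - csT[lo]) / (m - lo + 1L)
      bN <- (csN[m + 1L] - csN[lo]) / (m - lo + 1L)
    }
    rT <- th[i] / max(bT, 1e-12)
    rN <- na_[i] / max(bN, 1e-12)
    apneaC[i] <- rT <= 0.10
    suppT[i] <- rT <= 0.70
    hypoC[i] <- rN <= 0.70
    if (rT > 0.7 && rN > 0.7) {  # unsuppressed breathing feeds the baseline
      m <- m + 1L
      csT[m + 1L] <- csT[m] + th[i]
      csN[m + 1L] <- csN[m] + na_[i]
    }
  }

  toSec <- function(runs) {
    if (nrow(runs) == 0) return(runs)
    data.frame(start = (runs$start - 1) / fsD, end = runs$end / fsD)
  }
  # deep cores (>= 4 s at <= 0.10) extended to the enclosing suppression span
  cores <- .runs(apneaC)
  cores <- cores[(cores$end - cores$start + 1) / fsD >= 4, , drop = FALSE]
  spans <- .runs(suppT)
  apneaIdx <- unique(vapply(seq_len(nrow(cores)), function(i) {
    which(spans$start <= cores$start[i] & spans$end >= cores$end[i])[1]
  }, integer(1)))
  apneaRuns <- toSec(spans[apneaIdx[!is.na(apneaIdx)], , drop = FALSE])
  apneaRuns <- apneaRuns[apneaRuns$end - apneaRuns$start >= minDur, , drop = FALSE]
  hypoRuns <- toSec(.runs(hypoC))
  hypoRuns <- hypoRuns[hypoRuns$end - hypoRuns$start >= minDur, , drop = FALSE]

  # apnea precedence: drop hypopnea candidates overlapping any apnea
  if (nrow(apneaRuns) > 0 && nrow(hypoRuns) > 0) {
    overlaps <- vapply(seq_len(nrow(hypoRuns)), function(i) {
      any(hypoRuns$start[i] < apneaRuns$end & hypoRuns$end[i] > apneaRuns$start)
    }, logical(1))
    hypoRuns <- hypoRuns[!overlaps, , drop = FALSE]
  }

  desatAt <- function(endS) {
    nS <- length(spo2Clean)
    pre <- spo2Clean[max(1, floor(endS) - baselineWin):min(nS, max(1, floor(endS)))]
    post <- spo2Clean[min(nS, floor(endS) + 1):min(nS, floor(endS + desatWin))]
    max(pre) - min(post) >= desatMin
  }
  arousalAt <- function(startS, endS) {
    if (is.null(arousals) || nrow(arousals) == 0) return(FALSE)
    any(arousals[, 1] < endS + 5 & arousals[, 2] > startS)
  }

  type <- character(0); st <- numeric(0); en <- numeric(0)
  dm <- logical(0); am <- logical(0)
  for (i in seq_len(nrow(apneaRuns))) {
    type <- c(type, "apnea"); st <- c(st, apneaRuns$start[i]); en <- c(en, apneaRuns$end[i])
    dm <- c(dm, desatAt(apneaRuns$end[i]))
    am <- c(am, arousalAt(apneaRuns$start[i], apneaRuns$end[i]))
  }
  for (i in seq_len(nrow(hypoRuns))) {
    d <- desatAt(hypoRuns$end[i]); a <- arousalAt(hypoRuns$start[i], hypoRuns$end[i])
    if (!d && !a) next  # 30 percent reduction alone does not score
    type <- c(type, "hypopnea"); st <- c(st, hypoRuns$start[i]); en <- c(en, hypoRuns$end[i])
    dm <- c(dm, d); am <- c(am, a)
  }
  EventList(type = type, start_s = st, end_s = en,
            desat_matched = dm, arousal_matched = am)
}

#' Hypoxic area of one event
#'
#' The event baseline is the maximum SpO2 in the 100 s before event end; the
#' search window is `[start, end + 45 s)`, clipped at the next event's start.
#' The area under the baseline (deficit clipped at zero) is integrated by
#' the trapezoid rule on the 1-Hz grid and reported in percent-minutes.
#'
#' @param spo2Clean cleaned 1-Hz SpO2 trace.
#' @param startS,endS event bounds, seconds.
#' @param nextEventStart start of the next event (any type), seconds;
#'   `Inf` for the last event.
#' @param baselineWin pre-termination baseline window, seconds (100).
#' @param postWin post-event extension, seconds (45).
#' @return hypoxic area, percent-minutes.
#' @export
eventHypoxicArea <- function(spo2Clean, startS, endS, nextEventStart = Inf,
                             baselineWin = 100, postWin = 45) {
  nS <- length(spo2Clean)
  times <- 0:(nS - 1)
  preIdx <- times >= endS - baselineWin & times < endS
  if (!any(preIdx)) preIdx <- times < endS
  baseline <- max(spo2Clean[preIdx])
  wEnd <- min(endS + postWin, nextEventStart)
  wIdx <- which(times >= startS & times < wEnd)
  if (length(wIdx) < 2) return(0)
  deficit <- pmax(0, baseline - spo2Clean[wIdx])
  pracma::trapz(times[wIdx], deficit) / 60
}

#' Hypoxic burden
#'
#' Sum of per-event hypoxic areas over the events passing the type filter,
#' divided by total sleep time: percent-minutes per hour. Windows are always
#' clipped at the next event of any type, so the apnea-specific and
#' hypopnea-specific burdens partition the total exactly.
#'
#' @param spo2Clean cleaned 1-Hz SpO2 trace.
#' @param events an [EventList-class].
#' @param tstH total sleep time, hours (> 0).
#' @param typeFilter `"all"`, `"apnea"`, or `"hypopnea"`.
#' @param usable SpO2 usability flag from [cleanSpo2()]; if `FALSE` the
#'   result is `NA` (night excluded from hypoxic-burden calculation).
#' @return hypoxic burden in percent-minutes per hour.
#' @export
hypoxicBurden <- function(spo2Clean, events, tstH,
                          typeFilter = c("all", "apnea", "hypopnea"),
                          usable = TRUE) {
  typeFilter <- match.arg(typeFilter)
  stopifnot(tstH > 0)
  if (!usable) return(NA_real_)
  ev <- eventTable(events)
  if (nrow(ev) == 0) return(0)
  nextStart <- c(ev$start_s[-1], Inf)
  areas <- vapply(seq_len(nrow(ev)), function(i) {
    eventHypoxicArea(spo2Clean, ev$start_s[i], ev$end_s[i], nextStart[i])
  }, numeric(1))
  keep <- if (typeFilter == "all") rep(TRUE, nrow(ev)) else ev$type == typeFilter
  sum(areas[keep]) / tstH
}

#' Annotate an EventList with per-event hypoxic areas
#'
#' @inheritParams hypoxicBurden
#' @return the [EventList-class] with `hypoxic_area` filled (percent-minutes).
#' @export
annotateHypoxicArea <- function(events, spo2Clean) {
  ev <- eventTable(events)
  if (nrow(ev) == 0) return(events)
  nextStart <- c(ev$start_s[-1], Inf)
  ev$hypoxic_area <- vapply(seq_len(nrow(ev)), function(i) {
    eventHypoxicArea(spo2Clean, ev$start_s[i], ev$end_s[i], nextStart[i])
  }, numeric(1))
  EventList(ev)
}

#' Oxygen desaturation episodes
#'
#' Episodes where SpO2 falls >= `desatMin` percent below the maximum of the
#' preceding 100 s, sustained >= 5 s; episodes separated by < 10 s merge.
#'
#' @param spo2Clean cleaned 1-Hz SpO2 trace.
#' @param desatMin qualifying fall, percent (3).
#' @param baselineWin preceding-maximum window, seconds (100).
#' @return data.frame of episode `start`/`end` times (seconds).
#' @keywords internal
.desatEpisodes <- function(spo2Clean, desatMin = 3, baselineWin = 100) {
  n <- length(spo2Clean)
  prevMax <- zoo::rollapplyr(zoo::zoo(spo2Clean),
                             width = list(-(baselineWin:1)), FUN = max,
                             partial = TRUE, fill = NA)
  prevMax <- as.numeric(prevMax)
  prevMax[1] <- spo2Clean[1]
  below <- spo2Clean <= prevMax - desatMin
  runs <- .runs(below)
  if (nrow(runs) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  runs <- data.frame(start = runs$start - 1, end = runs$end)  # seconds
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs) - 1) + 1) {
    if (runs$start[i] - merged$end[nrow(merged)] < 10) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged[merged$end - merged$start >= 5, , drop = FALSE]
}

#' Sleep and respiratory indices for one night
#'
#' Event counts per hour of total sleep time (AHI and its apnea/hypopnea
#' components), the arousal index, the oxygen desaturation index (>= 3
#' percent falls sustained >= 5 s), and total/apnea-specific/
#' hypopnea-specific hypoxic burden. `AHI = apnea index + hypopnea index`
#' and `total HB = apnea HB + hypopnea HB` hold exactly.
#'
#' @param events an [EventList-class].
#' @param arousals n x 2 matrix of arousal intervals.
#' @param spo2Clean cleaned 1-Hz SpO2 trace.
#' @param hypnogram the night's [Hypnogram-class] (defines TST).
#' @param spo2Usable usability flag from [cleanSpo2()].
#' @return a one-row data.frame of class `respiratory_indices` with columns
#'   `ahi, apnea_index, hypopnea_index, ai, odi, hb_total, hb_apnea,
#'   hb_hypopnea, tst_h, spo2_usable`.
#' @export
computeIndices <- function(events, arousals, spo2Clean, hypnogram,
                           spo2Usable = TRUE) {
  tstH <- totalSleepTime(hypnogram)
  if (tstH <= 0) stop("total sleep time must be positive")
  ev <- eventTable(events)
  nA <- sum(ev$type == "apnea"); nH <- sum(ev$type == "hypopnea")
  nAr <- if (is.null(arousals)) 0 else nrow(arousals)
  odi <- nrow(.desatEpisodes(spo2Clean)) / tstH
  hbT <- hypoxicBurden(spo2Clean, events, tstH, "all", usable = spo2Usable)
  hbA <- hypoxicBurden(spo2Clean, events, tstH, "apnea", usable = spo2Usable)
  hbH <- hypoxicBurden(spo2Clean, events, tstH, "hypopnea", usable = spo2Usable)
  out <- data.frame(ahi = (nA + nH) / tstH, apnea_index = nA / tstH,
                    hypopnea_index = nH / tstH, ai = nAr / tstH, odi = odi,
                    hb_total = hbT, hb_apnea = hbA, hb_hypopnea = hbH,
                    tst_h = tstH, spo2_usable = spo2Usable)
  class(out) <- c("respiratory_indices", "data.frame")
  out
}
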