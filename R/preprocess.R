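# Sleep-EEG preprocessing chain: contralateral mastoid referencing, sleep
# latency trimming, zero-phase low-pass filtering, reference-channel artifact
# regression, 5-SD spike interpolation, >30 percent bad-channel replacement,
# and per-channel z-scoring. Fixed step order; no randomness anywhere.

# Contralateral mastoid montage: left scalp referenced to the right mastoid
# and vice versa.
.REF_MAP <- c(F3 = "A2", C3 = "A2", O1 = "A2", F4 = "A1", C4 = "A1", O2 = "A1")
.HOMOLOGOUS <- list(F3 = "F4", F4 = "F3", C3 = "C4", C4 = "C3",
                    O1 = "O2", O2 = "O1")

#' Re-reference scalp EEG to the contralateral mastoid
#'
#' `F3-A2, C3-A2, O1-A2, F4-A1, C4-A1, O2-A1` (clinical PSG convention).
#'
#' @param eeg 8 x N matrix with rows `F3,F4,C3,C4,O1,O2,A1,A2`.
#' @return 6 x N matrix of referenced scalp channels.
#' @export
rereference <- function(eeg) {
  missing <- setdiff(EEG_CHANNELS, rownames(eeg))
  if (length(missing) > 0) {
    stop(sprintf("cannot re-reference: channel %s missing", missing[1]))
  }
  out <- matrix(0, length(SCALP_CHANNELS), ncol(eeg),
                dimnames = list(SCALP_CHANNELS, NULL))
  for (ch in SCALP_CHANNELS) out[ch, ] <- eeg[ch, ] - eeg[.REF_MAP[[ch]], ]
  out
}

#' Trim the sleep-latency interval from a PSG record
#'
#' Crops all signals to start at the first non-wake epoch and shifts every
#' annotation accordingly (annotations that end before sleep onset are
#' dropped; ones straddling it are clipped at zero).
#'
#' @param record a [PSGRecord-class].
#' @return the trimmed [PSGRecord-class].
#' @export
trimSleepLatency <- function(record) {
  st <- stages(record@hypnogram)
  onset <- which(st != "W")[1]
  if (is.na(onset)) stop("no sleep onset: hypnogram is all wake")
  if (onset == 1) return(record)
  tOff <- (onset - 1) * 30
  shift <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(m)
    m[, 1] <- m[, 1] - tOff; m[, 2] <- m[, 2] - tOff
    m <- m[m[, 2] > 0, , drop = FALSE]
    m[, 1] <- pmax(m[, 1], 0)
    m
  }
  arousals <- shift(record@arousals)
  events <- record@events
  if (!is.null(events) && length(events) > 0) {
    ev <- eventTable(events)
    ev$start_s <- ev$start_s - tOff; ev$end_s <- ev$end_s - tOff
    ev <- ev[ev$start_s >= 0, , drop = FALSE]
    events <- EventList(ev)
  }
  PSGRecord(subjectID = record@subjectID, visit = record@visit,
            eeg = record@eeg[, -(1:(tOff * record@fsEEG)), drop = FALSE],
            airflowThermal = record@airflowThermal[-(1:(tOff * record@fsAirflow))],
            airflowNasal = record@airflowNasal[-(1:(tOff * record@fsAirflow))],
            spo2 = record@spo2[-(1:tOff)],
            hypnogram = Hypnogram(st[-(1:(onset - 1))]),
            fsEEG = record@fsEEG, fsAirflow = record@fsAirflow,
            arousals = arousals, events = events, meta = record@meta)
}

#' Zero-phase low-pass filter at 50 Hz
#'
#' The band limit is 0-50 Hz; a 0 Hz lower edge is a no-op, so this is a pure
#' low-pass. Implemented as a linear-phase FIR (Hamming window, 101 taps at
#' 200 Hz) applied by FFT convolution with exact group-delay compensation,
#' hence zero phase. Stop-band attenuation exceeds 40 dB by 60 Hz.
#'
#' @param channel numeric vector.
#' @param fs sampling rate, Hz (> 100).
#' @param cutoff low-pass edge, Hz.
#' @return filtered vector, same length.
#' @export
bandlimit <- function(channel, fs = 200, cutoff = 50) {
  stopifnot(fs > 100)
  ord <- 100  # even: integer group delay of ord/2 samples
  b <- signal::fir1(ord, cutoff / (fs / 2), type = "low")
  b <- b / sum(b)  # exact unit gain at DC
  half <- ord / 2
  xp <- c(rep(channel[1], half), channel, rep(channel[length(channel)], ord - half))
  y <- signal::fftfilt(b, xp)
  y[(ord + 1):(ord + length(channel))]
}

#' Regress reference-channel artifacts out of an EEG channel
#'
#' Least-squares projection of the channel onto the span of the reference
#' signals (ECG/EOG); returns the residual. With no references the channel
#' is returned unchanged with a warning (the artifact-regression step is
#' then skipped).
#'
#' @param channel numeric vector.
#' @param refs numeric matrix with one reference signal per column (or a
#'   vector), time-aligned with `channel`; `NULL` to skip.
#' @return the cleaned channel.
#' @export
regressOutArtifacts <- function(channel, refs = NULL) {
  if (is.null(refs) || length(refs) == 0) {
    warning("no ECG/EOG reference channels supplied; artifact regression skipped")
    return(channel)
  }
  refs <- as.matrix(refs)
  stopifnot(nrow(refs) == length(channel))
  if (all(abs(refs) < .Machine$double.eps)) return(channel)
  qr.resid(qr(refs), channel)
}

#' Interpolate amplitude spikes beyond 5 standard deviations
#'
#' The mean and SD are computed once over the whole channel (single pass, no
#' re-estimation); samples with `|x - mean| > nSD * sd` are flagged and each
#' maximal flagged run is replaced by linear interpolation between its
#' nearest unflagged neighbours (nearest-value extension at the edges).
#' A zero-variance channel is returned unchanged with an empty mask.
#'
#' @param channel numeric vector (length >= 3).
#' @param nSD flagging threshold in SDs (default 5).
#' @return list with `channel` (repaired) and `mask` (logical flags).
#' @export
interpolateSpikes <- function(channel, nSD = 5) {
  stopifnot(length(channel) >= 3)
  mu <- mean(channel); sigma <- sd(channel)
  if (sigma == 0) return(list(channel = channel, mask = rep(FALSE, length(channel))))
  mask <- abs(channel - mu) > nSD * sigma
  if (!any(mask)) return(list(channel = channel, mask = mask))
  good <- which(!mask)
  if (length(good) == 0) return(list(channel = channel, mask = mask))
  repaired <- channel
  repaired[mask] <- approx(good, channel[good], xout = which(mask),
                           rule = 2)$y
  list(channel = repaired, mask = mask)
}

#' Replace bad channels with their homologous partner
#'
#' A referenced channel whose flagged-sample fraction exceeds `maxBadFrac`
#' is overwritten by its opposite-hemisphere homologue (F3 with F4, C3 with
#' C4, O1 with O2, and vice versa). If both channels of a pair exceed the
#' threshold the pair is unusable and an error is raised.
#'
#' @param eeg 6 x N referenced matrix (rows `F3,C3,O1,F4,C4,O2`).
#' @param masks named list of logical flag masks (one per channel), as
#'   produced by [interpolateSpikes()].
#' @param maxBadFrac replacement threshold on the flagged fraction (0.30).
#' @return list with `eeg` (repaired) and `replaced` (data.frame of
#'   (bad, donor) pairs).
#' @export
replaceBadChannels <- function(eeg, masks, maxBadFrac = 0.30) {
  fracs <- vapply(rownames(eeg), function(ch) mean(masks[[ch]]), numeric(1))
  bad <- names(fracs)[fracs > maxBadFrac]
  replaced <- data.frame(bad = character(0), donor = character(0))
  for (ch in bad) {
    donor <- .HOMOLOGOUS[[ch]]
    if (fracs[donor] > maxBadFrac) {
      stop(sprintf("pair unusable: both %s and %s exceed %.0f%% artifact data",
                   ch, donor, 100 * maxBadFrac))
    }
    eeg[ch, ] <- eeg[donor, ]
    replaced <- rbind(replaced, data.frame(bad = ch, donor = donor))
  }
  list(eeg = eeg, replaced = replaced)
}

#' Z-score a channel over the whole recording
#'
#' @param channel numeric vector with positive variance.
#' @return the standardized channel (mean 0, SD 1).
#' @export
zscoreChannel <- function(channel) {
  sigma <- sd(channel)
  if (!is.finite(sigma) || sigma == 0) stop("zero variance: cannot z-score channel")
  (channel - mean(channel)) / sigma
}

#' Run the full EEG preprocessing chain
#'
#' Applies, in fixed order: contralateral re-referencing, sleep-latency
#' trimming, zero-phase 0-50 Hz band limiting, ECG/EOG artifact regression
#' (skipped with a note when no reference channels exist), 5-SD spike
#' interpolation, >30 percent bad-channel replacement, and per-channel
#' z-scoring. Deterministic.
#'
#' @param record a [PSGRecord-class].
#' @param refs optional matrix of ECG/EOG reference channels (columns) at the
#'   EEG rate, covering the untrimmed recording.
#' @param nSD spike threshold in SDs.
#' @param maxBadFrac bad-channel threshold.
#' @return list with `eeg` (6 x N clean matrix), `hypnogram` (trimmed), and
#'   `report` (a `preprocess_report`: per-channel flagged fractions, channel
#'   replacements, overall interpolated fraction, ordered steps applied).
#' @export
preprocessPSG <- function(record, refs = NULL, nSD = 5, maxBadFrac = 0.30) {
  steps <- character(0)
  st <- stages(record@hypnogram)
  onset <- which(st != "W")[1]
  if (is.na(onset)) stop("no sleep onset: hypnogram is all wake")

  eeg <- rereference(record@eeg)
  steps <- c(steps, "rereference")
  trimmed <- trimSleepLatency(record)
  nTrim <- (onset - 1) * 30 * record@fsEEG
  if (nTrim > 0) eeg <- eeg[, -(1:nTrim), drop = FALSE]
  if (!is.null(refs)) refs <- as.matrix(refs)[(nTrim + 1):(nTrim + ncol(eeg)), , drop = FALSE]
  steps <- c(steps, "trim_sleep_latency")

  for (ch in rownames(eeg)) eeg[ch, ] <- bandlimit(eeg[ch, ], fs = record@fsEEG)
  steps <- c(steps, "bandlimit_0_50Hz")

  if (is.null(refs)) {
    steps <- c(steps, "artifact_regression_skipped_no_refs")
  } else {
    for (ch in rownames(eeg)) {
      eeg[ch, ] <- suppressWarnings(regressOutArtifacts(eeg[ch, ], refs))
    }
    steps <- c(steps, "artifact_regression")
  }

  masks <- list()
  for (ch in rownames(eeg)) {
    rep_ <- interpolateSpikes(eeg[ch, ], nSD = nSD)
    eeg[ch, ] <- rep_$channel
    masks[[ch]] <- rep_$mask
  }
  steps <- c(steps, "interpolate_spikes_5sd")

  rb <- replaceBadChannels(eeg, masks, maxBadFrac = maxBadFrac)
  eeg <- rb$eeg
  steps <- c(steps, "replace_bad_channels")

  for (ch in rownames(eeg)) eeg[ch, ] <- zscoreChannel(eeg[ch, ])
  steps <- c(steps, "zscore")

  fracs <- vapply(masks, mean, numeric(1))
  report <- structure(list(
    flagged_fraction = fracs,
    channels_replaced = rb$replaced,
    interpolated_fraction_overall = mean(unlist(masks)),
    steps_applied = steps), class = "preprocess_report")
  list(eeg = eeg, hypnogram = trimmed@hypnogram, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("EEG preprocessing report\n")
  cat("  steps:", paste(x$steps_applied, collapse = " -> "), "\n")
  cat(sprintf("  interpolated overall: %.3f%%\n", 100 * x$interpolated_fraction_overall))
  cat("  flagged fraction per channel:\n")
  print(round(x$flagged_fraction, 5))
  if (nrow(x$channels_replaced) > 0) {
    cat("  replaced:", paste(sprintf("%s<-%s", x$channels_replaced$bad,
                                     x$channels_replaced$donor), collapse = ", "), "\n")
  } else cat("  no channels replaced\n")
  invisible(x)
}
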