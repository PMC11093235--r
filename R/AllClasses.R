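#' Hypnogram: per-epoch sleep stages
#'
#' A sequence of 30-second sleep-stage epochs over the alphabet
#' `W, N1, N2, N3, REM`.
#'
#' @slot stages character vector, one stage code per 30-s epoch.
#' @slot epochLenS epoch length in seconds (fixed at 30).
#' @export
setClass("Hypnogram",
         representation(stages = "character", epochLenS = "numeric"),
         prototype(epochLenS = 30))

setValidity("Hypnogram", function(object) {
  if (length(object@stages) == 0) return("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(object@stages), STAGE_LEVELS)
  if (length(bad) > 0) {
    return(sprintf("unknown stage code(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "), paste(STAGE_LEVELS, collapse = ", ")))
  }
  if (!identical(object@epochLenS, 30)) return("epoch length must be 30 s")
  TRUE
})

#' Construct a Hypnogram
#'
#' @param stages character vector of stage codes (`W`, `N1`, `N2`, `N3`, `REM`),
#'   one per 30-s epoch.
#' @return A [Hypnogram-class] object.
#' @examples
#' Hypnogram(c("W", "W", "N1", "N2", "N2", "N3", "REM"))
#' @export
Hypnogram <- function(stages) {
  new("Hypnogram", stages = as.character(stages), epochLenS = 30)
}

#' EventList: typed respiratory events for one night
#'
#' Apnea/hypopnea intervals (half-open `[start_s, end_s)` seconds from
#' recording start) with linked desaturation/arousal evidence and, once
#' computed, the per-event hypoxic area in percent-minutes.
#'
#' @slot events data.frame with columns `type`, `start_s`, `end_s`,
#'   `desat_matched`, `arousal_matched`, `hypoxic_area`.
#' @export
setClass("EventList", representation(events = "data.frame"))

setValidity("EventList", function(object) {
  ev <- object@events
  need <- c("type", "start_s", "end_s", "desat_matched", "arousal_matched",
            "hypoxic_area")
  if (!all(need %in% names(ev))) {
    return(sprintf("events table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(ev) == 0) return(TRUE)
  if (!all(ev$type %in% c("apnea", "hypopnea"))) {
    return("event type must be 'apnea' or 'hypopnea'")
  }
  if (any(ev$end_s - ev$start_s < 10 - 1e-9)) {
    return("every respiratory event must last at least 10 s")
  }
  if (is.unsorted(ev$start_s)) return("events must be sorted by start time")
  for (ty in unique(ev$type)) {
    sub <- ev[ev$type == ty, ]
    if (nrow(sub) > 1 && any(sub$start_s[-1] < sub$end_s[-nrow(sub)] - 1e-9)) {
      return(sprintf("%s events overlap", ty))
    }
  }
  TRUE
})

#' Construct an EventList
#'
#' @param type character vector, `"apnea"` or `"hypopnea"`, or a data.frame
#'   already holding the event columns.
#' @param start_s,end_s numeric vectors of half-open event bounds in seconds.
#' @param desat_matched,arousal_matched logical evidence flags (default `NA`).
#' @param hypoxic_area per-event hypoxic area in %·min (default `NA`, filled
#'   by the hypoxic-burden stage).
#' @return An [EventList-class] object, sorted by start time.
#' @export
EventList <- function(type = character(), start_s = numeric(), end_s = numeric(),
                      desat_matched = NA, arousal_matched = NA,
                      hypoxic_area = NA_real_) {
  if (is.data.frame(type)) {
    ev <- type
    ev$desat_matched <- ev$desat_matched %||% NA
    ev$arousal_matched <- ev$arousal_matched %||% NA
    ev$hypoxic_area <- ev$hypoxic_area %||% NA_real_
  } else {
    n <- length(type)
    ev <- data.frame(type = as.character(type),
                     start_s = as.numeric(start_s),
                     end_s = as.numeric(end_s),
                     desat_matched = rep_len(desat_matched, n),
                     arousal_matched = rep_len(arousal_matched, n),
                     hypoxic_area = rep_len(as.numeric(hypoxic_area), n))
  }
  ev <- ev[order(ev$start_s), , drop = FALSE]
  rownames(ev) <- NULL
  new("EventList", events = ev)
}

#' PSGRecord: one night of polysomnography
#'
#' Multirate signal container for a single subject-visit: 8 EEG channels at a
#' common rate, two airflow sensors, a 1-Hz SpO2 trace, the hypnogram, arousal
#' annotations, optional scored respiratory events, and subject metadata.
#' All annotation intervals are half-open `[start, end)` seconds from
#' recording start.
#'
#' @slot subjectID subject identifier.
#' @slot visit `"baseline"` or `"followup"`.
#' @slot eeg 8 x N numeric matrix (rows `F3,F4,C3,C4,O1,O2,A1,A2`), volts.
#' @slot fsEEG EEG sampling rate in Hz (200 by convention).
#' @slot airflowThermal,airflowNasal airflow traces, arbitrary units.
#' @slot fsAirflow airflow sampling rate in Hz (>= 10).
#' @slot spo2 1-Hz oxygen saturation trace, percent in `[0, 100]`.
#' @slot hypnogram a [Hypnogram-class].
#' @slot arousals n x 2 matrix of `[start_s, end_s)` arousal intervals.
#' @slot events an [EventList-class] or `NULL`.
#' @slot meta named list (age, sex, bmi, ess, interval_years, group, ...).
#' @export
setClass("PSGRecord",
         representation(subjectID = "character", visit = "character",
                        eeg = "matrix", fsEEG = "numeric",
                        airflowThermal = "numeric", airflowNasal = "numeric",
                        fsAirflow = "numeric", spo2 = "numeric",
                        hypnogram = "Hypnogram", arousals = "matrix",
                        events = "ANY", meta = "list"))

setValidity("PSGRecord", function(object) {
  if (!object@visit %in% c("baseline", "followup")) {
    return("visit must be 'baseline' or 'followup'")
  }
  if (!identical(rownames(object@eeg), EEG_CHANNELS)) {
    return(sprintf("eeg rows must be exactly: %s", paste(EEG_CHANNELS, collapse = ", ")))
  }
  if (object@fsEEG <= 0 || object@fsAirflow <= 0) {
    return("sampling rates must be positive")
  }
  if (object@fsAirflow < 10) return("airflow sampling rate must be >= 10 Hz")
  if (any(object@spo2 < 0 | object@spo2 > 100)) {
    return("spo2 values must lie within [0, 100]")
  }
  durs <- c(eeg = ncol(object@eeg) / object@fsEEG,
            thermal = length(object@airflowThermal) / object@fsAirflow,
            nasal = length(object@airflowNasal) / object@fsAirflow,
            spo2 = length(object@spo2),
            hypnogram = length(object@hypnogram@stages) * 30)
  if (max(durs) - min(durs) > 30 + 1e-9) {
    return(sprintf("signal durations disagree by more than one 30-s epoch (%s)",
                   paste(sprintf("%s=%.1fs", names(durs), durs), collapse = ", ")))
  }
  ok <- .checkIntervals(object@arousals, "arousal")
  if (!isTRUE(ok)) return(ok)
  if (!is.null(object@events) && !is(object@events, "EventList")) {
    return("events must be an EventList or NULL")
  }
  TRUE
})

#' Construct a PSGRecord
#'
#' @param subjectID subject identifier string.
#' @param visit `"baseline"` or `"followup"`.
#' @param eeg 8 x N matrix with rownames `F3,F4,C3,C4,O1,O2,A1,A2` (volts).
#' @param airflowThermal,airflowNasal airflow traces (arbitrary units).
#' @param spo2 1-Hz SpO2 trace (percent).
#' @param hypnogram a [Hypnogram-class].
#' @param fsEEG,fsAirflow sampling rates in Hz.
#' @param arousals n x 2 matrix of half-open arousal intervals in seconds
#'   (default none).
#' @param events optional [EventList-class] of scored respiratory events.
#' @param meta named list of subject metadata.
#' @return A validated [PSGRecord-class].
#' @export
PSGRecord <- function(subjectID, visit, eeg, airflowThermal, airflowNasal,
                      spo2, hypnogram, fsEEG = 200, fsAirflow = 25,
                      arousals = NULL, events = NULL, meta = list()) {
  if (is.null(arousals) || length(arousals) == 0) {
    arousals <- matrix(numeric(0), ncol = 2)
  }
  arousals <- matrix(as.numeric(arousals), ncol = 2,
                     dimnames = list(NULL, c("start_s", "end_s")))
  new("PSGRecord", subjectID = as.character(subjectID), visit = visit,
      eeg = eeg, fsEEG = fsEEG, airflowThermal = as.numeric(airflowThermal),
      airflowNasal = as.numeric(airflowNasal), fsAirflow = fsAirflow,
      spo2 = as.numeric(spo2), hypnogram = hypnogram, arousals = arousals,
      events = events, meta = meta)
}

#' ModelInput: the fixed-shape brain-age model tensor
#'
#' The 2000 x 16 x 7 array fed to the brain-age regressor: six scalogram
#' channels (log10 Morlet power, 2000 time bins x 16 frequency bands) plus a
#' seventh channel holding the resampled sleep-stage vector broadcast across
#' the band axis (stage codes `W=0, N1=0.25, N2=0.5, N3=0.75, REM=1`).
#'
#' @slot tensor numeric array of dimension `c(2000, 16, 7)`.
#' @slot bandCentersHz the 16 ascending band-center frequencies in Hz.
#' @slot meta named list (chronological age, subject id, ground truth when
#'   generated synthetically).
#' @export
setClass("ModelInput",
         representation(tensor = "array", bandCentersHz = "numeric",
                        meta = "list"))

setValidity("ModelInput", function(object) {
  d <- dim(object@tensor)
  if (!identical(d, c(2000L, 16L, 7L))) {
    return(sprintf("tensor must be 2000 x 16 x 7 (got %s)", paste(d, collapse = " x ")))
  }
  if (any(!is.finite(object@tensor))) return("tensor must be finite")
  if (length(object@bandCentersHz) != 16 || is.unsorted(object@bandCentersHz, strictly = TRUE)) {
    return("bandCentersHz must be 16 strictly ascending values")
  }
  stage <- object@tensor[, , 7]
  if (max(abs(stage - stage[, 1])) > 1e-9) {
    return("stage channel must be constant across the band axis")
  }
  if (!all(vapply(stage[, 1], function(v) any(abs(v - STAGE_CODES) < 1e-9), logical(1)))) {
    return("stage channel values must be in {0, 0.25, 0.5, 0.75, 1}")
  }
  TRUE
})

#' BrainAgeModel: trainable brain-age regressor contract
#'
#' Three interchangeable kinds share one fit/predict contract:
#' `"ridge"` (default) — ridge regression on band-power summary features;
#' `"mlp"` — a single-hidden-layer perceptron on the same features;
#' `"oracle"` — returns the generator's ground-truth brain age plus seeded
#' Gaussian noise (test/pipeline-validation use only; requires ground-truth
#' metadata on the input).
#'
#' @slot kind one of `"ridge"`, `"mlp"`, `"oracle"`.
#' @slot fit fitted state (kind-specific).
#' @slot config hyperparameter list.
#' @slot seed training seed.
#' @slot trained logical.
#' @export
setClass("BrainAgeModel",
         representation(kind = "character", fit = "list", config = "list",
                        seed = "numeric", trained = "logical"),
         prototype(trained = FALSE))

setValidity("BrainAgeModel", function(object) {
  if (!object@kind %in% c("ridge", "mlp", "oracle")) {
    return("kind must be one of 'ridge', 'mlp', 'oracle'")
  }
  TRUE
})
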