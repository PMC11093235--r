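# Accessor generics and show methods for the core S4 containers.

#' @describeIn Hypnogram-class stage codes, one per epoch.
#' @param object,x object to access.
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @export
setMethod("stages", "Hypnogram", function(x) x@stages)

#' @describeIn Hypnogram-class number of 30-s epochs.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @export
setMethod("nEpochs", "Hypnogram", function(x) length(x@stages))

#' Recording / sleep durations
#'
#' `recordingDuration` is the hypnogram span in seconds; `totalSleepTime`
#' is the non-wake time in hours (the denominator of all per-hour indices).
#'
#' @param x a [Hypnogram-class] or [PSGRecord-class].
#' @return duration in seconds (`recordingDuration`) or hours
#'   (`totalSleepTime`).
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @export
setMethod("recordingDuration", "Hypnogram", function(x) length(x@stages) * x@epochLenS)

#' @export
setMethod("recordingDuration", "PSGRecord", function(x) recordingDuration(x@hypnogram))

#' @rdname recordingDuration
#' @export
setGeneric("totalSleepTime", function(x) standardGeneric("totalSleepTime"))

#' @export
setMethod("totalSleepTime", "Hypnogram", function(x) sum(x@stages != "W") * x@epochLenS / 3600)

#' @export
setMethod("totalSleepTime", "PSGRecord", function(x) totalSleepTime(x@hypnogram))

#' @describeIn PSGRecord-class the 8 x N EEG matrix in volts.
#' @param x a PSGRecord.
#' @export
setGeneric("eegSignals", function(x) standardGeneric("eegSignals"))

#' @export
setMethod("eegSignals", "PSGRecord", function(x) x@eeg)

#' @describeIn PSGRecord-class the 1-Hz SpO2 trace.
#' @export
setGeneric("spo2Trace", function(x) standardGeneric("spo2Trace"))

#' @export
setMethod("spo2Trace", "PSGRecord", function(x) x@spo2)

#' @describeIn PSGRecord-class the night's hypnogram.
#' @export
setGeneric("hypnogram", function(x) standardGeneric("hypnogram"))

#' @export
setMethod("hypnogram", "PSGRecord", function(x) x@hypnogram)

#' @describeIn PSGRecord-class arousal intervals (n x 2, seconds, half-open).
#' @export
setGeneric("arousalIntervals", function(x) standardGeneric("arousalIntervals"))

#' @export
setMethod("arousalIntervals", "PSGRecord", function(x) x@arousals)

#' @describeIn PSGRecord-class scored respiratory events ([EventList-class] or NULL).
#' @export
setGeneric("respiratoryEvents", function(x) standardGeneric("respiratoryEvents"))

#' @export
setMethod("respiratoryEvents", "PSGRecord", function(x) x@events)

#' @describeIn PSGRecord-class subject metadata list.
#' @export
setGeneric("psgMeta", function(x) standardGeneric("psgMeta"))

#' @export
setMethod("psgMeta", "PSGRecord", function(x) x@meta)

#' @describeIn EventList-class events as a data.frame.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @export
setMethod("eventTable", "EventList", function(x) x@events)

#' @export
setMethod("length", "EventList", function(x) nrow(x@events))

#' @describeIn ModelInput-class the 2000 x 16 x 7 array.
#' @export
setGeneric("inputTensor", function(x) standardGeneric("inputTensor"))

#' @export
setMethod("inputTensor", "ModelInput", function(x) x@tensor)

#' @export
setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@stages, levels = STAGE_LEVELS))
  cat(sprintf("Hypnogram: %d epochs (%.1f min), TST %.1f min\n",
              nEpochs(object), recordingDuration(object) / 60,
              totalSleepTime(object) * 60))
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
})

#' @export
setMethod("show", "PSGRecord", function(object) {
  cat(sprintf("PSGRecord: subject %s, %s visit\n", object@subjectID, object@visit))
  cat(sprintf("  EEG: 8 ch x %d samples @ %g Hz; airflow @ %g Hz; SpO2 @ 1 Hz\n",
              ncol(object@eeg), object@fsEEG, object@fsAirflow))
  cat(sprintf("  %d epochs, %d arousals, %s scored events\n",
              nEpochs(object@hypnogram), nrow(object@arousals),
              if (is.null(object@events)) "no" else length(object@events)))
})

#' @export
setMethod("show", "EventList", function(object) {
  ev <- object@events
  cat(sprintf("EventList: %d events (%d apnea, %d hypopnea)\n", nrow(ev),
              sum(ev$type == "apnea"), sum(ev$type == "hypopnea")))
  if (nrow(ev) > 0) print(utils::head(ev, 5))
})

#' @export
setMethod("show", "ModelInput", function(object) {
  cat("ModelInput: 2000 x 16 x 7 tensor\n")
  cat(sprintf("  bands %.2f-%.1f Hz; stage codes present: %s\n",
              min(object@bandCentersHz), max(object@bandCentersHz),
              paste(names(STAGE_CODES)[STAGE_CODES %in% unique(object@tensor[, 1, 7])],
                    collapse = ", ")))
})

#' @export
setMethod("show", "BrainAgeModel", function(object) {
  cat(sprintf("BrainAgeModel (kind = %s): %s\n", object@kind,
              if (object@trained) sprintf("trained (seed %d)", as.integer(object@seed))
              else "untrained"))
  if (object@trained && !is.null(object@fit$train_mae)) {
    cat(sprintf("  train MAE %.2f y, validation MAE %.2f y\n",
                object@fit$train_mae, object@fit$val_mae))
  }
})
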