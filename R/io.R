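# Readers/writers for the external formats the pipeline touches: EDF signals,
# sidecar CSVs (hypnogram, arousals, events), JSON metadata, and the subject
# feature table. All interval annotations are half-open [start, end) seconds
# from recording start.

FEATURE_TABLE_COLS <- c("subject_id", "group", FEATURES_CANONICAL,
                        "ess", "bmi", "interval_years",
                        "adherence_pct_days_4h", "adherence_mean_hours",
                        "bai_followup", "delta_bai", "annual_delta_bai")
FEATURE_TABLE_REQUIRED <- c("subject_id", "group", FEATURES_CANONICAL,
                            "ess", "bmi", "interval_years", "annual_delta_bai")

# Resolve an EDF label to a canonical EEG channel name, or NA.
# Handles case, an "EEG " prefix, mastoid aliases M1/M2, and reference
# suffixes such as "F3-A2" or "F3-REF". Anything unresolvable stays NA.
.canonicalChannel <- function(label) {
  s <- toupper(trimws(label))
  s <- sub("^EEG[ _]*", "", s)
  s <- sub("[-_](A1|A2|M1|M2|REF|LE)$", "", s)
  alias <- c(M1 = "A1", M2 = "A2")
  if (s %in% names(alias)) s <- alias[[s]]
  if (s %in% EEG_CHANNELS) s else NA_character_
}

.sidecar <- function(edfPath, suffix, ext = ".csv") {
  paste0(sub("\\.edf$", "", edfPath, ignore.case = TRUE), "_", suffix, ext)
}

#' Read a hypnogram CSV
#'
#' Expects columns `epoch` (0-based index) and `stage`
#' (`W`, `N1`, `N2`, `N3`, `REM`), one row per 30-s epoch in order.
#'
#' @param path CSV file path.
#' @return A [Hypnogram-class].
#' @export
readHypnogram <- function(path) {
  if (!file.exists(path)) stop(sprintf("hypnogram file not found: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, comment.char = "#"),
                 error = function(e) stop(sprintf("cannot parse hypnogram CSV %s: %s",
                                                  path, conditionMessage(e))))
  if (nrow(df) == 0) stop(sprintf("hypnogram file is empty: %s", path))
  if (!all(c("epoch", "stage") %in% names(df))) {
    stop("hypnogram CSV must have columns 'epoch' and 'stage'")
  }
  df <- df[order(df$epoch), ]
  Hypnogram(df$stage)
}

#' Write a hypnogram CSV
#'
#' @param hyp a [Hypnogram-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeHypnogram <- function(hyp, path) {
  stopifnot(is(hyp, "Hypnogram"))
  write.csv(data.frame(epoch = seq_along(hyp@stages) - 1L, stage = hyp@stages),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a PSGRecord to EDF plus sidecar files
#'
#' Signals go to plain EDF (16-bit, 1-s records, physical ranges covering each
#' signal's extrema). The hypnogram, arousals, scored events, and metadata are
#' written as diffable sidecars next to the EDF:
#' `<base>_hypnogram.csv`, `<base>_arousals.csv`, `<base>_events.csv`
#' (only if events are present), and `<base>_meta.json`.
#'
#' @param record a validated [PSGRecord-class].
#' @param edfPath output EDF path.
#' @return `edfPath`, invisibly.
#' @export
writePSG <- function(record, edfPath) {
  validObject(record)
  eeg <- record@eeg
  signals <- c(stats::setNames(lapply(EEG_CHANNELS, function(ch) eeg[ch, ]),
                               paste("EEG", EEG_CHANNELS)),
               list(`Flow Thermal` = record@airflowThermal,
                    `Flow Nasal` = record@airflowNasal,
                    `SpO2` = record@spo2))
  rates <- c(rep(record@fsEEG, 8), record@fsAirflow, record@fsAirflow, 1)
  units <- c(rep("V", 8), "au", "au", "%")
  writeEDF(edfPath, signals, rates, units,
           patientID = record@subjectID,
           recordingID = sprintf("Startdate X %s", record@visit))
  writeHypnogram(record@hypnogram, .sidecar(edfPath, "hypnogram"))
  write.csv(as.data.frame(record@arousals), .sidecar(edfPath, "arousals"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(record@events)) {
    write.csv(eventTable(record@events), .sidecar(edfPath, "events"),
              row.names = FALSE, quote = FALSE)
  }
  meta <- record@meta
  meta$visit <- record@visit
  meta$subject_id <- record@subjectID
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
             .sidecar(edfPath, "meta", ".json"))
  invisible(edfPath)
}

#' Read a PSGRecord from EDF plus sidecar files
#'
#' Channel labels are resolved case-insensitively to the canonical montage
#' (`F3, F4, C3, C4, O1, O2, A1, A2`), accepting common aliases (`M1/M2` for
#' the mastoids, `EEG ` prefixes, reference suffixes). A missing mandatory
#' channel is a fatal error naming that channel. Airflow channels are matched
#' on `therm` / `nasal|pres`, SpO2 on `spo2|sao2`.
#'
#' @param edfPath EDF file path.
#' @param hypnogramPath hypnogram CSV; defaults to the `_hypnogram.csv` sidecar.
#' @param arousalsPath,eventsPath,metaPath optional annotation sidecars;
#'   default to the matching sidecar path when that file exists.
#' @return A validated [PSGRecord-class]; `psgMeta(x)$provenance` records the
#'   source file and any label remapping performed.
#' @export
readPSG <- function(edfPath, hypnogramPath = NULL, arousalsPath = NULL,
                    eventsPath = NULL, metaPath = NULL) {
  edf <- readEDF(edfPath)
  labels <- names(edf$signals)
  canon <- vapply(labels, .canonicalChannel, character(1))
  remapped <- labels[!is.na(canon) & toupper(trimws(labels)) != canon]

  eegIdx <- stats::setNames(match(EEG_CHANNELS, canon), EEG_CHANNELS)
  missing <- EEG_CHANNELS[is.na(eegIdx)]
  if (length(missing) > 0) {
    stop(sprintf("channel %s not found in %s", missing[1], edfPath))
  }
  fsEEG <- unique(edf$rates[eegIdx])
  if (length(fsEEG) != 1) stop("EEG channels must share one sampling rate")
  eeg <- do.call(rbind, lapply(eegIdx, function(i) edf$signals[[i]]))
  rownames(eeg) <- EEG_CHANNELS

  up <- toupper(labels)
  thermIdx <- which(grepl("THERM", up))[1]
  nasalIdx <- which(grepl("NASAL|PRES", up))[1]
  spo2Idx <- which(grepl("SPO2|SAO2", up))[1]
  if (is.na(thermIdx)) stop(sprintf("channel Flow Thermal not found in %s", edfPath))
  if (is.na(nasalIdx)) stop(sprintf("channel Flow Nasal not found in %s", edfPath))
  if (is.na(spo2Idx)) stop(sprintf("channel SpO2 not found in %s", edfPath))

  hypnogramPath <- hypnogramPath %||% .sidecar(edfPath, "hypnogram")
  hyp <- readHypnogram(hypnogramPath)
  eegDur <- ncol(eeg) / fsEEG
  if (abs(eegDur - recordingDuration(hyp)) > 30 + 1e-9) {
    stop(sprintf("hypnogram (%.0f s) and EEG (%.0f s) durations differ by more than one epoch",
                 recordingDuration(hyp), eegDur))
  }

  defaultIf <- function(p, suffix, ext = ".csv") {
    if (!is.null(p)) return(p)
    cand <- .sidecar(edfPath, suffix, ext)
    if (file.exists(cand)) cand else NA_character_
  }
  arousalsPath <- defaultIf(arousalsPath, "arousals")
  arousals <- if (!is.na(arousalsPath)) {
    a <- read.csv(arousalsPath)
    if (nrow(a) > 0) as.matrix(a[, c("start_s", "end_s")]) else NULL
  } else NULL
  eventsPath <- defaultIf(eventsPath, "events")
  events <- if (!is.na(eventsPath)) {
    ev <- read.csv(eventsPath, stringsAsFactors = FALSE)
    if (nrow(ev) > 0) EventList(ev) else NULL
  } else NULL
  metaPath <- defaultIf(metaPath, "meta", ".json")
  meta <- if (!is.na(metaPath)) jsonlite::fromJSON(metaPath, simplifyVector = TRUE) else list()
  visit <- meta$visit %||% "baseline"
  subjectID <- as.character(meta$subject_id %||% trimws(edf$header$patientID))
  meta$visit <- NULL; meta$subject_id <- NULL
  meta$provenance <- list(source = edfPath, remapped_labels = remapped,
                          resampled = character(0))

  PSGRecord(subjectID = subjectID, visit = visit, eeg = eeg,
            airflowThermal = edf$signals[[thermIdx]],
            airflowNasal = edf$signals[[nasalIdx]],
            spo2 = .clamp(edf$signals[[spo2Idx]], 0, 100),
            hypnogram = hyp, fsEEG = fsEEG, fsAirflow = edf$rates[thermIdx],
            arousals = arousals, events = events, meta = meta)
}

#' Validate a subject feature table
#'
#' Checks the documented column set, absence of missing values in required
#' columns, `sex` coded 0/1 (male = 1), and `group` in
#' `{treated, untreated}`.
#'
#' @param table a data.frame of per-subject rows.
#' @return the table, invisibly, or an error describing the violation.
#' @export
validateFeatureTable <- function(table) {
  missingCols <- setdiff(FEATURE_TABLE_COLS, names(table))
  if (length(missingCols) > 0) {
    stop(sprintf("feature table missing column(s): %s", paste(missingCols, collapse = ", ")))
  }
  for (cc in FEATURE_TABLE_REQUIRED) {
    if (anyNA(table[[cc]])) stop(sprintf("feature table column '%s' contains missing values", cc))
  }
  if (!all(table$sex %in% c(0, 1))) stop("sex must be coded 0/1 (male = 1)")
  if (!all(table$group %in% c("treated", "untreated"))) {
    stop("group must be 'treated' or 'untreated'")
  }
  invisible(table)
}

#' Write / read the subject feature table
#'
#' CSV with a fixed, documented column order (see `somnage:::FEATURE_TABLE_COLS`);
#' a `#`-prefixed first line carries provenance and is skipped on read.
#' Round-trips exactly up to numeric printing at full precision.
#'
#' @param table validated feature table (one row per subject).
#' @param path CSV path.
#' @param provenance optional provenance list to embed in the header comment.
#' @return `path` (write) or the validated data.frame (read).
#' @export
writeFeatureTable <- function(table, path, provenance = NULL) {
  validateFeatureTable(table)
  table <- table[, FEATURE_TABLE_COLS]
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (!is.null(provenance)) {
    writeLines(paste0("# ", jsonlite::toJSON(provenance, auto_unbox = TRUE, digits = NA)), con)
  }
  write.csv(format(table, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature table not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  df$subject_id <- as.character(df$subject_id)
  validateFeatureTable(df)
  df
}
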