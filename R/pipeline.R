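# Orchestration: configuration handling and the end-to-end run on a
# simulated cohort (simulate -> preprocess -> scalogram -> brain age ->
# respiratory -> feature table -> statistics -> responder grid).

#' Default pipeline configuration
#'
#' All analysis constants at their documented defaults: 5-SD spike
#' threshold, 30 percent bad-channel threshold, 0-50 Hz band limit, 2000
#' time bins x 16 bands, 100-s hypoxic-burden baseline window, 45-s
#' post-event window, 60 percent SpO2 floor with 20 percent exclusion, the
#' two cohort presets, the default ridge brain-age model, and the standard
#' covariate set. Every field can be overridden via a YAML file
#' ([readPipelineConfig()]) or by editing the returned list.
#'
#' @param seed master seed for the run.
#' @return nested configuration list of class `pipeline_config`.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = list(n_treated = 24, n_untreated = 24,
                  tst_min = 10, latency_epochs = 2, artifact_rate = 0.5),
    preprocess = list(spike_sd = 5, bad_channel_frac = 0.30, lowpass_hz = 50),
    scalogram = list(n_bins = 2000, n_bands = 16,
                     band_lo_hz = 0.5, band_hi_hz = 48),
    hypoxic_burden = list(baseline_win_s = 100, post_win_s = 45,
                          spo2_floor = 60, max_low_frac = 0.20),
    model = list(kind = "ridge", sigma = 0.5),
    stats = list(covariates = c("sex", "age", "bmi", "ahi", "ai")),
    ml = list(min_n = 12, n_folds = 5))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file path.
#' @param seed master seed (overridden by a `seed` field in the file).
#' @return a `pipeline_config` list.
#' @export
readPipelineConfig <- function(path, seed = 1L) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig(seed)
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge2(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  cfg <- merge2(cfg, user)
  class(cfg) <- "pipeline_config"
  cfg
}

# Per-subject-visit processing: PSG -> clean EEG -> model input; respiratory
# analysis on the trimmed record. Returns model input + indices.
.processNight <- function(subject, visit, seed, cfg) {
  rec <- generatePSG(subject, visit = visit, seed = seed,
                     tstMin = cfg$cohort$tst_min,
                     latencyEpochs = cfg$cohort$latency_epochs,
                     artifactRate = cfg$cohort$artifact_rate)
  pp <- preprocessPSG(rec, nSD = cfg$preprocess$spike_sd,
                      maxBadFrac = cfg$preprocess$bad_channel_frac)
  trimmed <- trimSleepLatency(rec)
  input <- buildModelInput(pp$eeg, pp$hypnogram, fs = rec@fsEEG,
                           meta = c(psgMeta(rec), list(visit = visit)))
  cl <- cleanSpo2(spo2Trace(trimmed), floorPct = cfg$hypoxic_burden$spo2_floor,
                  maxLowFrac = cfg$hypoxic_burden$max_low_frac)
  thermEnv <- breathEnvelope(trimmed@airflowThermal, trimmed@fsAirflow)
  nasalEnv <- breathEnvelope(trimmed@airflowNasal, trimmed@fsAirflow)
  events <- detectEvents(thermEnv, nasalEnv, cl$spo2,
                         arousalIntervals(trimmed), fs = trimmed@fsAirflow)
  idx <- computeIndices(events, arousalIntervals(trimmed), cl$spo2,
                        hypnogram(trimmed), spo2Usable = cl$usable)
  list(input = input, indices = idx, record = rec)
}

#' Run the full analysis end to end on a simulated cohort
#'
#' Simulates treated and untreated cohorts, processes every subject's
#' baseline and follow-up nights through preprocessing and scalogram
#' construction, estimates brain age (training the configured regressor on
#' the baseline visits unless the oracle kind is configured), detects
#' respiratory events and computes indices, assembles the feature table,
#' runs the longitudinal statistics, and — when the treated cohort is large
#' enough — the responder prediction grid. Every output file carries a
#' provenance block (package version, config hash, seed).
#'
#' @param config a `pipeline_config` (default [defaultPipelineConfig()]).
#' @param outDir output directory; created if missing. `NULL` skips writing.
#' @return list with `features` (the feature table), `stats`, `grid` (or
#'   `NULL`), and `provenance`; written as `feature_table.csv`,
#'   `stats.json`, `responder_grid.csv`, `provenance.json` under `outDir`.
#' @export
runEndToEnd <- function(config = defaultPipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  prov <- .provenance(config, seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cohorts <- stage("simulate", {
    rbind(generateCohort(cohortConfig("smc_treated",
                                      nSubjects = config$cohort$n_treated,
                                      seed = .deriveSeed(seed, 1))),
          generateCohort(cohortConfig("smc_untreated",
                                      nSubjects = config$cohort$n_untreated,
                                      seed = .deriveSeed(seed, 2))))
  })

  nights <- stage("preprocess+scalogram+respiratory", {
    lapply(seq_len(nrow(cohorts)), function(i) {
      sub <- cohorts[i, ]
      list(baseline = .processNight(sub, "baseline", .deriveSeed(seed, 10 + 2 * i), config),
           followup = .processNight(sub, "followup", .deriveSeed(seed, 11 + 2 * i), config))
    })
  })

  model <- stage("brainage", {
    if (config$model$kind == "oracle") {
      fitBrainAge(list(kind = "oracle", sigma = config$model$sigma),
                  seed = .deriveSeed(seed, 3))
    } else {
      fitBrainAge(list(kind = config$model$kind),
                  inputs = lapply(nights, function(nn) nn$baseline$input),
                  ages = cohorts$age, seed = .deriveSeed(seed, 3))
    }
  })

  features <- stage("features", {
    rows <- lapply(seq_len(nrow(cohorts)), function(i) {
      sub <- cohorts[i, ]
      nn <- nights[[i]]
      predB <- predictAge(model, nn$baseline$input)
      predF <- predictAge(model, nn$followup$input)
      baiB <- computeBAI(predB, sub$age)
      baiF <- computeBAI(predF, sub$age + sub$interval_years)
      idx <- nn$baseline$indices
      data.frame(subject_id = sub$subject_id, group = sub$group,
                 bai = baiB, age = sub$age, sex = sub$sex,
                 ai = idx$ai, ahi = idx$ahi, apnea_index = idx$apnea_index,
                 hypopnea_index = idx$hypopnea_index, odi = idx$odi,
                 hb_total = idx$hb_total, hb_apnea = idx$hb_apnea,
                 hb_hypopnea = idx$hb_hypopnea,
                 ess = sub$ess, bmi = sub$bmi,
                 interval_years = sub$interval_years,
                 adherence_pct_days_4h = sub$adherence_pct_days_4h,
                 adherence_mean_hours = sub$adherence_mean_hours,
                 bai_followup = baiF, delta_bai = baiF - baiB,
                 annual_delta_bai = annualDeltaBAI(baiB, baiF, sub$interval_years))
    })
    validateFeatureTable(do.call(rbind, rows))
  })

  statsOut <- stage("stats", {
    treated <- features[features$group == "treated", ]
    untreated <- features[features$group == "untreated", ]
    list(paired_treated = pairedTTest(treated$bai, treated$bai_followup),
         paired_untreated = pairedTTest(untreated$bai, untreated$bai_followup),
         adjusted_annual = adjustedGroupComparison(features, "annual_delta_bai",
                                                   config$stats$covariates),
         adjusted_delta = adjustedGroupComparison(features, "delta_bai",
                                                  config$stats$covariates),
         scan_untreated = as.list(associationScan(untreated)),
         scan_treated = as.list(associationScan(treated)))
  })

  grid <- NULL
  treated <- features[features$group == "treated", ]
  if (nrow(treated) >= config$ml$min_n) {
    grid <- stage("responder", {
      lab <- medianSplit(treated$annual_delta_bai)
      evaluateGrid(treated[, FEATURES_CANONICAL], lab$labels,
                   seed = .deriveSeed(seed, 4), nFolds = config$ml$n_folds)
    })
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureTable(features, file.path(outDir, "feature_table.csv"),
                      provenance = prov)
    jsonlite::write_json(c(list(provenance = prov), statsOut),
                         file.path(outDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(grid)) {
      con <- file(file.path(outDir, "responder_grid.csv"), "w")
      writeLines(paste0("# ", jsonlite::toJSON(prov, auto_unbox = TRUE)), con)
      write.csv(as.data.frame(grid), con, row.names = FALSE)
      close(con)
    }
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(features = features, stats = statsOut, grid = grid, provenance = prov)
}
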