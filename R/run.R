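#' Default run configuration
#'
#' All stage parameters of the pipeline in one serializable list, suitable
#' for writing to YAML and hashing into the run manifest. Every design knob
#' is here: simulation layout and heart-period model, filter settings,
#' ectopic-correction rule, feature conventions, normalization basis and
#' statistical family.
#'
#' @param seed master seed.
#' @return Nested list of configuration blocks.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      nPerGroup = list(HC = 17L, MCS = 5L, UWS = 6L),
      groupEffectScale = list(HC = 1, MCS = 0, UWS = 0),
      model = list(m0 = 850, aLF = 20, aHF = 25, fLF = 0.1, fHF = 0.25,
                   sigma = 10,
                   delta = list(acquaintance = 25, stranger = 0)),
      withECG = FALSE, fs = 256,
      noise = list(wanderAmp = 0.2, wanderFreq = 0.25, mainsAmp = 0.05,
                   whiteSd = 0.05),
      ectopicFraction = 0),
    resample = list(targetFs = 256),
    highpass = list(order = 5L, fc = 0.5),
    notch = list(f0 = 50, q = 30),
    ectopic = list(maxFraction = 0.20, tol = 0.2, k = 5L),
    features = list(madConstant = 1.4826),
    normalize = list(madConstant = 1, madFloor = 1e-9),
    stats = list(unit = "window", mFamily = 12L, alpha = 0.05)
  )
}

#' @rdname defaultRunConfig
#' @param path YAML file with any subset of the configuration keys; missing
#'   keys fall back to the defaults.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopConfig("config file %s does not exist", path)
  user <- yaml::read_yaml(path)
  mergeIn <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        mergeIn(base[[k]], upd[[k]]) else upd[[k]]
    }
    base
  }
  cfg <- mergeIn(defaultRunConfig(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

configToSpec <- function(config) {
  sim <- config$simulate
  model <- new("HeartPeriodModel",
               m0 = sim$model$m0, aLF = sim$model$aLF, aHF = sim$model$aHF,
               fLF = sim$model$fLF, fHF = sim$model$fHF,
               sigma = sim$model$sigma,
               delta = unlist(sim$model$delta))
  cohortSpec(nPerGroup = unlist(sim$nPerGroup),
             groupEffectScale = unlist(sim$groupEffectScale),
             model = model, seed = config$seed,
             withECG = isTRUE(sim$withECG), fs = sim$fs, noise = sim$noise,
             ectopicFraction = sim$ectopicFraction)
}

writeManifest <- function(config, outDir, extra = list()) {
  manifest <- c(list(configHash = configHash(config), seed = config$seed,
                     config = config),
                extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a synthetic cohort to disk
#'
#' Generates the cohort described by the configuration's `simulate` block and
#' writes, per subject, the protocol (JSON), the beat series (CSV) and, when
#' `withECG` is set, the waveform (CSV), plus a run manifest with the config
#' hash and seed. Identical configuration and seed give identical files.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param outDir output directory (created if missing).
#' @return Invisibly, the subject index data.frame.
#' @export
runSimulation <- function(config = defaultRunConfig(), outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  cohort <- generateCohort(configToSpec(config))
  idx <- data.frame(id = character(0), group = character(0),
                    protocol = character(0), beats = character(0),
                    ecg = character(0), stringsAsFactors = FALSE)
  for (subj in cohort) {
    pPath <- file.path(outDir, sprintf("%s_protocol.json", subj$id))
    bPath <- file.path(outDir, sprintf("%s_beats.csv", subj$id))
    writeProtocol(subj$protocol, pPath, format = "json")
    writeBeatsCSV(subj$beats, bPath)
    ePath <- ""
    if (!is.null(subj$ecg)) {
      ePath <- file.path(outDir, sprintf("%s_ecg.csv", subj$id))
      writeECGCSV(subj$ecg, ePath)
    }
    idx <- rbind(idx, data.frame(id = subj$id, group = subj$group,
                                 protocol = basename(pPath),
                                 beats = basename(bPath),
                                 ecg = basename(ePath),
                                 stringsAsFactors = FALSE))
  }
  utils::write.csv(idx, file.path(outDir, "subjects.csv"), row.names = FALSE)
  writeManifest(config, outDir, list(nSubjects = nrow(idx)))
  invisible(idx)
}

#' Preprocess one ECG record into a corrected beat series
#'
#' The full waveform chain under one configuration: resample to the target
#' rate, Butterworth high-pass, notch, Pan-Tompkins detection, ectopic
#' correction under the rejection rule.
#'
#' @param record an [ECGRecord-class].
#' @param config configuration list.
#' @return A corrected [BeatSeries-class].
#' @export
preprocessECG <- function(record, config = defaultRunConfig()) {
  record <- resampleECG(record, targetFs = config$resample$targetFs)
  record <- highpassECG(record, order = config$highpass$order,
                        fc = config$highpass$fc)
  record <- notchECG(record, f0 = config$notch$f0, q = config$notch$q)
  beats <- detectRPeaks(record)
  correctEctopics(beats, maxFraction = config$ectopic$maxFraction,
                  k = config$ectopic$k, tol = config$ectopic$tol)
}

readCohortDir <- function(cohortDir, config) {
  idxPath <- file.path(cohortDir, "subjects.csv")
  if (!file.exists(idxPath))
    stopData("no subjects.csv in %s", cohortDir)
  idx <- utils::read.csv(idxPath, stringsAsFactors = FALSE)
  subjects <- list(); exclusions <- list()
  for (i in seq_len(nrow(idx))) {
    rec <- tryCatch({
      protocol <- readProtocol(file.path(cohortDir, idx$protocol[i]))
      beats <- if (!is.na(idx$ecg[i]) && nzchar(idx$ecg[i])) {
        preprocessECG(readECGCSV(file.path(cohortDir, idx$ecg[i])), config)
      } else {
        readBeatsCSV(file.path(cohortDir, idx$beats[i]))
      }
      list(id = idx$id[i], group = idx$group[i], protocol = protocol,
           beats = beats)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      exclusions[[idx$id[i]]] <- data.frame(
        subject_id = idx$id[i],
        reason = if (inherits(rec, "uncorrectableSeries"))
          "uncorrectable-series" else "unreadable-subject",
        detail = conditionMessage(rec), stringsAsFactors = FALSE)
    } else {
      subjects[[idx$id[i]]] <- rec
    }
  }
  list(subjects = subjects,
       exclusions = if (length(exclusions)) do.call(rbind, exclusions)
                    else data.frame())
}

#' Analyze a cohort directory end to end
#'
#' Reads every subject (preprocessing waveforms when present), extracts and
#' normalizes features, runs all comparisons, and writes the normalized long
#' table, condition means, full comparison statistics, the contrast-by-feature
#' results matrix, an exclusion log and a run manifest. Unreadable or
#' uncorrectable subjects are excluded with a logged reason and the run
#' continues.
#'
#' @param config configuration list.
#' @param cohortDir directory produced by [runSimulation()] (or hand-built
#'   with the same layout).
#' @param outDir output directory.
#' @return Invisibly, a list with `comparisons`, `resultsMatrix`,
#'   `cohortResult`, `exclusions`.
#' @export
runAnalysis <- function(config = defaultRunConfig(), cohortDir, outDir) {
  if (!dir.exists(cohortDir)) stopConfig("cohort dir %s missing", cohortDir)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  loaded <- readCohortDir(cohortDir, config)
  res <- runCohort(loaded$subjects,
                   madFloor = config$normalize$madFloor,
                   madConstant = config$normalize$madConstant)
  cmp <- compareCohort(res, unit = config$stats$unit,
                       mFamily = config$stats$mFamily,
                       alpha = config$stats$alpha)
  mat <- buildResultsTable(cmp)
  utils::write.csv(res$normalized, file.path(outDir, "normalized.csv"),
                   row.names = FALSE)
  utils::write.csv(res$conditionMeans,
                   file.path(outDir, "condition_means.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp, file.path(outDir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(mat),
                   file.path(outDir, "results_matrix.csv"))
  excl <- loaded$exclusions
  if (nrow(res$exclusions)) {
    we <- res$exclusions
    we$detail <- sprintf("window %s / %s", we$windowId, we$feature)
    we <- data.frame(subject_id = we$subject_id, reason = we$reason,
                     detail = we$detail, stringsAsFactors = FALSE)
    excl <- if (nrow(excl)) rbind(excl, we) else we
  }
  utils::write.csv(excl, file.path(outDir, "exclusions.csv"),
                   row.names = FALSE)
  writeManifest(config, outDir,
                list(nSubjects = length(loaded$subjects),
                     nExcludedSubjects = sum(excl$reason %in%
                       c("unreadable-subject", "uncorrectable-series"))))
  invisible(list(comparisons = cmp, resultsMatrix = mat, cohortResult = res,
                 exclusions = excl))
}
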