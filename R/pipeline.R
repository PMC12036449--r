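.presets <- list(
  smoke = list(nPatients = 2L, nTrials = 100L, nPerm = 100L,
               channels = c(dmPFC = 1L, dlPFC = 1L)),
  desk = list(nPatients = 6L, nTrials = 300L, nPerm = 1000L,
              channels = c(dmPFC = 4L, dlPFC = 8L)),
  full = list(nPatients = 14L, nTrials = 500L, nPerm = 5000L,
              channels = c(dmPFC = 6L, dlPFC = 14L))
)

.allowedAnalyses <- c("model_comparison", "feedback_tfr", "coupling")

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list; applies the scale preset, fills
#' defaults (sampling rate 500 Hz, three-arm environment, VKF generating
#' agent) and checks fields, collecting all violations into one error.
#'
#' @param config path to a YAML file or a configuration list
#' @return normalized list of class \code{"PipelineConfig"}
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  errs <- character()
  preset <- config$preset %||% "smoke"
  if (!preset %in% names(.presets))
    errs <- c(errs, paste0("unknown preset '", preset, "' (allowed: ",
                           paste(names(.presets), collapse = ", "), ")"))
  base <- .presets[[preset]] %||% .presets$smoke
  cfg <- list(
    preset = preset,
    seed = as.integer(config$seed %||% 1L),
    fs = config$fs %||% 500,
    nPatients = as.integer(config$nPatients %||% base$nPatients),
    nTrials = as.integer(config$nTrials %||% base$nTrials),
    nPerm = as.integer(config$nPerm %||% base$nPerm),
    channels = unlist(config$channels %||% base$channels),
    agent = config$agent %||% list(learner = "VKF",
                                   choiceRule = "value_and_uncertainty",
                                   useRelative = TRUE,
                                   params = list(lambda = 0.2, v0 = 0.5,
                                                 omega = 0.5, betaV = 8,
                                                 betaU = 2)),
    effects = config$effects %||% list(
      list(region = "dmPFC", band = c(4, 9), regressor = "reward",
           slope = 0.5, stage = "post_feedback", amp = 0.8)),
    pac = config$pac %||% list(phaseRegion = "dlPFC", ampRegion = "dmPFC",
                               phaseFreq = 8, ampFreq = 110, depth = 0.6,
                               stage = "pre_selection", amp0 = 0.5,
                               slowAmp = 0.8),
    aac = config$aac %||% list(regionA = "dlPFC", regionB = "dmPFC",
                               band = c(4, 9), targetR = 0.5,
                               stage = "post_feedback", amp = 0.8),
    analyses = unlist(config$analyses %||% .allowedAnalyses)
  )
  if (cfg$nTrials < 10) errs <- c(errs, "nTrials must be >= 10")
  if (cfg$nPatients < 2) errs <- c(errs, "nPatients must be >= 2")
  if (cfg$fs <= 0) errs <- c(errs, "fs must be positive")
  bad <- setdiff(cfg$analyses, .allowedAnalyses)
  if (length(bad))
    errs <- c(errs, paste0("unknown analysis '", paste(bad, collapse = "', '"),
                           "' (allowed: ",
                           paste(.allowedAnalyses, collapse = ", "), ")"))
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "))
  class(cfg) <- "PipelineConfig"
  cfg
}

.logLine <- function(con, stage, seed, note = "") {
  writeLines(jsonlite::toJSON(list(stage = stage, seed = seed, note = note),
                              auto_unbox = TRUE), con)
}

#' Run the full synthetic study
#'
#' Executes the stages in dependency order: behavioral simulation, model
#' fitting and comparison, synthetic neural generation, spectral and
#' coupling analyses, group statistics, and a JSON summary comparing
#' detected effects against the injected ground truth. One global seed fans
#' out deterministically to per-stage seeds.
#'
#' @param config a \code{\link{validateConfig}} result (or anything it
#'   accepts)
#' @param outDir output directory (created if needed)
#' @return the summary list, invisibly; artifacts are written to
#'   \code{outDir}
#' @export
runPipeline <- function(config, outDir = tempfile("nbrun")) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(outDir, "log.jsonl"), "w")
  on.exit(close(logCon))
  summary <- list(preset = cfg$preset, seed = cfg$seed)

  # stage 1: behavior
  agentSpec <- modelSpec(cfg$agent$learner, cfg$agent$choiceRule,
                         isTRUE(cfg$agent$useRelative))
  behavior <- lapply(seq_len(cfg$nPatients), function(i) {
    bc <- banditConfig(nTrials = cfg$nTrials, seed = cfg$seed + 100L * i)
    sess <- simulateAgent(bc, agentSpec, cfg$agent$params,
                          seed = cfg$seed + 100L * i + 1L)
    list(session = sess,
         trajectory = sessionTrajectory(sess, agentSpec, cfg$agent$params))
  })
  .logLine(logCon, "behavior", cfg$seed)
  dir.create(file.path(outDir, "sessions"), showWarnings = FALSE)
  for (i in seq_along(behavior))
    writeSessionCsv(behavior[[i]]$session,
                    file.path(outDir, "sessions",
                              sprintf("P%02d.csv", i)))
  summary$behavior <- list(
    nPatients = cfg$nPatients, nTrials = cfg$nTrials,
    winStay = round(mean(vapply(behavior, function(b)
      winStay(b$session), 0)), 4),
    loseShift = round(mean(vapply(behavior, function(b)
      loseShift(b$session), 0)), 4))

  # stage 2: model comparison
  if ("model_comparison" %in% cfg$analyses) {
    sessions <- lapply(behavior, `[[`, "session")
    grid <- list(modelSpec("RW1", "value_only", FALSE),
                 modelSpec("KF", "value_only", TRUE),
                 modelSpec("VKF", "value_and_uncertainty", TRUE))
    gf <- hierarchicalFit(sessions, grid, maxIter = 3, nStarts = 2,
                          seed = cfg$seed + 11L)
    .logLine(logCon, "model_comparison", cfg$seed + 11L)
    summary$modelComparison <- list(
      models = vapply(grid, function(s)
        paste0(s@learner, "/", s@choiceRule), ""),
      xp = round(unname(gf$xp), 4),
      sumLogEv = round(colSums(gf$logEvidence), 2))
  }

  # stage 3: synthetic neural data
  rspec <- recordingSpec(fs = cfg$fs, channels = cfg$channels,
                         effects = cfg$effects, pac = cfg$pac,
                         aac = cfg$aac, seed = cfg$seed + 23L)
  ds <- generateDataset(behavior, rspec)
  write.csv(ds$events, file.path(outDir, "events.csv"), row.names = FALSE)
  .logLine(logCon, "neural", cfg$seed + 23L)

  # stage 4: time-frequency group statistics
  if ("feedback_tfr" %in% cfg$analyses) {
    freqs <- logFreqGrid(4, min(150, cfg$fs / 2 - 10), 30)
    maps <- lapply(seq_len(cfg$nPatients), function(i) {
      rec <- patientRecording(ds, i)
      epochRecording(rec, "dmPFC", "tfr", window = c(-0.5, 2),
                     align = "feedback", freqs = freqs,
                     channels = 1L, decimate = 10L)
    })
    tfmap <- new("TFMap",
                 power = array(unlist(lapply(maps, function(m) m@power)),
                               c(dim(maps[[1]]@power)[1:2],
                                 sum(vapply(maps, nTrials, 0L)))),
                 phase = array(0, c(0, 0, 0)), times = maps[[1]]@times,
                 freqs = maps[[1]]@freqs,
                 events = do.call(rbind, lapply(maps, trialEvents)))
    cl <- clusterPermutation2d(tfmap, c("reward", "prev_feedback"),
                               term = "reward", nPerm = cfg$nPerm,
                               seed = cfg$seed + 31L)
    .logLine(logCon, "feedback_tfr", cfg$seed + 31L)
    summary$feedbackTfr <- list(
      nClusters = nrow(cl$clusters),
      nSignificant = sum(cl$clusters$significant),
      maxStat = if (nrow(cl$clusters)) round(max(cl$clusters$stat), 1) else 0,
      truthInjected = length(cfg$effects) > 0)
  }

  # stage 5: coupling
  if ("coupling" %in% cfg$analyses) {
    tabs <- lapply(seq_len(cfg$nPatients), function(i)
      couplingTable(patientRecording(ds, i),
                    pacPair = c(cfg$pac$phaseFreq, cfg$pac$ampFreq),
                    nPerm = min(cfg$nPerm, 200L), seed = cfg$seed + 41L + i))
    tab <- do.call(rbind, tabs)
    write.csv(tab, file.path(outDir, "coupling.csv"), row.names = FALSE)
    sc <- couplingStageContrast(tab, "aac_theta_theta")
    dp <- tryCatch(couplingDecisionPrediction(tab, "pac_z", "pre_selection"),
                   error = function(e) NULL)
    .logLine(logCon, "coupling", cfg$seed + 41L)
    summary$coupling <- list(
      aacStageT = round(sc$t[1], 3),
      pacDecisionT = if (!is.null(dp)) round(dp$t[1], 3) else NA)
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
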