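SESSION_SCHEMA_VERSION <- 1L

#' Write a session to a plain-text container
#'
#' The container is a directory holding \code{events.csv} (trial_id,
#' electrode_id, unit_id, time_ms), \code{trials.csv} (trial_id, condition,
#' task_id, correct, session_id) and \code{meta.yaml} (schema version,
#' recording window, bin resolution, seed).
#'
#' @param session a \linkS4class{SessionData}
#' @param path directory to create/overwrite
#' @return \code{path}, invisibly
#' @export
writeSession <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(session@events, file.path(path, "events.csv"), row.names = FALSE)
  write.csv(session@trials, file.path(path, "trials.csv"), row.names = FALSE)
  meta <- list(schema_version = SESSION_SCHEMA_VERSION,
               window_ms = as.numeric(session@windowMs),
               bin_ms = as.numeric(session@binMs),
               n_electrodes = nElectrodes(session),
               seed = session@meta$seed %||% NA)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a session from a plain-text container
#'
#' Validates referential integrity (every event's trial id exists in the
#' trial table) and time bounds; violations raise errors naming the
#' offending ids. A session with an empty trial table is valid but warned
#' about.
#'
#' @param path directory written by \code{\link{writeSession}}
#' @return a \linkS4class{SessionData}
#' @export
readSession <- function(path) {
  metaFile <- file.path(path, "meta.yaml")
  if (!file.exists(metaFile)) stop("not a session container: missing meta.yaml")
  meta <- yaml::read_yaml(metaFile)
  if (is.null(meta$schema_version) ||
      meta$schema_version != SESSION_SCHEMA_VERSION)
    stop(sprintf("unknown session schema version: %s",
                 as.character(meta$schema_version %||% "missing")))
  events <- read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  trials <- read.csv(file.path(path, "trials.csv"), stringsAsFactors = FALSE)
  if (nrow(trials) == 0L) warning("session has no trials")
  orphan <- setdiff(unique(events$trial_id), trials$trial_id)
  if (length(orphan))
    stop(sprintf("events reference missing trial ids: %s",
                 paste(head(orphan, 5L), collapse = ", ")))
  win <- as.numeric(unlist(meta$window_ms))
  bad <- events$time_ms < win[1] | events$time_ms >= win[2]
  if (any(bad))
    stop(sprintf("%d event times outside the recording window [%g, %g)",
                 sum(bad), win[1], win[2]))
  new("SessionData", events = events, trials = trials, windowMs = win,
      binMs = as.numeric(meta$bin_ms),
      meta = list(nElectrodes = as.integer(meta$n_electrodes),
                  seed = meta$seed))
}

#' Analysis run configuration
#'
#' Collects the tunable parameters of every stage with their standard
#' values: 200/50-ms sliding windows, 20-trial batches, 15 training batches
#' per condition, 0.01 sp tuning floor, 25-ms jitter with 3 rounds and the
#' 7-SD rule, 20 cross-validation folds with 200 iterations. The config is
#' serialized verbatim into every output's metadata.
#'
#' @param epochs an \code{\link{epochSpec}}
#' @param batchSize,windowWidth,windowStep,trainPerCondition,repetitions,floor
#'   decoding parameters
#' @param jitterMs,jitterRounds,sdMultiplier,maxLag connectivity parameters
#' @param folds,cmiIters CMI cross-validation parameters
#' @param seed integer seed
#' @param outDir output directory for \code{\link{runPipeline}}
#' @return a classed list
#' @export
runConfig <- function(epochs = epochSpec(), batchSize = 20,
                      windowWidth = 200, windowStep = 50,
                      trainPerCondition = 15, repetitions = 1000,
                      floor = 0.01, jitterMs = 25, jitterRounds = 3,
                      sdMultiplier = 7, maxLag = 40, folds = 20,
                      cmiIters = 200, seed = 1, outDir = "wmv1-out") {
  stopifnot(windowWidth > 0, windowStep > 0, jitterMs > 0, batchSize > 0)
  structure(list(epochs = epochs, batchSize = batchSize,
                 windowWidth = windowWidth, windowStep = windowStep,
                 trainPerCondition = trainPerCondition,
                 repetitions = repetitions, floor = floor,
                 jitterMs = jitterMs, jitterRounds = jitterRounds,
                 sdMultiplier = sdMultiplier, maxLag = maxLag,
                 folds = folds, cmiIters = cmiIters, seed = seed,
                 outDir = outDir),
            class = c("RunConfig", "list"))
}

# md5 of the canonical YAML serialization of a config.
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[setdiff(names(config), "outDir")], tmp)
  unname(tools::md5sum(tmp))
}

stampedCsv <- function(df, path, config, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schema_version=%d config_hash=%s seed=%d",
                     SESSION_SCHEMA_VERSION, configHash(config),
                     as.integer(seed)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a session
#'
#' Chains preprocessing (artifact-trial rejection, channel SNR filtering),
#' delay-period CMI with held-out cross-validation, a cross-temporal
#' decoding matrix and jitter-corrected CCG connectivity for a set of
#' electrode pairs, writing stamped CSV artifacts plus a JSON log of counts
#' at each filter. Identical config + seed + input reproduce identical
#' outputs.
#'
#' @param config a \code{\link{runConfig}}
#' @param session a \linkS4class{SessionData} or a container path
#' @param pairs matrix/data.frame of electrode pairs for the CCG stage
#'   (default: all pairs of the first four retained channels)
#' @param decodeWindows optional window grid overriding the full sliding
#'   grid (keeps desk-scale runs fast)
#' @return list with the QC report, result tables and output paths
#' @export
runPipeline <- function(config, session, pairs = NULL,
                        decodeWindows = NULL) {
  if (is.character(session)) session <- readSession(session)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  log <- list(schema_version = SESSION_SCHEMA_VERSION, config_hash = hash,
              seed = config$seed)

  # --- preprocess: artifact trials (pooled over the experiment), channel SNR
  allRates <- epochRates(session, session@windowMs)
  keepTrial <- rejectArtifactTrials(rowMeans(allRates))
  keptIds <- session@trials$trial_id[keepTrial]
  log$trials_total <- nrow(session@trials)
  log$trials_rejected <- sum(!keepTrial)
  session@trials <- session@trials[keepTrial, , drop = FALSE]
  session@events <- session@events[session@events$trial_id %in% keptIds, ,
                                   drop = FALSE]
  nE <- nElectrodes(session)
  snr <- vapply(seq_len(nE), function(e) {
    ps <- sessionPsth(session, e)
    channelSnr(ps$rate, ps$times,
               spontaneousWindow = config$epochs$spontaneous,
               stimulusWindow = config$epochs$stimulus)$snr
  }, numeric(1))
  channels <- which(!is.na(snr) & snr >= 5)
  log$channels_total <- nE
  log$channels_excluded <- nE - length(channels)
  if (!length(channels)) stop("pipeline stage 'preprocess': all channels excluded")

  # --- cmi (delay window, correct trials, cross-validated)
  delayRates <- epochRates(session, config$epochs$delay, correctOnly = TRUE)
  delayRates <- structure(delayRates[, channels, drop = FALSE],
                          labels = attr(delayRates, "labels"))
  cv <- cmiCrossval(delayRates, k = config$folds, iters = config$cmiIters,
                    seed = childSeed(config$seed, 1L))
  cmiTab <- data.frame(electrode_id = channels, epoch = "delay",
                       cmi = cv$correct$cmi)
  cmiPath <- stampedCsv(cmiTab, file.path(config$outDir, "cmi.csv"),
                        config, config$seed)

  # --- decode
  windows <- if (is.null(decodeWindows))
    makeWindows(session@windowMs, config$windowWidth, config$windowStep)
  else decodeWindows
  decTab <- NULL; decPath <- NULL
  batches <- tryCatch(makeBatches(session, windows, config$batchSize),
                      error = function(e)
                        stop("pipeline stage 'decode': ", conditionMessage(e)))
  batches$counts <- batches$counts[, channels, , drop = FALSE]
  mat <- crossTemporalMatrix(batches, config$trainPerCondition,
                             config$repetitions, config$floor,
                             seed = childSeed(config$seed, 2L))
  decTab <- data.frame(train_start = rep(windows$start, ncol(accuracyMatrix(mat))),
                       test_start = rep(windows$start, each = nrow(accuracyMatrix(mat))),
                       accuracy = as.vector(accuracyMatrix(mat)))
  decPath <- stampedCsv(decTab, file.path(config$outDir, "decoding.csv"),
                        config, config$seed)

  # --- connectivity
  if (is.null(pairs)) {
    ch <- head(channels, 4L)
    pairs <- if (length(ch) >= 2L) t(utils::combn(ch, 2L)) else NULL
  }
  ccgTab <- NULL; ccgPath <- NULL
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      res <- lapply(c(stimulus = "stimulus", delay = "delay"), function(ep) {
        sessionCcg(session, pairs[i, ], epoch = config$epochs[[ep]],
                   epochName = ep, maxLag = config$maxLag,
                   jitterMs = config$jitterMs, rounds = config$jitterRounds,
                   seed = childSeed(config$seed, 10L + i))
      })
      do.call(rbind, lapply(res, function(r) data.frame(
        j = r@pair[1], k = r@pair[2], epoch = r@epoch,
        peak = if (r@valid) max(r@corrected[r@lags >= 1 & r@lags <= 20]) else NA,
        peak_lag = r@peakLag, noise_sd = r@noiseSd,
        significant = r@significant, valid = r@valid)))
    })
    ccgTab <- do.call(rbind, rows)
    rownames(ccgTab) <- NULL
    ccgPath <- stampedCsv(ccgTab, file.path(config$outDir, "ccg.csv"),
                          config, config$seed)
    log$fc_significant_stimulus <- sum(ccgTab$significant[ccgTab$epoch == "stimulus"])
    log$fc_significant_delay <- sum(ccgTab$significant[ccgTab$epoch == "delay"])
  }
  logPath <- file.path(config$outDir, "run_log.json")
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE), logPath)
  list(log = log, channels = channels, cmi = cmiTab, decoding = decTab,
       ccg = ccgTab,
       paths = c(cmi = cmiPath, decoding = decPath, ccg = ccgPath,
                 log = logPath))
}
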