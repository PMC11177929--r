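#' @import methods
NULL

#' Configuration for the synthetic DMTS session generator
#'
#' Collects every parameter of the generative model: per-epoch firing-rate
#' structure (baseline, multiplicative cue-evoked gains, additive delay
#' offsets, an exponentially decaying off-response after cue offset),
#' behavioural structure (fraction of incorrect trials and how strongly their
#' delay modulation is attenuated), optional pairwise lagged synchrony, and
#' the seed that makes a session reproducible.
#'
#' Rates are in spikes/s, times in ms relative to cue onset. Spikes are drawn
#' as Bernoulli events in 1-ms bins (at most one spike per bin, the multiunit
#' convention), so instantaneous rates above 1000 sp/s are not representable.
#'
#' @slot nElectrodes number of recorded electrodes
#' @slot nConditions number of memory-content conditions
#' @slot nTrialsPerCondition correct + incorrect trials generated per condition
#' @slot windowMs recording window \code{c(start, end)} in ms
#' @slot cueWindow cue presentation interval, default \code{c(0, 200)}
#' @slot delayWindow delay interval, default \code{c(700, 1700)}
#' @slot baselineRate spontaneous rate, sp/s
#' @slot stimGain electrodes x conditions matrix of multiplicative gains in
#'   the cue window
#' @slot delayDelta electrodes x conditions matrix of additive rate offsets
#'   (sp/s) in the delay window
#' @slot offResponseAmp amplitude (sp/s) of the transient after cue offset
#' @slot offResponseTau decay time constant (ms) of that transient
#' @slot incorrectFraction fraction of trials per condition marked incorrect
#' @slot incorrectAttenuation factor in [0,1] scaling delay deltas on
#'   incorrect trials
#' @slot syncPairs list of lists with fields \code{a}, \code{b},
#'   \code{copyProbability}, \code{lagMs}, \code{epoch}
#' @slot seed integer seed
#' @export
setClass("SimConfig", representation(
  nElectrodes = "integer", nConditions = "integer",
  nTrialsPerCondition = "integer", windowMs = "numeric",
  cueWindow = "numeric", delayWindow = "numeric",
  baselineRate = "numeric", stimGain = "matrix", delayDelta = "matrix",
  offResponseAmp = "numeric", offResponseTau = "numeric",
  incorrectFraction = "numeric", incorrectAttenuation = "numeric",
  syncPairs = "list", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nElectrodes < 1L) msg <- c(msg, "nElectrodes must be >= 1")
  if (object@nConditions < 2L) msg <- c(msg, "nConditions must be >= 2")
  if (object@nTrialsPerCondition < 1L)
    msg <- c(msg, "nTrialsPerCondition must be >= 1 (zero trials is an error)")
  if (object@windowMs[1] >= object@windowMs[2])
    msg <- c(msg, "windowMs must have start < end")
  if (!all(dim(object@stimGain) == c(object@nElectrodes, object@nConditions)))
    msg <- c(msg, "stimGain must be nElectrodes x nConditions")
  if (!all(dim(object@delayDelta) == c(object@nElectrodes, object@nConditions)))
    msg <- c(msg, "delayDelta must be nElectrodes x nConditions")
  if (object@incorrectFraction < 0 || object@incorrectFraction > 1)
    msg <- c(msg, "incorrectFraction must be in [0, 1]")
  if (object@incorrectAttenuation < 0 || object@incorrectAttenuation > 1)
    msg <- c(msg, "incorrectAttenuation must be in [0, 1]")
  for (sp in object@syncPairs) {
    if (!all(c("a", "b", "copyProbability", "lagMs", "epoch") %in% names(sp)))
      msg <- c(msg, "each sync pair needs fields a, b, copyProbability, lagMs, epoch")
    else if (abs(sp$lagMs) > 40)
      msg <- c(msg, "sync pair lagMs must be within +/-40 ms")
  }
  if (length(msg)) msg else TRUE
})

#' One recorded (or simulated) DMTS session
#'
#' Spike events with their trial metadata, aligned to cue onset. The event
#' table has one row per spike (\code{trial_id}, \code{electrode_id},
#' \code{unit_id}, \code{time_ms}); the trial table has one row per trial
#' (\code{trial_id}, \code{condition}, \code{task_id}, \code{correct},
#' \code{session_id}).
#'
#' @slot events data.frame of spike events
#' @slot trials data.frame of trial metadata
#' @slot windowMs recording window in ms relative to cue onset
#' @slot binMs bin resolution in ms
#' @slot meta list of free-form metadata (generator config, seed, ...)
#' @export
setClass("SessionData", representation(
  events = "data.frame", trials = "data.frame", windowMs = "numeric",
  binMs = "numeric", meta = "list"))

setValidity("SessionData", function(object) {
  msg <- character()
  evNeed <- c("trial_id", "electrode_id", "unit_id", "time_ms")
  trNeed <- c("trial_id", "condition", "task_id", "correct", "session_id")
  if (!all(evNeed %in% names(object@events)))
    msg <- c(msg, paste("events must have columns:", paste(evNeed, collapse = ", ")))
  if (!all(trNeed %in% names(object@trials)))
    msg <- c(msg, paste("trials must have columns:", paste(trNeed, collapse = ", ")))
  if (!length(msg)) {
    orphan <- setdiff(unique(object@events$trial_id), object@trials$trial_id)
    if (length(orphan))
      msg <- c(msg, paste("events reference missing trial ids:",
                          paste(head(orphan, 5L), collapse = ", ")))
    if (nrow(object@events)) {
      tt <- object@events$time_ms
      if (any(tt < object@windowMs[1] | tt >= object@windowMs[2]))
        msg <- c(msg, "event times outside the recording window")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SessionData", function(object) {
  cat(sprintf("SessionData: %d trials, %d electrodes, %d spikes\n",
              nrow(object@trials),
              length(unique(object@events$electrode_id)),
              nrow(object@events)))
  cat(sprintf("  window [%g, %g) ms, %g-ms bins, conditions: %s\n",
              object@windowMs[1], object@windowMs[2], object@binMs,
              paste(sort(unique(as.character(object@trials$condition))),
                    collapse = ", ")))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d electrodes, %d conditions x %d trials, ",
                     "baseline %g sp/s, seed %d\n"),
              object@nElectrodes, object@nConditions,
              object@nTrialsPerCondition, object@baselineRate, object@seed))
})

#' Cross-temporal decoding accuracy matrix
#'
#' Train-window x test-window grid of Poisson-independent-decoder accuracies,
#' averaged over random train/test splits.
#'
#' @slot accuracy train x test accuracy matrix in [0, 1]
#' @slot windows data.frame of the shared window grid (start, end in ms)
#' @slot nRepetitions number of random splits averaged
#' @slot chance chance level, 1 / number of conditions
#' @slot meta list (batch size, train batches per condition, seed)
#' @export
setClass("DecodingMatrix", representation(
  accuracy = "matrix", windows = "data.frame", nRepetitions = "integer",
  chance = "numeric", meta = "list"))

setValidity("DecodingMatrix", function(object) {
  msg <- character()
  if (nrow(object@accuracy) != ncol(object@accuracy))
    msg <- c(msg, "accuracy grid must be square over the shared window set")
  a <- object@accuracy
  if (any(a < 0 | a > 1, na.rm = TRUE)) msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DecodingMatrix", function(object) {
  cat(sprintf("DecodingMatrix: %d x %d windows, %d repetitions, chance %.3g\n",
              nrow(object@accuracy), ncol(object@accuracy),
              object@nRepetitions, object@chance))
  cat(sprintf("  accuracy range [%.3f, %.3f]\n",
              min(object@accuracy), max(object@accuracy)))
})

#' Jitter-corrected cross-correlogram for one electrode pair
#'
#' @slot pair electrode/unit pair (j, k)
#' @slot condition content condition the CCG was computed for
#' @slot epoch epoch name
#' @slot lags lag axis in ms
#' @slot raw raw normalized correlogram
#' @slot jitterExpectation averaged jittered correlogram
#' @slot corrected raw minus jitter expectation
#' @slot peakLag lag (ms) of the corrected maximum over 1-20 ms
#' @slot noiseSd SD of corrected values over |lag| in [20, 40] ms
#' @slot significant logical, 7-SD rule
#' @slot valid FALSE when either train fired no spike in the epoch
#' @export
setClass("CcgResult", representation(
  pair = "integer", condition = "character", epoch = "character",
  lags = "integer", raw = "numeric", jitterExpectation = "numeric",
  corrected = "numeric", peakLag = "integer", noiseSd = "numeric",
  significant = "logical", valid = "logical"))

setValidity("CcgResult", function(object) {
  msg <- character()
  if (length(object@lags) != length(object@raw) ||
      length(object@lags) != length(object@corrected))
    msg <- c(msg, "lags, raw and corrected must have equal length")
  if (object@valid && any(object@raw < 0)) msg <- c(msg, "raw CCG values must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CcgResult", function(object) {
  cat(sprintf("CcgResult pair (%d, %d), condition %s, epoch %s\n",
              object@pair[1], object@pair[2], object@condition, object@epoch))
  if (object@valid)
    cat(sprintf("  peak %.4f at %d ms, noise SD %.4g, significant: %s\n",
                max(object@corrected[object@lags >= 1 & object@lags <= 20]),
                object@peakLag, object@noiseSd, object@significant))
  else cat("  invalid (a unit was silent in this epoch)\n")
})

#' @rdname SessionData-class
#' @param object a \code{SessionData}
#' @export
sessionTrials <- function(object) object@trials

#' @rdname SessionData-class
#' @export
sessionEvents <- function(object) object@events

#' @rdname SessionData-class
#' @export
sessionWindow <- function(object) object@windowMs

#' @rdname SessionData-class
#' @export
sessionConditions <- function(object) sort(unique(as.character(object@trials$condition)))

#' @rdname SessionData-class
#' @export
nElectrodes <- function(object) {
  n <- object@meta$nElectrodes
  if (is.null(n)) n <- max(object@events$electrode_id, 0L)
  as.integer(n)
}

#' @rdname DecodingMatrix-class
#' @param object a \code{DecodingMatrix}
#' @export
accuracyMatrix <- function(object) object@accuracy

#' @rdname CcgResult-class
#' @param object a \code{CcgResult}
#' @export
correctedCcg <- function(object) object@corrected

#' @rdname CcgResult-class
#' @export
isSignificant <- function(object) object@significant
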