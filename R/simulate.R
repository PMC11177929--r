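#' Build a generator configuration
#'
#' Returns a validated \linkS4class{SimConfig}. Defaults emulate a
#' delayed match-to-sample session: four memory contents, a strong tuned
#' response during the 200-ms cue, an exponentially decaying off-response
#' after cue offset, and a weak additive content modulation during the
#' 700-1700-ms delay whose condition ranking is drawn independently of the
#' stimulus-period ranking. Delay firing stays near the spontaneous level.
#'
#' When \code{stimGain}/\code{delayDelta} are not supplied they are drawn
#' (deterministically from \code{seed}) as independent per-electrode
#' permutations of a descending gain profile (8, 5, 3, 2 at four conditions)
#' and a delay-offset profile (+2, +0.7, -0.7, -2 sp/s), so that stimulus and
#' delay rankings are unrelated by construction.
#'
#' @param nElectrodes,nConditions,nTrialsPerCondition session dimensions
#' @param windowMs recording window in ms relative to cue onset
#' @param cueWindow,delayWindow analysis epochs of the generative model
#' @param baselineRate spontaneous rate in sp/s
#' @param stimGain optional electrodes x conditions gain matrix
#' @param delayDelta optional electrodes x conditions additive offsets, sp/s
#' @param offResponseAmp,offResponseTau off-response amplitude (sp/s) and
#'   decay constant (ms)
#' @param incorrectFraction fraction of trials per condition marked incorrect
#' @param incorrectAttenuation factor scaling delay deltas on incorrect trials
#' @param syncPairs list of lagged-synchrony injections, each a list with
#'   fields \code{a}, \code{b}, \code{copyProbability}, \code{lagMs},
#'   \code{epoch}
#' @param equalRankings if TRUE, the default delay ranking copies the
#'   stimulus ranking (contrast simulations)
#' @param seed integer seed; the same config yields an identical session
#' @return a \code{SimConfig}
#' @export
simConfig <- function(nElectrodes = 8, nConditions = 4,
                      nTrialsPerCondition = 100,
                      windowMs = c(-200, 1700),
                      cueWindow = c(0, 200), delayWindow = c(700, 1700),
                      baselineRate = 10,
                      stimGain = NULL, delayDelta = NULL,
                      offResponseAmp = 20, offResponseTau = 100,
                      incorrectFraction = 0, incorrectAttenuation = 0.25,
                      syncPairs = list(), equalRankings = FALSE, seed = 1) {
  nElectrodes <- as.integer(nElectrodes)
  nConditions <- as.integer(nConditions)
  windowMs <- checkInterval(windowMs)
  gainProfile <- seq(8, 2, length.out = nConditions)
  deltaProfile <- seq(2, -2, length.out = nConditions)
  if (is.null(stimGain) || is.null(delayDelta)) {
    drawn <- withSeed(childSeed(seed, 7L), {
      g <- t(vapply(seq_len(nElectrodes),
                    function(i) sample(gainProfile), numeric(nConditions)))
      d <- t(vapply(seq_len(nElectrodes),
                    function(i) sample(deltaProfile), numeric(nConditions)))
      list(g = g, d = d)
    })
    if (is.null(stimGain)) stimGain <- drawn$g
    if (is.null(delayDelta)) {
      delayDelta <- if (equalRankings) {
        # same condition ranking as the stimulus gains
        t(apply(stimGain, 1, function(g) deltaProfile[order(order(-g))]))
      } else drawn$d
    }
  }
  stimGain <- matrix(as.numeric(stimGain), nElectrodes, nConditions)
  delayDelta <- matrix(as.numeric(delayDelta), nElectrodes, nConditions)
  new("SimConfig", nElectrodes = nElectrodes, nConditions = nConditions,
      nTrialsPerCondition = as.integer(nTrialsPerCondition),
      windowMs = windowMs, cueWindow = checkInterval(cueWindow),
      delayWindow = checkInterval(delayWindow),
      baselineRate = as.numeric(baselineRate),
      stimGain = stimGain, delayDelta = delayDelta,
      offResponseAmp = as.numeric(offResponseAmp),
      offResponseTau = as.numeric(offResponseTau),
      incorrectFraction = as.numeric(incorrectFraction),
      incorrectAttenuation = as.numeric(incorrectAttenuation),
      syncPairs = syncPairs, seed = as.integer(seed))
}

# Per-bin rate profile (sp/s) for one electrode/condition/correctness.
# Bins are 1 ms, left edges windowMs[1] .. windowMs[2]-1.
rateProfile <- function(config, electrode, condition, correct = TRUE,
                        clip = TRUE) {
  t <- seq(config@windowMs[1], config@windowMs[2] - 1)
  r <- rep(config@baselineRate, length(t))
  cue <- t >= config@cueWindow[1] & t < config@cueWindow[2]
  r[cue] <- config@baselineRate * config@stimGain[electrode, condition]
  post <- t >= config@cueWindow[2]
  r[post] <- r[post] + config@offResponseAmp *
    exp(-(t[post] - config@cueWindow[2]) / config@offResponseTau)
  dl <- t >= config@delayWindow[1] & t < config@delayWindow[2]
  delta <- config@delayDelta[electrode, condition]
  if (!correct) delta <- delta * config@incorrectAttenuation
  r[dl] <- r[dl] + delta
  if (any(r < 0)) {
    if (!clip) stop("rate profile goes negative and clipping is disabled")
    r <- pmax(r, 0)
  }
  r
}

#' Simulate a DMTS session
#'
#' Draws spikes as independent Bernoulli events in 1-ms bins (probability
#' rate/1000 per bin), which makes the trains inhomogeneous-Poisson to first
#' order while respecting the one-spike-per-bin multiunit convention. Trial
#' order is randomized across conditions; \code{incorrectFraction} of each
#' condition's trials (rounded down) are marked incorrect and receive delay
#' deltas scaled by \code{incorrectAttenuation}. Any synchrony pairs in the
#' config are injected afterwards.
#'
#' @param config a \linkS4class{SimConfig}
#' @param taskId task identifier stored in the trial table
#' @param sessionId session identifier stored in the trial table
#' @param clip clip negative rates at 0 (an error is raised otherwise)
#' @return a \linkS4class{SessionData}
#' @export
simulateSession <- function(config, taskId = "dmts", sessionId = 1L,
                            clip = TRUE) {
  validObject(config)
  conds <- sprintf("c%d", seq_len(config@nConditions))
  nPer <- config@nTrialsPerCondition
  nTotal <- nPer * config@nConditions
  nBins <- as.integer(diff(config@windowMs))
  withSeed(config@seed, {
    condSeq <- sample(rep(conds, each = nPer))
    nInc <- floor(config@incorrectFraction * nPer)
    correct <- rep(TRUE, nTotal)
    for (cc in conds) {
      idx <- which(condSeq == cc)
      if (nInc > 0) correct[sample(idx, nInc)] <- FALSE
    }
    trials <- data.frame(trial_id = seq_len(nTotal), condition = condSeq,
                         task_id = taskId, correct = correct,
                         session_id = sessionId, stringsAsFactors = FALSE)
    evList <- vector("list", config@nElectrodes * config@nConditions * 2L)
    k <- 0L
    for (e in seq_len(config@nElectrodes)) {
      for (ci in seq_len(config@nConditions)) {
        for (corr in c(TRUE, FALSE)) {
          ids <- trials$trial_id[trials$condition == conds[ci] &
                                   trials$correct == corr]
          if (!length(ids)) next
          p <- pmin(rateProfile(config, e, ci, corr, clip) / 1000, 1)
          draws <- matrix(runif(length(ids) * nBins), length(ids), nBins)
          hit <- which(draws < rep(p, each = length(ids)), arr.ind = TRUE)
          k <- k + 1L
          evList[[k]] <- data.frame(
            trial_id = ids[hit[, 1L]], electrode_id = e, unit_id = 1L,
            time_ms = config@windowMs[1] + hit[, 2L] - 1)
        }
      }
    }
    events <- do.call(rbind, evList[seq_len(k)])
    events <- events[order(events$trial_id, events$electrode_id,
                           events$time_ms), , drop = FALSE]
    rownames(events) <- NULL
    session <- new("SessionData", events = events, trials = trials,
                   windowMs = config@windowMs, binMs = 1,
                   meta = list(nElectrodes = config@nElectrodes,
                               seed = config@seed, droppedSyncSpikes = 0L))
    for (i in seq_along(config@syncPairs)) {
      sp <- config@syncPairs[[i]]
      session <- injectPairwiseSynchrony(
        session, c(sp$a, sp$b), sp$copyProbability, sp$lagMs, sp$epoch,
        seed = childSeed(config@seed, 100L + i))
    }
    session
  })
}

#' Inject lagged pairwise synchrony
#'
#' Each spike of electrode \code{pair[1]} inside \code{epoch} is copied to
#' electrode \code{pair[2]} at \code{+lagMs} with probability
#' \code{copyProbability}, providing ground-truth functional connectivity for
#' the cross-correlogram analysis. Copies landing outside the recording
#' window, or in a bin where the target already fires (the binary-bin
#' convention), are dropped; the dropped count is accumulated in
#' \code{meta$droppedSyncSpikes}.
#'
#' @param session a \linkS4class{SessionData}
#' @param pair integer vector \code{c(source, target)} electrode ids
#' @param copyProbability probability a source spike is copied
#' @param lagMs lag of the copy, ms (|lag| <= 40)
#' @param epoch interval \code{c(start, end)} restricting the source spikes
#' @param seed integer seed
#' @return the modified \code{SessionData}
#' @export
injectPairwiseSynchrony <- function(session, pair, copyProbability, lagMs,
                                    epoch, seed = 1) {
  stopifnot(length(pair) == 2L, copyProbability >= 0, copyProbability <= 1)
  if (abs(lagMs) > 40) stop("lagMs must be within +/-40 ms")
  epoch <- checkInterval(epoch)
  if (epoch[1] < session@windowMs[1] || epoch[2] > session@windowMs[2])
    stop("epoch must lie within the recording window")
  ev <- session@events
  if (!all(pair %in% seq_len(nElectrodes(session))))
    stop("both electrodes must exist in the session")
  if (copyProbability == 0) return(session)
  withSeed(seed, {
    src <- which(ev$electrode_id == pair[1] &
                   ev$time_ms >= epoch[1] & ev$time_ms < epoch[2])
    take <- src[runif(length(src)) < copyProbability]
    newt <- ev$time_ms[take] + lagMs
    inWin <- newt >= session@windowMs[1] & newt < session@windowMs[2]
    dropped <- sum(!inWin)
    add <- data.frame(trial_id = ev$trial_id[take][inWin],
                      electrode_id = rep(pair[2], sum(inWin)),
                      unit_id = rep(1L, sum(inWin)),
                      time_ms = newt[inWin])
    # keep target trains binary: drop copies colliding with existing spikes
    tgt <- ev[ev$electrode_id == pair[2], c("trial_id", "time_ms")]
    key <- paste(add$trial_id, add$time_ms)
    clash <- key %in% paste(tgt$trial_id, tgt$time_ms) | duplicated(key)
    dropped <- dropped + sum(clash)
    add <- add[!clash, , drop = FALSE]
    ev <- rbind(ev, add)
    ev <- ev[order(ev$trial_id, ev$electrode_id, ev$time_ms), , drop = FALSE]
    rownames(ev) <- NULL
    session@events <- ev
    session@meta$droppedSyncSpikes <-
      (session@meta$droppedSyncSpikes %||% 0L) + dropped
    session
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize a raw voltage trace around known spike times
#'
#' Gaussian noise plus a short biphasic deflection at each spike time: a
#' 0.4-ms positive lobe of peak amplitude \code{spikeAmp} followed by a
#' 0.8-ms negative lobe of 0.35 x \code{spikeAmp}, the asymmetry typical of
#' extracellular waveforms. Any detection threshold between the trough and
#' the peak therefore sees exactly one |trace| crossing per spike. Serves as
#' a fixture for threshold-crossing event detection.
#'
#' @param spikeTimesMs spike times in ms from trace start
#' @param noiseSd noise standard deviation (same units as \code{spikeAmp})
#' @param spikeAmp peak absolute amplitude of the spike waveform
#' @param durationMs trace duration in ms
#' @param dtMs sample interval in ms (e.g. 1/30 for 30 kHz)
#' @param seed integer seed for the noise
#' @return numeric vector of samples
#' @export
synthesizeRawTrace <- function(spikeTimesMs, noiseSd, spikeAmp, durationMs,
                               dtMs = 1 / 30, seed = 1) {
  if (dtMs <= 0) stop("dtMs must be > 0")
  if (spikeAmp <= 0) stop("spikeAmp must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  n <- as.integer(round(durationMs / dtMs))
  withSeed(seed, {
    trace <- if (noiseSd > 0) rnorm(n, 0, noiseSd) else numeric(n)
    tk <- seq(0, 1.2, by = dtMs)       # total waveform duration 1.2 ms
    kernel <- ifelse(tk < 0.4,
                     spikeAmp * sin(pi * tk / 0.4),
                     -0.35 * spikeAmp * sin(pi * (tk - 0.4) / 0.8))
    for (st in spikeTimesMs) {
      i0 <- as.integer(round(st / dtMs)) + 1L
      idx <- i0 + seq_along(kernel) - 1L
      ok <- idx >= 1L & idx <= n
      trace[idx[ok]] <- trace[idx[ok]] + kernel[ok]
    }
    trace
  })
}
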