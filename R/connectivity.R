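#' Binary spike-train matrix for one electrode and epoch
#'
#' One row per trial, one 1-ms bin per column; entries are 0/1 per the
#' multiunit convention.
#'
#' @param session a \linkS4class{SessionData}
#' @param electrode electrode id
#' @param epoch interval \code{c(start, end)} in ms
#' @param trials optional trial ids to restrict to (defaults to all trials)
#' @param binMs bin width in ms, default 1
#' @return trials x bins 0/1 matrix
#' @export
spikeTrainMatrix <- function(session, electrode, epoch, trials = NULL,
                             binMs = 1) {
  epoch <- checkInterval(epoch)
  if (is.null(trials)) trials <- session@trials$trial_id
  nBins <- as.integer(floor(diff(epoch) / binMs))
  ev <- session@events
  keep <- ev$electrode_id == electrode & ev$trial_id %in% trials &
    ev$time_ms >= epoch[1] & ev$time_ms < epoch[1] + nBins * binMs
  tIdx <- match(ev$trial_id[keep], trials)
  bIdx <- floor((ev$time_ms[keep] - epoch[1]) / binMs) + 1L
  m <- matrix(0L, length(trials), nBins)
  m[cbind(tIdx, bIdx)] <- 1L
  rownames(m) <- as.character(trials)
  m
}

#' Raw normalized cross-correlogram
#'
#' For binary trains \code{r_j}, \code{r_k} (trials x bins), the correlogram
#' at lag \code{tau} is the trial-summed coincidence count
#' \code{sum_i sum_t r_j(t - tau) r_k(t)} divided by the geometric mean of
#' the two units' total spike counts in the epoch. The pair is invalid when
#' either unit is silent across all trials.
#'
#' @param trainsJ,trainsK trials x bins matrices on the same grid
#' @param maxLag largest lag in bins, default 40
#' @return list with \code{lags}, \code{ccg}, \code{valid}
#' @export
computeCcg <- function(trainsJ, trainsK, maxLag = 40) {
  stopifnot(all(dim(trainsJ) == dim(trainsK)))
  n <- ncol(trainsJ)
  lags <- seq.int(-maxLag, maxLag)
  totJ <- sum(trainsJ); totK <- sum(trainsK)
  if (totJ == 0 || totK == 0)
    return(list(lags = lags, ccg = rep(NA_real_, length(lags)), valid = FALSE))
  denom <- sqrt(totJ * totK)
  binary <- all(trainsJ == 0 | trainsJ == 1) && all(trainsK == 0 | trainsK == 1)
  if (binary) {
    # exact sparse evaluation: tau = t_k - t_j over same-trial spike pairs
    num <- numeric(length(lags))
    for (i in seq_len(nrow(trainsJ))) {
      tj <- which(trainsJ[i, ] == 1)
      tk <- which(trainsK[i, ] == 1)
      if (!length(tj) || !length(tk)) next
      d <- rep(tk, each = length(tj)) - tj
      d <- d[d >= -maxLag & d <= maxLag]
      if (length(d)) num <- num + tabulate(d + maxLag + 1L, length(lags))
    }
  } else {
    num <- vapply(lags, function(tau) {
      if (tau >= 0)
        sum(trainsJ[, seq_len(n - tau), drop = FALSE] *
              trainsK[, seq.int(1 + tau, n), drop = FALSE])
      else
        sum(trainsJ[, seq.int(1 - tau, n), drop = FALSE] *
              trainsK[, seq_len(n + tau), drop = FALSE])
    }, numeric(1))
  }
  list(lags = lags, ccg = num / denom, valid = TRUE)
}

# Resample each spike uniformly within its trial's jitter block (blocks of
# `jitterBins` bins aligned to the epoch start). Sampling bins without
# replacement preserves the binary convention and per-trial block counts
# exactly, hence the across-trial PSTH at block resolution.
jitterSpikeTrains <- function(trains, jitterBins = 25L) {
  n <- ncol(trains)
  blockOf <- (seq_len(n) - 1L) %/% jitterBins
  out <- trains
  for (i in seq_len(nrow(trains))) {
    # a random permutation of bins within each block relocates every spike
    # uniformly without replacement, preserving block counts exactly
    perm <- order(blockOf, runif(n))
    out[i, ] <- trains[i, perm]
  }
  out
}

# Block-mean rate profiles: the exact per-bin expectation of a jittered
# train.
jitterExpectedProfile <- function(trains, jitterBins = 25L) {
  n <- ncol(trains)
  blockOf <- (seq_len(n) - 1L) %/% jitterBins
  out <- trains * 0
  for (b in unique(blockOf)) {
    cols <- which(blockOf == b)
    out[, cols] <- rowMeans(trains[, cols, drop = FALSE])
  }
  out
}

#' Jitter-corrected cross-correlogram
#'
#' Subtracts from the raw correlogram the average of \code{rounds} jittered
#' correlograms, in which every spike is resampled uniformly within its
#' trial's jitter-window block. This removes correlations locked to the
#' stimulus (shared PSTH) and correlations on timescales longer than the
#' jitter window, leaving fine-timescale coordination. With
#' \code{exact = TRUE} the Monte-Carlo rounds are replaced by the analytic
#' expectation (correlogram of the block-mean profiles).
#'
#' @param trainsJ,trainsK trials x bins binary matrices
#' @param maxLag largest lag in bins, default 40
#' @param jitterMs jitter window, default 25 ms
#' @param rounds Monte-Carlo rounds averaged, default 3
#' @param binMs bin width in ms, default 1
#' @param exact use the analytic jitter expectation instead
#' @param seed integer seed for the resampling
#' @param pair,condition,epoch labels carried into the result
#' @return a \linkS4class{CcgResult}
#' @export
jitterCorrect <- function(trainsJ, trainsK, maxLag = 40, jitterMs = 25,
                          rounds = 3, binMs = 1, exact = FALSE, seed = 1,
                          pair = c(1L, 2L), condition = "c1",
                          epoch = "epoch") {
  jitterBins <- as.integer(round(jitterMs / binMs))
  if (jitterBins < 2L) stop("jitter window must span at least 2 bins")
  raw <- computeCcg(trainsJ, trainsK, maxLag)
  lags <- as.integer(raw$lags)
  if (!raw$valid) {
    return(new("CcgResult", pair = as.integer(pair), condition = condition,
               epoch = epoch, lags = lags, raw = raw$ccg,
               jitterExpectation = raw$ccg, corrected = raw$ccg,
               peakLag = NA_integer_, noiseSd = NA_real_,
               significant = FALSE, valid = FALSE))
  }
  expectation <- if (exact) {
    pj <- jitterExpectedProfile(trainsJ, jitterBins)
    pk <- jitterExpectedProfile(trainsK, jitterBins)
    computeCcg(pj, pk, maxLag)$ccg
  } else {
    withSeed(seed, {
      acc <- numeric(length(lags))
      for (r in seq_len(rounds)) {
        jj <- jitterSpikeTrains(trainsJ, jitterBins)
        jk <- jitterSpikeTrains(trainsK, jitterBins)
        acc <- acc + computeCcg(jj, jk, maxLag)$ccg
      }
      acc / rounds
    })
  }
  corrected <- raw$ccg - expectation
  sig <- testSignificance(corrected, lags)
  new("CcgResult", pair = as.integer(pair), condition = condition,
      epoch = epoch, lags = lags, raw = raw$ccg,
      jitterExpectation = expectation, corrected = corrected,
      peakLag = sig$peakLag, noiseSd = sig$noiseSd,
      significant = sig$significant, valid = TRUE)
}

#' 7-SD significance rule for a corrected correlogram
#'
#' The noise SD is taken over the corrected values at lags with absolute
#' value between 20 and 40 ms; the correlogram is significant iff its
#' maximum over the 1-20-ms lags strictly exceeds \code{sdMultiplier} times
#' that SD. If the flank SD is exactly zero, significance requires the
#' maximum to be strictly positive.
#'
#' @param corrected corrected CCG values
#' @param lags lag axis in ms, must cover \code{[-40, 40]}
#' @param sdMultiplier default 7
#' @param peakRange lag range searched for the peak, default \code{c(1, 20)}
#' @param flankRange absolute-lag range defining noise, default
#'   \code{c(20, 40)}
#' @return list with \code{significant}, \code{peakLag}, \code{noiseSd},
#'   \code{peak}
#' @export
testSignificance <- function(corrected, lags, sdMultiplier = 7,
                             peakRange = c(1, 20), flankRange = c(20, 40)) {
  stopifnot(length(corrected) == length(lags))
  inPeak <- lags >= peakRange[1] & lags <= peakRange[2]
  inFlank <- abs(lags) >= flankRange[1] & abs(lags) <= flankRange[2]
  if (!any(inPeak) || sum(inFlank) < 2L)
    stop("corrected CCG must cover lags up to +/-40 ms")
  noiseSd <- sd(corrected[inFlank])
  peak <- max(corrected[inPeak])
  peakLag <- as.integer(lags[inPeak][which.max(corrected[inPeak])])
  significant <- if (noiseSd == 0) peak > 0 else peak > sdMultiplier * noiseSd
  list(significant = significant, peakLag = peakLag, noiseSd = noiseSd,
       peak = peak)
}

#' Jitter-corrected CCG for an electrode pair of a session
#'
#' Convenience wrapper: extracts the two units' binary trains for one
#' content condition and epoch, then runs \code{\link{jitterCorrect}}.
#'
#' @param session a \linkS4class{SessionData}
#' @param pair electrode ids \code{c(j, k)}
#' @param condition content condition (all conditions when NULL)
#' @param epoch interval in ms
#' @param epochName label stored in the result
#' @param correctOnly use correct trials only
#' @param ... passed to \code{\link{jitterCorrect}}
#' @return a \linkS4class{CcgResult}
#' @export
sessionCcg <- function(session, pair, condition = NULL, epoch,
                       epochName = "epoch", correctOnly = TRUE, ...) {
  tr <- session@trials
  if (correctOnly) tr <- tr[tr$correct, , drop = FALSE]
  if (!is.null(condition)) tr <- tr[tr$condition == condition, , drop = FALSE]
  tj <- spikeTrainMatrix(session, pair[1], epoch, tr$trial_id)
  tk <- spikeTrainMatrix(session, pair[2], epoch, tr$trial_id)
  jitterCorrect(tj, tk, pair = pair,
                condition = if (is.null(condition)) "all" else condition,
                epoch = epochName, ...)
}

#' Categorize functional connectivity across epochs
#'
#' Pairs significant in either epoch are labelled \code{stimulus_only},
#' \code{delay_only} or \code{both}; the three proportions are reported
#' relative to the number of pairs significant during the stimulus period.
#' With no stimulus-significant pair the proportions are undefined and
#' flagged.
#'
#' @param stimSignificant,delaySignificant logical vectors over the same
#'   pair set (or lists of \linkS4class{CcgResult})
#' @return list with \code{categories} (data.frame), \code{proportions},
#'   \code{denominator}, \code{undefined}
#' @export
categorizeFc <- function(stimSignificant, delaySignificant) {
  asFlag <- function(x) if (is.list(x)) vapply(x, isSignificant, logical(1)) else x
  s <- asFlag(stimSignificant); d <- asFlag(delaySignificant)
  stopifnot(length(s) == length(d))
  cat <- rep(NA_character_, length(s))
  cat[s & !d] <- "stimulus_only"
  cat[!s & d] <- "delay_only"
  cat[s & d] <- "both"
  denom <- sum(s)
  props <- if (denom > 0)
    c(stimulus_only = sum(s & !d) / denom, delay_only = sum(!s & d) / denom,
      both = sum(s & d) / denom)
  else c(stimulus_only = NA_real_, delay_only = NA_real_, both = NA_real_)
  list(categories = data.frame(pair = seq_along(s), category = cat,
                               stringsAsFactors = FALSE),
       proportions = props, denominator = denom, undefined = denom == 0)
}
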