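#' Named analysis epochs
#'
#' Standard half-open windows \code{[start, end)} in ms relative to cue
#' onset: spontaneous (-150 to 0), stimulus (0 to 200), delay (700 to 1700)
#' and later delay (1200 to 1700).
#'
#' @param spontaneous,stimulus,delay,laterDelay intervals in ms
#' @return a named list of intervals
#' @export
epochSpec <- function(spontaneous = c(-150, 0), stimulus = c(0, 200),
                      delay = c(700, 1700), laterDelay = c(1200, 1700)) {
  out <- list(spontaneous = checkInterval(spontaneous),
              stimulus = checkInterval(stimulus),
              delay = checkInterval(delay),
              laterDelay = checkInterval(laterDelay))
  structure(out, class = c("EpochSpec", "list"))
}

#' High-pass filter a raw trace
#'
#' 4th-order Butterworth high-pass (zero-phase, filtered forwards and
#' backwards), the standard step before threshold-crossing MUA detection.
#'
#' @param trace sampled signal
#' @param fsHz sampling rate in Hz
#' @param cutoffHz cutoff frequency, default 1000 Hz
#' @return filtered trace
#' @export
highpassFilter <- function(trace, fsHz, cutoffHz = 1000) {
  bf <- signal::butter(4, cutoffHz / (fsHz / 2), type = "high")
  as.numeric(signal::filtfilt(bf, trace))
}

#' Detect multiunit threshold-crossing events
#'
#' Marks 1 exactly at samples where |trace| transitions from below to
#' at-or-above the threshold; samples where it stays above (or below) are 0,
#' so one excursion yields one event. The threshold is
#' \code{thresholdFactor} times a robust noise-SD estimate,
#' \code{median(|trace|)/0.6745}, unless an absolute \code{threshold} is
#' given.
#'
#' @param trace high-pass-filtered sampled signal
#' @param thresholdFactor multiple of the noise SD, default 4.5
#' @param threshold optional absolute threshold overriding the factor
#' @return integer 0/1 event train, same length as \code{trace}
#' @export
detectMuaEvents <- function(trace, thresholdFactor = 4.5, threshold = NULL) {
  a <- abs(trace)
  if (is.null(threshold)) {
    if (is.na(sd(trace)) || sd(trace) == 0)
      stop("constant trace: noise SD is zero, cannot set a threshold")
    noiseSd <- median(a) / 0.6745
    if (noiseSd == 0) noiseSd <- sd(trace)   # spike-dominated sparse trace
    threshold <- thresholdFactor * noiseSd
  }
  above <- a >= threshold
  ev <- above & !c(FALSE, above[-length(above)])
  as.integer(ev)
}

#' Reject artifact trials by modified z-score
#'
#' A trial is kept iff its modified z-score (the Iglewicz-Hoaglin statistic
#' \code{0.6745 * (x - median) / MAD}) lies within \code{[-zCut, zCut]}.
#' When the MAD is 0 the standard z-score \code{(x - mean)/SD} is used
#' instead; identical rates keep every trial.
#'
#' @param perTrialRates vector of per-trial firing rates, sp/s
#' @param zCut rejection threshold, default 2.5
#' @return logical keep mask in trial order
#' @export
rejectArtifactTrials <- function(perTrialRates, zCut = 2.5) {
  x <- as.numeric(perTrialRates)
  if (!length(x)) stop("empty input")
  if (length(x) < 3L) stop("need at least 3 trials")
  med <- median(x)
  madRaw <- median(abs(x - med))
  if (madRaw > 0) {
    z <- 0.6745 * (x - med) / madRaw
  } else {
    s <- sd(x)
    z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  abs(z) <= zCut
}

#' Channel signal-to-noise ratio
#'
#' Peak height of the stimulus-evoked response (maximum of the boxcar-
#' smoothed PSTH in the stimulus window, above the prestimulus mean) divided
#' by the SD of the smoothed prestimulus activity. Channels with SNR below
#' \code{minSnr}, or with zero prestimulus SD, are flagged for exclusion.
#'
#' @param psth rate time series, sp/s
#' @param times bin centres of \code{psth}, ms relative to cue onset
#' @param spontaneousWindow prestimulus window, default \code{c(-150, 0)}
#' @param stimulusWindow evoked window, default \code{c(0, 200)}
#' @param smoothMs boxcar width for PSTH smoothing, default 10 ms
#' @param minSnr exclusion threshold, default 5
#' @return list with \code{snr}, \code{excluded}, \code{valid}
#' @export
channelSnr <- function(psth, times, spontaneousWindow = c(-150, 0),
                       stimulusWindow = c(0, 200), smoothMs = 10,
                       minSnr = 5) {
  stopifnot(length(psth) == length(times))
  binMs <- if (length(times) > 1) median(diff(times)) else 1
  sm <- boxcarSmooth(psth, smoothMs / binMs)
  pre <- sm[times >= spontaneousWindow[1] & times < spontaneousWindow[2]]
  stim <- sm[times >= stimulusWindow[1] & times < stimulusWindow[2]]
  if (!length(pre) || !length(stim))
    stop("psth must cover both the spontaneous and the stimulus window")
  sdPre <- sd(pre)
  if (is.na(sdPre) || sdPre == 0)
    return(list(snr = NA_real_, excluded = TRUE, valid = FALSE))
  snr <- (max(stim) - mean(pre)) / sdPre
  list(snr = snr, excluded = snr < minSnr, valid = TRUE)
}

#' Fit a 2-D Gaussian receptive field
#'
#' Least-squares fit of
#' \code{amp * exp(-((x-x0)^2/(2 sx^2) + (y-y0)^2/(2 sy^2))) + base} to a
#' grid of mean responses over probe positions. The RF size is reported as
#' twice the geometric mean of the axis sigmas. Non-convergent fits are
#' marked unfitted (\code{rSquared = -Inf}).
#'
#' @param grid matrix of mean rates, rows indexed by \code{yDeg}, columns by
#'   \code{xDeg} (at least 5 x 5)
#' @param xDeg,yDeg probe positions in degrees
#' @return list with \code{center}, \code{sizeDeg}, \code{rSquared},
#'   \code{params}
#' @export
fitRf <- function(grid, xDeg = seq_len(ncol(grid)),
                  yDeg = seq_len(nrow(grid))) {
  if (nrow(grid) < 5L || ncol(grid) < 5L) stop("grid must be at least 5 x 5")
  df <- data.frame(z = as.vector(grid),
                   x = rep(xDeg, each = nrow(grid)),
                   y = rep(yDeg, times = ncol(grid)))
  unfitted <- list(center = c(NA_real_, NA_real_), sizeDeg = NA_real_,
                   rSquared = -Inf, params = NULL)
  ssTot <- sum((df$z - mean(df$z))^2)
  if (ssTot == 0) {                      # flat grid: nothing to fit
    return(list(center = c(mean(xDeg), mean(yDeg)), sizeDeg = NA_real_,
                rSquared = 0, params = NULL))
  }
  imax <- which.max(df$z)
  start <- list(amp = max(df$z) - min(df$z), x0 = df$x[imax], y0 = df$y[imax],
                sx = diff(range(xDeg)) / 4, sy = diff(range(yDeg)) / 4,
                base = min(df$z))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ amp * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))) + base,
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(unfitted)
  p <- as.list(coef(fit))
  ssRes <- sum(residuals(fit)^2)
  r2 <- 1 - ssRes / ssTot
  list(center = c(p$x0, p$y0), sizeDeg = 2 * sqrt(abs(p$sx) * abs(p$sy)),
       rSquared = r2, params = p)
}

#' Assemble a receptive-field map over electrodes
#'
#' Collects per-electrode Gaussian fits into a table and averages the centres
#' of well-fitted electrodes (goodness of fit > \code{r2Min}) into the array
#' centre.
#'
#' @param fits list of \code{\link{fitRf}} results, one per electrode
#' @param r2Min goodness-of-fit criterion, default 0.6
#' @return list with \code{table} (data.frame) and \code{arrayCenter}
#' @export
buildRfMap <- function(fits, r2Min = 0.6) {
  tab <- data.frame(
    electrode_id = seq_along(fits),
    x = vapply(fits, function(f) f$center[1], numeric(1)),
    y = vapply(fits, function(f) f$center[2], numeric(1)),
    size_deg = vapply(fits, function(f) f$sizeDeg, numeric(1)),
    r_squared = vapply(fits, function(f) f$rSquared, numeric(1)))
  good <- is.finite(tab$r_squared) & tab$r_squared > r2Min
  center <- if (any(good)) c(mean(tab$x[good]), mean(tab$y[good]))
            else c(NA_real_, NA_real_)
  list(table = tab, arrayCenter = center, wellFitted = which(good))
}

#' Trial-averaged PSTH for one electrode
#'
#' @param session a \linkS4class{SessionData}
#' @param electrode electrode id
#' @param binMs histogram bin width in ms
#' @param trials optional trial ids to restrict to
#' @return list with \code{times} (bin centres, ms) and \code{rate} (sp/s)
#' @export
sessionPsth <- function(session, electrode, binMs = 10, trials = NULL) {
  ev <- session@events
  keep <- ev$electrode_id == electrode
  if (!is.null(trials)) keep <- keep & ev$trial_id %in% trials
  tt <- ev$time_ms[keep]
  edges <- seq(session@windowMs[1], session@windowMs[2], by = binMs)
  counts <- tabulate(findInterval(tt, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  nTrials <- if (is.null(trials)) nrow(session@trials) else length(trials)
  list(times = edges[-length(edges)] + binMs / 2,
       rate = counts / nTrials / (binMs / 1000))
}
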