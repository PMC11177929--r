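#' Define early and late training stages
#'
#' The early stage is the shortest prefix of sessions whose cumulative
#' correct-trial count reaches \code{earlyTrials}. The late stage is the
#' longest suffix whose running mean accuracy stays at or above
#' \code{lateThreshold}, walking backward from the final session; the first
#' session whose inclusion drops the mean below threshold is excluded unless
#' \code{includeBreakingSession} is set.
#'
#' @param accuracy per-session accuracy, in session order
#' @param nCorrect per-session correct-trial counts
#' @param earlyTrials correct trials the early stage must cover, default 1000
#' @param lateThreshold running-mean accuracy criterion, default 0.90
#' @param includeBreakingSession include the accuracy-dropping session
#' @return list with \code{early}, \code{late} (session indices),
#'   \code{overlap}, \code{lateEmpty}
#' @export
defineStages <- function(accuracy, nCorrect, earlyTrials = 1000,
                         lateThreshold = 0.90,
                         includeBreakingSession = FALSE) {
  stopifnot(length(accuracy) == length(nCorrect))
  n <- length(accuracy)
  if (n < 2L) stop("need at least 2 sessions")
  if (sum(nCorrect) < earlyTrials)
    stop(sprintf("total correct trials (%d) below the early-stage requirement (%d)",
                 sum(nCorrect), earlyTrials))
  early <- seq_len(which(cumsum(nCorrect) >= earlyTrials)[1])
  lateStart <- NA_integer_
  for (k in n:1) {
    if (mean(accuracy[k:n]) >= lateThreshold) lateStart <- k else break
  }
  lateEmpty <- is.na(lateStart)
  if (!lateEmpty && includeBreakingSession && lateStart > 1L)
    lateStart <- lateStart - 1L
  late <- if (lateEmpty) integer(0) else seq.int(lateStart, n)
  if (lateEmpty)
    warning("no suffix reaches the late-stage accuracy criterion; late stage empty")
  overlap <- length(intersect(early, late)) > 0
  if (overlap)
    warning("early and late stages overlap (short experiment)")
  list(early = early, late = late, overlap = overlap, lateEmpty = lateEmpty)
}

#' Select antagonistic condition pairings across two tasks
#'
#' Pairs the condition with the strongest population delay response in task
#' A with the weakest in task B, and vice versa (the association-task design
#' in which the preferred grating is paired with the anti-preferred color).
#' Ties are flagged and broken by condition-label order.
#'
#' @param delayMeansA,delayMeansB named vectors of population mean delay
#'   rates per condition for the two source tasks
#' @return list with \code{pairs} (data.frame of two rows) and \code{tied}
#' @export
selectAntagonisticPairs <- function(delayMeansA, delayMeansB) {
  a <- delayMeansA[order(names(delayMeansA))]
  b <- delayMeansB[order(names(delayMeansB))]
  tied <- (sum(a == max(a)) > 1) || (sum(a == min(a)) > 1) ||
    (sum(b == max(b)) > 1) || (sum(b == min(b)) > 1)
  if (tied) warning("ties in delay means; broken by condition-label order")
  pairs <- data.frame(
    task_a = c(names(a)[which.max(a)], names(a)[which.min(a)]),
    task_b = c(names(b)[which.min(b)], names(b)[which.max(b)]),
    stringsAsFactors = FALSE)
  list(pairs = pairs, tied = tied)
}

#' Stagewise CMI contrast with fixed early-stage designation
#'
#' Designates the h/l pair on the early-stage rates and holds it fixed for
#' the late stage, the congruent control task (CCT) and the other-content
#' control (OOT), so that a sign reversal in the late stage reflects a true
#' ranking reversal. Returns per-electrode CMIs and the |dCMI| of each stage
#' against both controls. Electrodes invalid in any dataset are dropped.
#'
#' @param ratesEarly,ratesLate,ratesCct,ratesOot trial x electrode rate
#'   matrices (later-delay window) with \code{labels} attributes
#' @param labelsEarly,labelsLate,labelsCct,labelsOot condition labels
#'   (default: each matrix's attribute)
#' @return data.frame with per-electrode \code{cmi_early}, \code{cmi_late},
#'   \code{cmi_cct}, \code{cmi_oot}, \code{dcmi_early_cct},
#'   \code{dcmi_late_cct}, \code{dcmi_early_oot}, \code{dcmi_late_oot};
#'   attribute \code{dropped} lists excluded electrodes
#' @export
stageCmiContrast <- function(ratesEarly, ratesLate, ratesCct, ratesOot,
                             labelsEarly = attr(ratesEarly, "labels"),
                             labelsLate = attr(ratesLate, "labels"),
                             labelsCct = attr(ratesCct, "labels"),
                             labelsOot = attr(ratesOot, "labels")) {
  hl <- designateHl(ratesEarly, labelsEarly)
  ce <- computeCmi(ratesEarly, labelsEarly, hl)
  cl <- computeCmi(ratesLate, labelsLate, hl)
  cc <- computeCmi(ratesCct, labelsCct, hl)
  co <- computeCmi(ratesOot, labelsOot, hl)
  ok <- ce$valid & cl$valid & cc$valid & co$valid
  out <- data.frame(
    electrode_id = ce$electrode_id[ok],
    cmi_early = ce$cmi[ok], cmi_late = cl$cmi[ok],
    cmi_cct = cc$cmi[ok], cmi_oot = co$cmi[ok])
  out$dcmi_early_cct <- deltaCmiAbs(out$cmi_early, out$cmi_cct)
  out$dcmi_late_cct <- deltaCmiAbs(out$cmi_late, out$cmi_cct)
  out$dcmi_early_oot <- deltaCmiAbs(out$cmi_early, out$cmi_oot)
  out$dcmi_late_oot <- deltaCmiAbs(out$cmi_late, out$cmi_oot)
  attr(out, "dropped") <- ce$electrode_id[!ok]
  out
}

#' PCA trajectory of CMI time courses
#'
#' Fits principal components on a pooled electrode x time CMI matrix
#' (per-electrode means over time removed first), projects any number of
#' datasets onto the first three components, then linearly interpolates each
#' trajectory onto a fine grid and smooths it with a 100-ms boxcar.
#' Statistics should always be computed on the raw electrode values, not on
#' these smoothed projections.
#'
#' @param cmiMatrix electrode x time matrix the components are fitted on
#' @param timesMs time axis of the matrix, ms
#' @param project named list of electrode x time matrices to project
#'   (defaults to the fitting matrix itself)
#' @param smoothMs boxcar width after projection, default 100
#' @param interpMs interpolation grid step, default 10
#' @param nComponents components retained, default 3
#' @return list with \code{trajectories} (named list of data.frames with
#'   time and pc columns), \code{varianceFractions}, \code{rotation},
#'   \code{center}
#' @export
cmiTrajectoryPca <- function(cmiMatrix, timesMs, project = NULL,
                             smoothMs = 100, interpMs = 10,
                             nComponents = 3) {
  cmiMatrix <- as.matrix(cmiMatrix)
  if (nrow(cmiMatrix) < nComponents)
    stop(sprintf("need at least %d electrodes", nComponents))
  stopifnot(ncol(cmiMatrix) == length(timesMs))
  center <- rowMeans(cmiMatrix)
  xc <- cmiMatrix - center
  sv <- svd(xc)
  varFrac <- sv$d^2 / sum(sv$d^2)
  rot <- sv$u[, seq_len(nComponents), drop = FALSE]  # electrode loadings
  if (is.null(project)) project <- list(fit = cmiMatrix)
  grid <- seq(min(timesMs), max(timesMs), by = interpMs)
  traj <- lapply(project, function(y) {
    stopifnot(nrow(y) == nrow(cmiMatrix))
    pcs <- t(rot) %*% (as.matrix(y) - center)     # nComponents x time
    sm <- vapply(seq_len(nComponents), function(k) {
      z <- approx(timesMs, pcs[k, ], xout = grid)$y
      boxcarSmooth(z, smoothMs / interpMs)
    }, numeric(length(grid)))
    out <- data.frame(time = grid, sm)
    names(out) <- c("time", sprintf("pc%d", seq_len(nComponents)))
    out
  })
  list(trajectories = traj, varianceFractions = varFrac, rotation = rot,
       center = center)
}
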