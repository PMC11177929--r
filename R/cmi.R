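#' Trial-by-electrode firing rates in an epoch
#'
#' Counts spikes in the half-open window \code{[epoch[1], epoch[2])} and
#' divides by its duration, giving sp/s. Rows follow trial order; columns
#' are electrodes 1..nElectrodes.
#'
#' @param session a \linkS4class{SessionData}
#' @param epoch interval \code{c(start, end)} in ms relative to cue onset
#' @param correctOnly restrict to correct trials
#' @return numeric matrix (trials x electrodes) with the trial ids as
#'   rownames and attribute \code{labels} giving each row's condition
#' @export
epochRates <- function(session, epoch, correctOnly = FALSE) {
  epoch <- checkInterval(epoch)
  if (epoch[1] < session@windowMs[1] || epoch[2] > session@windowMs[2])
    stop("epoch must lie within the recording window")
  tr <- session@trials
  if (correctOnly) tr <- tr[tr$correct, , drop = FALSE]
  nE <- nElectrodes(session)
  ev <- session@events
  keep <- ev$time_ms >= epoch[1] & ev$time_ms < epoch[2] &
    ev$trial_id %in% tr$trial_id
  counts <- table(factor(ev$trial_id[keep], levels = tr$trial_id),
                  factor(ev$electrode_id[keep], levels = seq_len(nE)))
  rates <- matrix(as.numeric(counts), nrow(tr), nE) / (diff(epoch) / 1000)
  rownames(rates) <- as.character(tr$trial_id)
  colnames(rates) <- sprintf("e%d", seq_len(nE))
  attr(rates, "labels") <- as.character(tr$condition)
  rates
}

#' Designate the highest/lowest firing conditions per electrode
#'
#' For every electrode, the conditions with the highest and lowest average
#' firing rate (the h/l pair). Ties are broken by condition-label order and
#' flagged.
#'
#' @param rates trial x electrode rate matrix
#' @param labels condition label per trial (defaults to the matrix's
#'   \code{labels} attribute)
#' @return data.frame with columns \code{electrode_id}, \code{cond_high},
#'   \code{cond_low}, \code{tied}
#' @export
designateHl <- function(rates, labels = attr(rates, "labels")) {
  labels <- as.character(labels)
  conds <- sort(unique(labels))
  if (length(conds) < 2L) stop("need at least 2 conditions to designate h/l")
  cm <- conditionMeans(rates, labels)   # conditions (sorted) x electrodes
  hi <- apply(cm, 2, which.max)         # first index on ties = label order
  lo <- apply(cm, 2, which.min)
  tied <- vapply(seq_len(ncol(cm)), function(j) {
    v <- cm[, j]
    sum(v == max(v)) > 1L || sum(v == min(v)) > 1L
  }, logical(1))
  data.frame(electrode_id = seq_len(ncol(rates)),
             cond_high = conds[hi], cond_low = conds[lo], tied = tied,
             stringsAsFactors = FALSE)
}

#' Content modulation index per electrode
#'
#' \code{CMI = (FR_high - FR_low) / (FR_high + FR_low)} where the two rates
#' are the mean firing of the designated high and low conditions. The
#' designation may come from another dataset or epoch; the minuend and
#' subtrahend roles are preserved regardless of which condition actually
#' fires more, so a negative CMI signals a ranking reversal. Electrodes with
#' zero rate sum return \code{NA} and are marked invalid.
#'
#' @param rates trial x electrode rate matrix
#' @param labels condition label per trial
#' @param hl h/l designation as returned by \code{\link{designateHl}}
#'   (possibly computed on other data)
#' @return data.frame with \code{electrode_id}, \code{cmi}, \code{cond_high},
#'   \code{cond_low}, \code{n_high}, \code{n_low}, \code{valid}
#' @export
computeCmi <- function(rates, labels = attr(rates, "labels"), hl = NULL) {
  labels <- as.character(labels)
  if (is.null(hl)) hl <- designateHl(rates, labels)
  conds <- sort(unique(labels))
  if (!all(hl$cond_high %in% conds) || !all(hl$cond_low %in% conds))
    stop("h/l designation refers to conditions absent from this dataset")
  cm <- conditionMeans(rates, labels)
  nPer <- table(factor(labels, levels = conds))
  frH <- cm[cbind(match(hl$cond_high, conds), hl$electrode_id)]
  frL <- cm[cbind(match(hl$cond_low, conds), hl$electrode_id)]
  s <- frH + frL
  cmi <- ifelse(s > 0, (frH - frL) / s, NA_real_)
  data.frame(electrode_id = hl$electrode_id, cmi = cmi,
             cond_high = hl$cond_high, cond_low = hl$cond_low,
             n_high = as.integer(nPer[hl$cond_high]),
             n_low = as.integer(nPer[hl$cond_low]),
             valid = s > 0, stringsAsFactors = FALSE)
}

#' Cross-validated CMI for correct, incorrect and fixation trials
#'
#' Per iteration, a random \code{1/k} of the correct trials (per condition)
#' is held back; the h/l pair is designated on the remaining correct trials
#' and evaluated on the held-back portion and on trial-number-matched random
#' subsets of the incorrect and fixation trials. When the incorrect set is
#' smaller than 5\% of the correct+incorrect total, the held-back fraction is
#' adapted to the incorrect:correct ratio so the evaluation sets stay
#' matched. Values are averaged over \code{iters} iterations.
#'
#' The held-out designation removes the selection (max minus min) bias that a
#' self-designated CMI carries on finite data; under a null simulation the
#' averaged cross-validated CMI is centred on zero.
#'
#' @param ratesCorrect trial x electrode rates of correct memory trials
#' @param labelsCorrect their condition labels
#' @param ratesIncorrect,labelsIncorrect optional incorrect-trial set
#' @param ratesFixation,labelsFixation optional fixation-task set
#' @param k fold count, default 20
#' @param iters iterations to average, default 200
#' @param seed integer seed
#' @return list of per-set data.frames (\code{correct}, \code{incorrect},
#'   \code{fixation}) with per-electrode mean CMI, plus \code{kEffective}
#' @export
cmiCrossval <- function(ratesCorrect, labelsCorrect = attr(ratesCorrect, "labels"),
                        ratesIncorrect = NULL, labelsIncorrect = NULL,
                        ratesFixation = NULL, labelsFixation = NULL,
                        k = 20, iters = 200, seed = 1) {
  labelsCorrect <- as.character(labelsCorrect)
  conds <- sort(unique(labelsCorrect))
  nE <- ncol(ratesCorrect)
  heldFrac <- 1 / k
  if (!is.null(ratesIncorrect)) {
    nInc <- nrow(ratesIncorrect); nCor <- nrow(ratesCorrect)
    if (nInc > 0 && nInc / (nInc + nCor) < 0.05)
      heldFrac <- max(nInc / nCor, 1 / nCor)
  }
  idxByCond <- split(seq_along(labelsCorrect), labelsCorrect)
  evalSet <- function(rates, labels, hl, matchedN) {
    if (is.null(rates)) return(NULL)
    labels <- as.character(labels)
    sub <- unlist(lapply(conds, function(cc) {
      pool <- which(labels == cc)
      m <- min(matchedN[[cc]], length(pool))
      if (m < matchedN[[cc]])
        warning(sprintf("set smaller than matched size for condition %s; using %d trials",
                        cc, m), call. = FALSE)
      sample(pool, m)
    }), use.names = FALSE)
    computeCmi(rates[sub, , drop = FALSE], labels[sub], hl)$cmi
  }
  withSeed(seed, {
    acc <- list(correct = matrix(0, iters, nE), incorrect = matrix(NA_real_, iters, nE),
                fixation = matrix(NA_real_, iters, nE))
    for (it in seq_len(iters)) {
      held <- lapply(idxByCond, function(ii)
        sample(ii, max(1L, round(heldFrac * length(ii)))))
      heldIdx <- unlist(held, use.names = FALSE)
      trainIdx <- setdiff(seq_along(labelsCorrect), heldIdx)
      hl <- designateHl(ratesCorrect[trainIdx, , drop = FALSE],
                        labelsCorrect[trainIdx])
      matchedN <- lapply(held, length)
      acc$correct[it, ] <- computeCmi(ratesCorrect[heldIdx, , drop = FALSE],
                                      labelsCorrect[heldIdx], hl)$cmi
      v <- evalSet(ratesIncorrect, labelsIncorrect, hl, matchedN)
      if (!is.null(v)) acc$incorrect[it, ] <- v
      v <- evalSet(ratesFixation, labelsFixation, hl, matchedN)
      if (!is.null(v)) acc$fixation[it, ] <- v
    }
    mk <- function(m) data.frame(electrode_id = seq_len(nE),
                                 cmi = colMeans(m, na.rm = TRUE))
    list(correct = mk(acc$correct),
         incorrect = if (!is.null(ratesIncorrect)) mk(acc$incorrect),
         fixation = if (!is.null(ratesFixation)) mk(acc$fixation),
         kEffective = 1 / heldFrac, iters = iters, seed = seed)
  })
}

#' Absolute CMI difference
#'
#' \code{|CMI_a - CMI_b|}, the distance between content modulation in two
#' datasets (e.g. an association-task stage and the color control task).
#' \code{NA} propagates.
#'
#' @param cmiA,cmiB CMI values (vectors recycle)
#' @return non-negative values, \code{NA} where either input is invalid
#' @export
deltaCmiAbs <- function(cmiA, cmiB) abs(cmiA - cmiB)

#' Normalize a PSTH to its stimulus peak
#'
#' Subtracts the spontaneous mean and divides by the peak stimulus response
#' above that mean, so the spontaneous level maps to 0 and the stimulus peak
#' to 1.
#'
#' @param psth rate series, sp/s
#' @param times bin centres, ms
#' @param spontaneousWindow,stimulusWindow intervals in ms
#' @return normalized series
#' @export
normalizeResponse <- function(psth, times, spontaneousWindow = c(-150, 0),
                              stimulusWindow = c(0, 200)) {
  m0 <- mean(psth[times >= spontaneousWindow[1] & times < spontaneousWindow[2]])
  peak <- max(psth[times >= stimulusWindow[1] & times < stimulusWindow[2]])
  if (!is.finite(peak - m0) || peak - m0 <= 0)
    stop("peak stimulus response must exceed the spontaneous mean")
  (psth - m0) / (peak - m0)
}

#' Spearman correlation of condition rankings between two epochs
#'
#' Per electrode, the rank correlation between the per-condition mean rates
#' of two epochs; a value near 0 indicates that the delay-period condition
#' ranking is unrelated to the stimulus-period ranking.
#'
#' @param ratesA,ratesB trial x electrode rate matrices for the two epochs
#'   (same trials)
#' @param labels condition label per trial
#' @return numeric vector, one rho per electrode
#' @export
epochRankCorrelation <- function(ratesA, ratesB,
                                 labels = attr(ratesA, "labels")) {
  labels <- as.character(labels)
  conds <- sort(unique(labels))
  if (length(conds) < 3L) stop("need at least 3 conditions for a rank correlation")
  cmA <- conditionMeans(ratesA, labels)
  cmB <- conditionMeans(ratesB, labels)
  vapply(seq_len(ncol(cmA)), function(j)
    suppressWarnings(cor(cmA[, j], cmB[, j], method = "spearman")),
    numeric(1))
}

#' Trial-by-trial response correlation between two epochs
#'
#' Pearson correlation over trials between the two epochs' rates, computed
#' within each condition and then averaged, which prevents condition-mean
#' differences from inducing a spurious correlation. Electrode/condition
#' cells with zero variance are dropped from the average.
#'
#' @param ratesA,ratesB trial x electrode rate matrices (same trials)
#' @param labels condition label per trial
#' @return numeric vector, one r per electrode (NA when no condition had
#'   variance in both epochs)
#' @export
epochResponseCorrelation <- function(ratesA, ratesB,
                                     labels = attr(ratesA, "labels")) {
  labels <- as.character(labels)
  if (nrow(ratesA) < 10L) stop("need at least 10 trials")
  conds <- sort(unique(labels))
  vapply(seq_len(ncol(ratesA)), function(j) {
    rs <- vapply(conds, function(cc) {
      i <- labels == cc
      a <- ratesA[i, j]; b <- ratesB[i, j]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
    if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
  }, numeric(1))
}
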