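#' Sliding analysis windows
#'
#' Half-open windows \code{[s, s+width)} for \code{s = start, start+step,
#' ...} while \code{s + width <= end}.
#'
#' @param tRange interval \code{c(start, end)} in ms
#' @param width window width in ms, default 200
#' @param step step size in ms, default 50
#' @return data.frame with columns \code{start}, \code{end}
#' @export
makeWindows <- function(tRange, width = 200, step = 50) {
  tRange <- checkInterval(tRange)
  if (step <= 0) stop("step must be > 0")
  if (width > diff(tRange)) stop("width exceeds the span of tRange")
  starts <- seq(tRange[1], tRange[2] - width, by = step)
  data.frame(start = starts, end = starts + width)
}

# Spike counts per trial x electrode x window. Windows may overlap; when
# they align to a common step grid the counts are assembled from step-sized
# sub-bins, otherwise each window is counted directly.
windowCounts <- function(session, windows, correctOnly = TRUE) {
  tr <- session@trials
  if (correctOnly) tr <- tr[tr$correct, , drop = FALSE]
  nE <- nElectrodes(session)
  nT <- nrow(tr)
  nW <- nrow(windows)
  ev <- session@events[session@events$trial_id %in% tr$trial_id, , drop = FALSE]
  trialIdx <- match(ev$trial_id, tr$trial_id)
  out <- array(0, dim = c(nT, nE, nW))
  steps <- unique(round(diff(sort(unique(windows$start))), 9))
  aligned <- FALSE
  if (nW > 1L && length(steps) == 1L && steps[1] > 0) {
    step <- steps[1]
    aligned <- all(abs((windows$end - windows$start) %% step) < 1e-9)
  }
  if (aligned) {
    edges <- seq(min(windows$start), max(windows$end), by = step)
    nS <- length(edges) - 1L
    sub <- findInterval(ev$time_ms, edges, rightmost.closed = FALSE)
    ok <- sub >= 1L & sub <= nS & ev$time_ms < max(windows$end)
    lin <- (sub[ok] - 1L) * nT * nE + (ev$electrode_id[ok] - 1L) * nT +
      trialIdx[ok]
    subCounts <- array(tabulate(lin, nbins = nT * nE * nS), c(nT, nE, nS))
    for (w in seq_len(nW)) {
      i0 <- which(abs(edges - windows$start[w]) < 1e-9)
      i1 <- which(abs(edges - windows$end[w]) < 1e-9) - 1L
      out[, , w] <- if (i1 > i0)
        rowSums(subCounts[, , i0:i1, drop = FALSE], dims = 2)
      else subCounts[, , i0]
    }
  } else {
    for (w in seq_len(nW)) {
      inw <- ev$time_ms >= windows$start[w] & ev$time_ms < windows$end[w]
      lin <- (ev$electrode_id[inw] - 1L) * nT + trialIdx[inw]
      out[, , w] <- matrix(tabulate(lin, nbins = nT * nE), nT, nE)
    }
  }
  attr(out, "labels") <- as.character(tr$condition)
  attr(out, "trial_id") <- tr$trial_id
  out
}

#' Batch trials for population decoding
#'
#' Averages the spike counts of \code{batchSize} adjacent (acquisition-order)
#' same-condition trials into one batch per window. The final partial run of
#' each condition is dropped, so a condition with \code{n} trials yields
#' \code{floor(n / batchSize)} batches.
#'
#' @param session a \linkS4class{SessionData}
#' @param windows window grid from \code{\link{makeWindows}}
#' @param batchSize trials per batch, default 20
#' @param correctOnly use only correct trials, default TRUE
#' @return list with \code{counts} (batch x electrode x window array of mean
#'   spike counts), \code{condition} per batch, \code{windows},
#'   \code{batchSize}
#' @export
makeBatches <- function(session, windows, batchSize = 20, correctOnly = TRUE) {
  counts <- windowCounts(session, windows, correctOnly)
  labels <- attr(counts, "labels")
  conds <- sort(unique(labels))
  perCond <- table(factor(labels, levels = conds))
  if (any(perCond < batchSize))
    stop(sprintf("condition %s has fewer than %d trials",
                 names(perCond)[which.min(perCond)], batchSize))
  batchIdx <- list(); batchCond <- character()
  for (cc in conds) {
    ii <- which(labels == cc)              # acquisition order within condition
    nb <- length(ii) %/% batchSize
    for (b in seq_len(nb)) {
      batchIdx[[length(batchIdx) + 1L]] <- ii[((b - 1L) * batchSize + 1L):(b * batchSize)]
      batchCond <- c(batchCond, cc)
    }
  }
  out <- array(0, dim = c(length(batchIdx), dim(counts)[2], dim(counts)[3]))
  for (b in seq_along(batchIdx))
    out[b, , ] <- colMeans(counts[batchIdx[[b]], , , drop = FALSE], dims = 1)
  list(counts = out, condition = batchCond, windows = windows,
       batchSize = batchSize)
}

#' Fit the Poisson-independent-decoder tuning function
#'
#' The tuning \code{f_i(theta)} is the mean spike count of electrode
#' \code{i} over the training batches of condition \code{theta} in the given
#' window, floored at \code{floor} to keep its logarithm finite.
#'
#' @param batches a batch set from \code{\link{makeBatches}}
#' @param windowIndex index into the window grid
#' @param batchIdx optional subset of batches to train on
#' @param floor tuning floor, default 0.01
#' @return conditions x electrodes matrix of floored mean counts
#' @export
fitPid <- function(batches, windowIndex, batchIdx = NULL, floor = 0.01) {
  if (is.null(batchIdx)) batchIdx <- seq_along(batches$condition)
  labels <- batches$condition[batchIdx]
  conds <- sort(unique(batches$condition))
  if (!all(conds %in% labels)) stop("a condition has no training batch")
  x <- matrix(batches$counts[batchIdx, , windowIndex],
              length(batchIdx), dim(batches$counts)[2])
  pmax(conditionMeans(x, labels), floor)
}

#' Decode content with the Poisson independent decoder
#'
#' Log-likelihood \code{log L(theta) = sum_i n_i log f_i(theta) - sum_i
#' f_i(theta)}; the second (bias) term is the summed tuning function. The
#' predicted condition is the argmax; exact ties are broken uniformly at
#' random.
#'
#' @param tuning conditions x electrodes tuning matrix from
#'   \code{\link{fitPid}}
#' @param counts electrode count vector, or electrodes x tests matrix
#' @param seed optional seed for tie-breaking
#' @return list with \code{predicted} (condition labels) and \code{logLik}
#'   (conditions x tests matrix)
#' @export
pidDecode <- function(tuning, counts, seed = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(tuning)) {
    if (ncol(counts) == ncol(tuning)) counts <- t(counts)
    else stop("counts must share the tuning's electrode set")
  }
  if (any(counts < 0)) stop("negative counts")
  logL <- log(tuning) %*% counts - rowSums(tuning)
  pick <- function() max.col(t(logL), ties.method = "random")
  idx <- if (is.null(seed)) pick() else withSeed(seed, pick())
  list(predicted = rownames(tuning)[idx], logLik = logL)
}

#' Cross-temporal generalization matrix
#'
#' Per repetition, \code{trainPerCondition} batches per condition are drawn
#' as the training set and the rest form the test set; for every training
#' window the tuning function is fitted and applied to every test window.
#' The cell (train w1, test w2) holds the fraction of test batches decoded
#' correctly, averaged over repetitions.
#'
#' @param batches batch set from \code{\link{makeBatches}}
#' @param trainPerCondition training batches per condition, default 15
#' @param repetitions random splits to average, default 1000
#' @param floor tuning floor, default 0.01
#' @param seed integer seed
#' @param shuffleLabels permute the batch condition labels first (chance
#'   calibration)
#' @return a \linkS4class{DecodingMatrix}
#' @export
crossTemporalMatrix <- function(batches, trainPerCondition = 15,
                                repetitions = 1000, floor = 0.01, seed = 1,
                                shuffleLabels = FALSE) {
  labels <- batches$condition
  conds <- sort(unique(labels))
  nW <- dim(batches$counts)[3]
  perCond <- table(factor(labels, levels = conds))
  if (any(perCond <= trainPerCondition))
    stop(sprintf("condition %s has only %d batches; need > %d",
                 names(perCond)[which.min(perCond)], min(perCond),
                 trainPerCondition))
  withSeed(seed, {
    if (shuffleLabels) labels <- sample(labels)
    acc <- matrix(0, nW, nW)
    for (rep in seq_len(repetitions)) {
      trainIdx <- unlist(lapply(conds, function(cc)
        sample(which(labels == cc), trainPerCondition)), use.names = FALSE)
      testIdx <- setdiff(seq_along(labels), trainIdx)
      truth <- labels[testIdx]
      nTest <- length(testIdx)
      # electrodes x (test-batch, window) stack of test counts
      testMat <- matrix(aperm(batches$counts[testIdx, , , drop = FALSE],
                              c(2, 1, 3)), dim(batches$counts)[2])
      trainLab <- labels[trainIdx]
      trainX <- batches$counts[trainIdx, , , drop = FALSE]
      for (w1 in seq_len(nW)) {
        f <- pmax(conditionMeans(matrix(trainX[, , w1], dim(trainX)[1],
                                        dim(trainX)[2]), trainLab), floor)
        logL <- log(f) %*% testMat - rowSums(f)
        pred <- conds[max.col(t(logL), ties.method = "random")]
        hit <- matrix(pred == rep(truth, times = nW), nTest, nW)
        acc[w1, ] <- acc[w1, ] + colMeans(hit)
      }
    }
    new("DecodingMatrix", accuracy = acc / repetitions,
        windows = batches$windows, nRepetitions = as.integer(repetitions),
        chance = 1 / length(conds),
        meta = list(trainPerCondition = trainPerCondition, seed = seed,
                    batchSize = batches$batchSize,
                    shuffled = shuffleLabels))
  })
}

#' Permutation test for decoding accuracy
#'
#' Builds a null by permuting condition labels across batches and
#' recomputing the cross-temporal accuracy grid; the one-tailed p-value per
#' cell is \code{(1 + #(null >= observed)) / (1 + nPerm)}.
#'
#' @param batches batch set from \code{\link{makeBatches}}
#' @param nPerm number of permutations, at least 99
#' @param repetitions splits averaged per grid (observed and each
#'   permutation)
#' @param trainPerCondition,floor passed to \code{\link{crossTemporalMatrix}}
#' @param seed integer seed
#' @param observed optional precomputed observed \code{DecodingMatrix}
#' @return list with \code{p} (matrix), \code{observed}, \code{null}
#'   (nPerm x train x test array)
#' @export
permutationNullPid <- function(batches, nPerm = 99, repetitions = 20,
                               trainPerCondition = 15, floor = 0.01,
                               seed = 1, observed = NULL) {
  if (nPerm < 99) stop("nPerm must be at least 99")
  if (is.null(observed))
    observed <- crossTemporalMatrix(batches, trainPerCondition, repetitions,
                                    floor, seed = childSeed(seed, 0L))
  obs <- accuracyMatrix(observed)
  nW <- nrow(obs)
  null <- array(NA_real_, c(nPerm, nW, nW))
  for (p in seq_len(nPerm)) {
    m <- crossTemporalMatrix(batches, trainPerCondition, repetitions, floor,
                             seed = childSeed(seed, p), shuffleLabels = TRUE)
    null[p, , ] <- accuracyMatrix(m)
  }
  ge <- apply(sweep(null, c(2, 3), obs, ">="), c(2, 3), sum)
  list(p = (1 + ge) / (1 + nPerm), observed = observed, null = null)
}

#' Cross-task linear-classifier harness
#'
#' Trains a linear support-vector classifier on window-averaged rates of one
#' task and evaluates it on another whose conditions are paired to the
#' training conditions via \code{conditionMap}. Per iteration,
#' \code{nPerCondition} trials per condition are drawn from each task. The
#' regularization cost is chosen once from a small logarithmic grid by 2-fold
#' cross-validation on the first training draw, keeping the harness
#' deterministic under the seed.
#'
#' @param trainRates,trainLabels training trial x electrode rates and labels
#' @param testRates,testLabels test-task rates and labels
#' @param conditionMap named character vector mapping each test-task label to
#'   the training label it is associated with (identity when NULL)
#' @param nPerCondition trials drawn per condition per iteration, default 300
#' @param iters iterations, default 100
#' @param costGrid costs searched, default \code{10^(-1:1)}
#' @param seed integer seed
#' @return list with \code{accuracy} (vector of per-iteration accuracies),
#'   \code{cost}, \code{chance}
#' @export
svmCrossTask <- function(trainRates, trainLabels, testRates, testLabels,
                         conditionMap = NULL, nPerCondition = 300,
                         iters = 100, costGrid = 10^(-1:1), seed = 1) {
  trainLabels <- as.character(trainLabels)
  testLabels <- as.character(testLabels)
  trainConds <- sort(unique(trainLabels))
  testConds <- sort(unique(testLabels))
  if (is.null(conditionMap)) conditionMap <- setNames(testConds, testConds)
  if (!all(testConds %in% names(conditionMap)))
    stop(sprintf("unmapped test condition: %s",
                 setdiff(testConds, names(conditionMap))[1]))
  if (!all(conditionMap[testConds] %in% trainConds))
    stop("conditionMap targets a condition absent from the training task")
  drawIdx <- function(labels, conds) unlist(lapply(conds, function(cc) {
    pool <- which(labels == cc)
    sample(pool, min(nPerCondition, length(pool)))
  }), use.names = FALSE)
  withSeed(seed, {
    ti <- drawIdx(trainLabels, trainConds)
    xs <- trainRates[ti, , drop = FALSE]
    ys <- factor(trainLabels[ti], levels = trainConds)
    half <- sample(seq_along(ti), floor(length(ti) / 2))
    cvAcc <- vapply(costGrid, function(cost) {
      fit <- e1071::svm(xs[half, , drop = FALSE], ys[half], kernel = "linear",
                        cost = cost, scale = FALSE)
      mean(predict(fit, xs[-half, , drop = FALSE]) == ys[-half])
    }, numeric(1))
    bestCost <- costGrid[which.max(cvAcc)]
    acc <- numeric(iters)
    for (it in seq_len(iters)) {
      ti <- drawIdx(trainLabels, trainConds)
      fit <- e1071::svm(trainRates[ti, , drop = FALSE],
                        factor(trainLabels[ti], levels = trainConds),
                        kernel = "linear", cost = bestCost, scale = FALSE)
      si <- drawIdx(testLabels, testConds)
      pred <- as.character(predict(fit, testRates[si, , drop = FALSE]))
      acc[it] <- mean(pred == unname(conditionMap[testLabels[si]]))
    }
    list(accuracy = acc, cost = bestCost, chance = 1 / length(trainConds))
  })
}
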