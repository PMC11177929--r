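test_that("sliding windows tile the range as specified", {
  w <- makeWindows(c(-200, 1700))
  expect_equal(nrow(w), 35)
  expect_equal(unlist(w[1, ]), c(start = -200, end = 0))
  expect_equal(unlist(w[35, ]), c(start = 1500, end = 1700))
  expect_equal(nrow(makeWindows(c(0, 200), width = 200, step = 50)), 1)
  tiling <- makeWindows(c(0, 1000), width = 200, step = 200)
  expect_equal(tiling$start, seq(0, 800, by = 200))
  expect_error(makeWindows(c(0, 1000), step = 0), "step")
})

test_that("batching floors partial runs and averages member trials exactly", {
  cfg <- flatConfig(nElectrodes = 2, nTrials = 25, seed = 71,
                    windowMs = c(0, 400))
  s <- simulateSession(cfg)
  w <- makeWindows(c(0, 400), 200, 200)
  b <- makeBatches(s, w, batchSize = 10)
  expect_equal(table(b$condition)[["c1"]], 2)   # floor(25/10)
  # brute-force oracle: average raw per-trial counts of the batch members
  counts <- wmv1:::windowCounts(s, w)
  lab <- attr(counts, "labels")
  first <- which(lab == "c1")[1:10]
  expect_equal(b$counts[1, , ], colMeans(counts[first, , ]), tolerance = 1e-12)
  expect_error(makeBatches(s, w, batchSize = 30), "fewer than")
})

test_that("tuning equals per-condition means with the floor applied", {
  b <- list(counts = array(c(2, 2, 4, 4, 0, 0, 3, 3), c(4, 2, 1)),
            condition = c("t1", "t1", "t2", "t2"),
            windows = data.frame(start = 0, end = 200), batchSize = 1)
  f <- fitPid(b, 1, floor = 0.01)
  expect_equal(f, rbind(t1 = c(2, 0.01), t2 = c(4, 3)))
})

test_that("the decoder log-likelihood matches direct evaluation", {
  t1 <- rbind(t1 = 2, t2 = 4)
  r1 <- pidDecode(t1, 3)
  expect_equal(unname(r1$logLik[, 1]),
               c(3 * log(2) - 2, 3 * log(4) - 4), tolerance = 1e-12)
  expect_equal(r1$predicted, "t2")
  t2 <- rbind(t1 = c(4, 2), t2 = c(2, 4))
  r2 <- pidDecode(t2, c(4, 2))
  expect_equal(unname(r2$logLik[, 1]),
               c(4 * log(4) + 2 * log(2) - 6, 4 * log(2) + 2 * log(4) - 6),
               tolerance = 1e-12)
  expect_equal(r2$predicted, "t1")
  expect_error(pidDecode(t2, c(-1, 2)), "negative")
})

test_that("identical tuning across conditions yields uniform random predictions", {
  tun <- rbind(a = c(2, 3), b = c(2, 3), c = c(2, 3), d = c(2, 3))
  preds <- withr::with_seed(8, replicate(1000, pidDecode(tun, c(1, 2))$predicted))
  tab <- table(factor(preds, levels = rownames(tun))) / 1000
  se <- sqrt(0.25 * 0.75 / 1000)
  expect_true(all(abs(tab - 0.25) < 3 * se + 1e-9))
})

test_that("PID agrees exactly with a brute-force Poisson MAP oracle", {
  mismatch <- 0
  for (k in 1:1000) {
    set.seed(k)
    nC <- sample(2:4, 1); nE <- sample(1:5, 1)
    tun <- matrix(rgamma(nC * nE, 2, 0.5) + 0.01, nC, nE,
                  dimnames = list(sprintf("c%d", 1:nC), NULL))
    counts <- rpois(nE, 3)
    got <- pidDecode(tun, counts, seed = k)$predicted
    # exact likelihood ties are broken randomly; compare only clear argmaxes
    ll <- pidDecode(tun, counts)$logLik
    if (sum(abs(ll - max(ll)) < 1e-12) > 1) next
    if (got != poissonMapOracle(tun, counts)) mismatch <- mismatch + 1
  }
  expect_equal(mismatch, 0)
})

test_that("a content-uninformative electrode never changes predictions", {
  for (k in 1:50) {
    set.seed(2000 + k)
    tun <- matrix(rgamma(4 * 3, 2, 0.5) + 0.01, 4, 3,
                  dimnames = list(sprintf("c%d", 1:4), NULL))
    counts <- rpois(3, 4)
    tunAug <- cbind(tun, 2.5)           # same tuning for every condition
    expect_equal(pidDecode(tun, counts, seed = k)$predicted,
                 pidDecode(tunAug, c(counts, 7), seed = k)$predicted)
  }
})

test_that("stimulus-only tuning decodes in the stimulus epoch and not the delay", {
  cfg <- simConfig(nElectrodes = 8, nTrialsPerCondition = 200,
                   delayDelta = matrix(0, 8, 4), seed = 91)
  s <- simulateSession(cfg)
  w <- data.frame(start = c(0, 1200), end = c(200, 1400))
  b <- makeBatches(s, w, batchSize = 10)
  m <- crossTemporalMatrix(b, trainPerCondition = 15, repetitions = 50,
                           seed = 3)
  acc <- accuracyMatrix(m)
  expect_gt(acc[1, 1], 0.8)                       # strong cue tuning
  expect_lt(abs(acc[2, 2] - 0.25), 0.1)           # no delay content
  expect_lt(abs(acc[1, 2] - 0.25), 0.1)
})

test_that("label-shuffled decoding sits at chance", {
  cfg <- simConfig(nElectrodes = 6, nTrialsPerCondition = 170, seed = 95)
  s <- simulateSession(cfg)
  w <- data.frame(start = c(0, 1200), end = c(200, 1400))
  b <- makeBatches(s, w, batchSize = 10)
  m <- crossTemporalMatrix(b, repetitions = 200, seed = 4,
                           shuffleLabels = TRUE)
  acc <- accuracyMatrix(m)
  expect_true(all(abs(acc - 0.25) < 0.06))
})

test_that("on-diagonal accuracy grows with the configured delay effect", {
  accAt <- function(spread, seed) {
    cfg <- simConfig(nElectrodes = 8, nTrialsPerCondition = 170,
                     delayDelta = matrix(rep(spread * c(1, 0.33, -0.33, -1),
                                             each = 8), 8),
                     seed = seed)
    s <- simulateSession(cfg)
    w <- data.frame(start = 1200, end = 1400)
    b <- makeBatches(s, w, batchSize = 10)
    accuracyMatrix(crossTemporalMatrix(b, repetitions = 30, seed = seed))[1, 1]
  }
  res <- vapply(1:20, function(k)
    c(accAt(0, 3000 + k), accAt(3, 3000 + k), accAt(8, 3000 + k)),
    numeric(3))
  means <- rowMeans(res)
  expect_true(all(diff(means) > 0))
})

test_that("permutation p-values follow their definition and null is at chance", {
  cfg <- simConfig(nElectrodes = 6, nTrialsPerCondition = 170, seed = 97)
  s <- simulateSession(cfg)
  w <- data.frame(start = 0, end = 200)
  b <- makeBatches(s, w, batchSize = 10)
  pn <- permutationNullPid(b, nPerm = 99, repetitions = 10, seed = 5)
  # strong stimulus tuning: observed beats every permutation
  expect_equal(pn$p[1, 1], 1 / 100)
  expect_lt(abs(mean(pn$null) - 0.25), 3 * sd(pn$null) / sqrt(length(pn$null)))
  # an observation below every null draw has p = 1
  nullMax <- apply(pn$null, c(2, 3), max)
  ge <- sum(pn$null[, 1, 1] >= 0)
  expect_equal((1 + ge) / (1 + 99), 1)
})

test_that("the linear-classifier harness generalizes only with shared tuning", {
  delta <- matrix(rep(c(6, 2, -2, -6), each = 6), 6)
  mkRates <- function(seedv, dd) {
    cfg <- simConfig(nElectrodes = 6, nTrialsPerCondition = 120,
                     delayDelta = dd, seed = seedv)
    s <- simulateSession(cfg)
    epochRates(s, c(700, 1700))
  }
  train <- mkRates(101, delta)
  same <- mkRates(102, delta)
  res <- svmCrossTask(train, attr(train, "labels"), same,
                      attr(same, "labels"), nPerCondition = 80, iters = 20,
                      seed = 6)
  se <- sd(res$accuracy) / sqrt(length(res$accuracy))
  expect_gt(mean(res$accuracy), 0.25 + 3 * se)
  indep <- mkRates(103, delta[, c(3, 4, 2, 1)])
  res2 <- svmCrossTask(train, attr(train, "labels"), indep,
                       attr(indep, "labels"),
                       conditionMap = c(c1 = "c1", c2 = "c2", c3 = "c3",
                                        c4 = "c4"),
                       nPerCondition = 80, iters = 20, seed = 7)
  expect_lt(mean(res2$accuracy), 0.4)
  expect_error(svmCrossTask(train, attr(train, "labels"), same,
                            attr(same, "labels"),
                            conditionMap = c(c1 = "c1"), nPerCondition = 10,
                            iters = 2, seed = 1),
               "unmapped")
})
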