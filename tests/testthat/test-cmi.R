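test_that("epoch rates are spike counts over duration", {
  s <- tinySession()
  r <- epochRates(s, c(700, 1700))
  expect_equal(unname(r[, 1]), c(5, 1))        # 5 and 1 spikes in 1 s
  r2 <- epochRates(s, c(0, 200))
  expect_equal(unname(r2[, 1]), c(0, 0))
  expect_error(epochRates(s, c(500, 500)), "interval")
  cfg <- simConfig(nElectrodes = 1, nTrialsPerCondition = 125,
                   stimGain = matrix(1, 1, 4),
                   delayDelta = matrix(2, 1, 4), offResponseAmp = 0,
                   baselineRate = 10, seed = 77)
  s2 <- simulateSession(cfg)
  r3 <- epochRates(s2, c(700, 1700))
  expect_lt(abs(mean(r3) - 12), 3 * sqrt(12 / 500))
})

test_that("h/l designation picks the extreme conditions with label-order ties", {
  rates <- matrix(c(rep(10, 3), rep(6, 3), rep(8, 3), rep(7, 3)), ncol = 1)
  labels <- rep(c("A", "B", "C", "D"), each = 3)
  hl <- designateHl(rates, labels)
  expect_equal(hl$cond_high, "A")
  expect_equal(hl$cond_low, "B")
  expect_false(hl$tied)
  hlTie <- designateHl(matrix(rep(5, 12), ncol = 1), labels)
  expect_equal(hlTie$cond_high, "A")
  expect_equal(hlTie$cond_low, "A")
  expect_true(hlTie$tied)
  expect_error(designateHl(rates, rep("A", 12)), "2 conditions")
})

test_that("designation recovers configured extremes with a clear delta spread", {
  cfg <- simConfig(nElectrodes = 20, nTrialsPerCondition = 500,
                   delayDelta = matrix(rep(c(6, 2, -2, -6), each = 20), 20),
                   seed = 13)
  s <- simulateSession(cfg)
  r <- epochRates(s, c(700, 1700))
  hl <- designateHl(r)
  ok <- hl$cond_high == "c1" & hl$cond_low == "c4"
  expect_gte(mean(ok), 0.95)
})

test_that("the CMI ratio, its sign convention and invalid sentinel behave", {
  rates <- matrix(c(rep(30, 4), rep(10, 4)), ncol = 1)
  labels <- rep(c("A", "B"), each = 4)
  expect_equal(computeCmi(rates, labels)$cmi, 0.5)
  expect_equal(computeCmi(matrix(rep(5, 8), ncol = 1), labels)$cmi, 0)
  # designation carried from another dataset: roles preserved, sign flips
  hl <- data.frame(electrode_id = 1L, cond_high = "A", cond_low = "B",
                   tied = FALSE)
  swapped <- matrix(c(rep(10, 4), rep(30, 4)), ncol = 1)
  expect_equal(computeCmi(swapped, labels, hl)$cmi, -0.5)
  zero <- computeCmi(matrix(0, 8, 1), labels, hl)
  expect_true(is.na(zero$cmi))
  expect_false(zero$valid)
})

test_that("CMI is bounded and self-designation is non-negative", {
  for (k in 1:50) {
    r <- withr::with_seed(k, matrix(rgamma(40 * 3, 2, 0.2), 40, 3))
    lab <- rep(c("A", "B", "C", "D"), each = 10)
    res <- computeCmi(r, lab)
    expect_true(all(abs(res$cmi) <= 1))
    expect_true(all(res$cmi >= 0))      # h/l designated on the same data
  }
  # CMI = +-1 iff one of the two rates is zero
  lab2 <- rep(c("A", "B"), each = 2)
  r2 <- matrix(c(3, 3, 0, 0), ncol = 1)
  expect_equal(computeCmi(r2, lab2)$cmi, 1)
})

test_that("|dCMI| matches the worked electrode example and is symmetric", {
  expect_equal(deltaCmiAbs(-0.015, -0.036), 0.021)
  expect_equal(deltaCmiAbs(0.025, -0.036), 0.061)
  # late (0.021) closer to the control task than early (0.061)
  expect_lt(deltaCmiAbs(-0.015, -0.036), deltaCmiAbs(0.025, -0.036))
  expect_equal(deltaCmiAbs(0.4, 0.4), 0)
  expect_equal(deltaCmiAbs(0.2, -0.3), deltaCmiAbs(-0.3, 0.2))
  expect_true(is.na(deltaCmiAbs(NA, 0.1)))
})

test_that("response normalization maps spontaneous to 0 and the peak to 1", {
  times <- seq(-145, 1695, by = 10)
  psth <- rep(5, length(times))
  psth[times >= 0 & times < 200] <- 55
  psth[times == 705] <- 30
  norm <- normalizeResponse(psth, times)
  expect_equal(norm[times == 705], 0.5)
  expect_equal(norm[times == -95], 0)
  expect_equal(max(norm[times >= 0 & times < 200]), 1)
  expect_error(normalizeResponse(rep(5, length(times)), times), "exceed")
})

test_that("epoch rank correlation reproduces the closed-form Spearman values", {
  lab <- rep(c("A", "B", "C", "D"), each = 5)
  mk <- function(means) matrix(rep(rep(means, each = 5)), ncol = 1)
  expect_equal(epochRankCorrelation(mk(1:4), mk(c(10, 20, 30, 40)), lab), 1)
  # rankings (1,2,3,4) vs (2,1,4,3): rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(epochRankCorrelation(mk(1:4), mk(c(2, 1, 4, 3)), lab), 0.6)
  expect_error(epochRankCorrelation(mk(1:2)[1:10, , drop = FALSE],
                                    mk(1:2)[1:10, , drop = FALSE],
                                    rep(c("A", "B"), each = 5)), "3 conditions")
})

test_that("independent epoch rankings give rank correlations centred on zero", {
  rhos <- unlist(lapply(1:12, function(k) {
    s <- simulateSession(simConfig(nElectrodes = 6, nTrialsPerCondition = 100,
                                   seed = 400 + k))
    rs <- epochRates(s, c(0, 200))
    rd <- epochRates(s, c(700, 1700))
    epochRankCorrelation(rs, rd)
  }))
  expect_lt(abs(mean(rhos)), 2 * sd(rhos) / sqrt(length(rhos)))
})

test_that("trial-by-trial epoch correlation separates shared gain from independence", {
  lab <- rep(c("A", "B"), each = 30)
  r <- withr::with_seed(5, {
    a <- matrix(rpois(60 * 2, 20), 60, 2)
    b <- matrix(rpois(60 * 2, 20), 60, 2)
    list(a = a, b = b)
  })
  expect_equal(epochResponseCorrelation(r$a, r$a, lab), c(1, 1))
  rIndep <- epochResponseCorrelation(r$a, r$b, lab)
  expect_true(all(abs(rIndep) < 2 / sqrt(30) * 2))
  shared <- vapply(1:40, function(k) withr::with_seed(600 + k, {
    g <- rgamma(60, 20, 20)
    a <- matrix(rpois(60, 40 * g), 60, 1)
    b <- matrix(rpois(60, 40 * g), 60, 1)
    epochResponseCorrelation(a, b, lab)
  }), numeric(1))
  expect_gte(mean(shared > 0), 0.95)
  expect_error(epochResponseCorrelation(r$a[1:5, ], r$b[1:5, ], lab[1:5]),
               "10 trials")
})

test_that("cross-validation removes the self-designation bias under the null", {
  cfg <- flatConfig(nElectrodes = 30, nTrials = 50, seed = 51)
  s <- simulateSession(cfg)
  r <- epochRates(s, c(0, 1000))
  naive <- computeCmi(r)$cmi
  cv <- cmiCrossval(r, k = 10, iters = 100, seed = 2)$correct$cmi
  expect_gt(mean(naive), mean(cv))             # naive is positively biased
  expect_gt(mean(naive), 0)
  expect_lt(abs(mean(cv)), 2 * sd(cv) / sqrt(length(cv)))
})

test_that("cross-validated CMI orders correct > incorrect ~ fixation when only
           correct trials carry delay modulation", {
  wins <- vapply(1:25, function(k) {
    cfg <- simConfig(nElectrodes = 6, nTrialsPerCondition = 60,
                     delayDelta = matrix(rep(c(6, 2, -2, -6), each = 6), 6),
                     incorrectFraction = 0.25, incorrectAttenuation = 0,
                     seed = 700 + k)
    s <- simulateSession(cfg)
    tr <- sessionTrials(s)
    rAll <- epochRates(s, c(700, 1700))
    lab <- attr(rAll, "labels")
    rc <- rAll[tr$correct, , drop = FALSE]
    ri <- rAll[!tr$correct, , drop = FALSE]
    fixCfg <- flatConfig(nElectrodes = 6, nTrials = 40, seed = 900 + k,
                         windowMs = c(0, 1000))
    sf <- simulateSession(fixCfg)
    rf <- epochRates(sf, c(0, 1000))
    cv <- cmiCrossval(rc, lab[tr$correct], ri, lab[!tr$correct],
                      rf, attr(rf, "labels"), k = 10, iters = 60,
                      seed = 800 + k)
    mean(cv$correct$cmi) > mean(cv$incorrect$cmi) &&
      mean(cv$correct$cmi) > mean(cv$fixation$cmi)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("spontaneous-window CMI under correct-trial designation is near zero", {
  cfg <- simConfig(nElectrodes = 20, nTrialsPerCondition = 100,
                   delayDelta = matrix(rep(c(4, 1, -1, -4), each = 20), 20),
                   seed = 61)
  s <- simulateSession(cfg)
  rd <- epochRates(s, c(700, 1700))
  rs <- epochRates(s, c(-150, 0))
  hl <- designateHl(rd)
  spont <- computeCmi(rs, attr(rs, "labels"), hl)$cmi
  expect_lt(abs(mean(spont)), 2 * sd(spont) / sqrt(length(spont)))
})
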