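# Small fixtures and independent oracles shared across tests.

# A hand-built two-trial session for arithmetic checks.
tinySession <- function() {
  events <- data.frame(
    trial_id = c(1L, 1L, 1L, 1L, 1L, 2L),
    electrode_id = c(1L, 1L, 1L, 1L, 1L, 1L),
    unit_id = 1L,
    time_ms = c(700, 800, 900, 1000, 1100, 750))
  trials <- data.frame(trial_id = 1:2, condition = c("A", "B"),
                       task_id = "t", correct = TRUE, session_id = 1L)
  new("SessionData", events = events, trials = trials,
      windowMs = c(-200, 1700), binMs = 1, meta = list(nElectrodes = 1L))
}

# Flat-rate config: no cue gain, no off-response, no delay modulation.
flatConfig <- function(nElectrodes = 2, nTrials = 100, rate = 10, seed = 1,
                       windowMs = c(0, 1000)) {
  simConfig(nElectrodes = nElectrodes, nConditions = 4,
            nTrialsPerCondition = nTrials, windowMs = windowMs,
            cueWindow = windowMs, delayWindow = windowMs,
            baselineRate = rate,
            stimGain = matrix(1, nElectrodes, 4),
            delayDelta = matrix(0, nElectrodes, 4),
            offResponseAmp = 0, seed = seed)
}

# Naive triple-loop evaluation of the normalized correlogram; the
# independent oracle for computeCcg.
ccgNaive <- function(trainsJ, trainsK, maxLag = 40) {
  M <- nrow(trainsJ); N <- ncol(trainsJ)
  lags <- -maxLag:maxLag
  denom <- sqrt(sum(trainsJ) * sum(trainsK))
  vapply(lags, function(tau) {
    s <- 0
    for (i in seq_len(M)) for (t in seq_len(N)) {
      tj <- t - tau
      if (tj >= 1 && tj <= N) s <- s + trainsJ[i, tj] * trainsK[i, t]
    }
    s / denom
  }, numeric(1))
}

# Brute-force Poisson naive-Bayes MAP with uniform prior; oracle for
# pidDecode when counts are integer.
poissonMapOracle <- function(tuning, counts) {
  post <- apply(tuning, 1, function(f) sum(dpois(counts, f, log = TRUE)))
  rownames(tuning)[which.max(post)]
}

# Independent Bernoulli spike trains (trials x bins) at a constant rate.
bernTrains <- function(nTrials, nBins, rate = 10) {
  matrix(as.integer(runif(nTrials * nBins) < rate / 1000), nTrials, nBins)
}
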