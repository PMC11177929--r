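---
title: "Methods: working-memory content coding analyses for V1 spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: working-memory content coding analyses for V1 spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmv1)
```

# The problem

During the delay of a delayed match-to-sample (DMTS) task, primary visual
cortex fires at close to spontaneous rates, yet small, condition-specific
rate differences may persist and carry the remembered content. Detecting
them reliably requires three things this package provides: an index of
content modulation whose selection bias is controlled (the CMI with held-out
h/l designation), a decoder that asks whether the coding *format* is shared
across time (the cross-temporal Poisson independent decoder), and a
fine-timescale connectivity measure immune to stimulus locking and slow
rate co-fluctuations (the jitter-corrected cross-correlogram). Because no
recorded dataset ships with the package, a synthetic session generator
reproduces the statistical structure these analyses assume, giving every
stage a ground-truth oracle.

# The synthetic session generator

A session is a set of trials, each with one of `nConditions` content labels,
and per-electrode spike trains in 1-ms bins over a recording window
(default −200 to 1700 ms relative to cue onset). Spikes are Bernoulli draws
per bin with probability `rate/1000`, which keeps trains inhomogeneous
Poisson to first order while honouring the one-spike-per-bin multiunit
convention that the correlogram arithmetic assumes. The per-bin rate is

- the baseline (default 10 sp/s, a typical V1 spontaneous level) outside
  all epochs;
- baseline × a per-electrode, per-condition gain during the 200-ms cue
  window (default gains: a per-electrode random permutation of 8, 5, 3, 2 —
  strong, tuned evoked responses);
- baseline plus an exponentially decaying off-response after cue offset
  (default amplitude 20 sp/s, time constant 100 ms; the transient is
  described qualitatively in the literature but not parameterized, so both
  numbers are configuration knobs);
- baseline plus a per-electrode, per-condition additive offset during the
  delay window (default: an *independent* permutation of +2, +0.7, −0.7,
  −2 sp/s).

Two defaults deserve justification. First, the delay-condition ranking is
drawn independently of the cue ranking because that is the phenomenon the
cross-temporal analyses are designed to expose: content present in both
epochs under unrelated coding formats. `equalRankings = TRUE` ties the two
rankings for contrast simulations. Second, the delay offsets (±2 sp/s on a
10 sp/s baseline, population CMI ≈ 0.2) are deliberately larger than the
few-percent modulation reported in vivo: no quantitative effect size is
published, and desk-scale test suites need effects detectable in hundreds
rather than hundreds of thousands of trials. The defaults are therefore
realistic *in kind* (weak, additive, near-spontaneous delay firing) but not
calibrated to any animal's data, and analyses that estimate effect sizes
should treat them as placeholders.

Incorrect trials (`incorrectFraction`, floor-rounded per condition) receive
delay offsets scaled by `incorrectAttenuation` (default 0.25), modelling the
observation that content differences weaken when the behavioural response is
wrong; the magnitude is unreported, so the factor is a knob. Ground-truth
connectivity is injected by copying each source spike inside a chosen epoch
to a target electrode at a fixed lag with probability `copyProbability`;
copies falling outside the window or onto an occupied 1-ms bin are dropped
and counted, preserving binary trains.

What the generator does **not** emulate: bursting and refractoriness,
oscillatory structure, slow nonstationarities across a session, electrode
crosstalk, and eye-movement-driven rate changes. Tests passing on synthetic
sessions therefore validate the *estimators* — their calibration, bias and
error control under the stated generative assumptions — not the biological
conclusions one might draw from real recordings.

# Preprocessing

**Event detection.** Multiunit events are below-to-above crossings of
|signal| over `thresholdFactor` (default 4.5) times a noise-SD estimate.
The robust estimate `median(|x|)/0.6745` is used so that the spikes
themselves do not inflate the threshold; a constant trace is an error. A
4th-order zero-phase Butterworth high-pass (default 1000 Hz) is provided
for raw traces.

**Artifact trials.** A trial is dropped when its modified z-score — the
Iglewicz–Hoaglin statistic `0.6745 (x − median)/MAD`, computed over all
trials of an experiment pooled — exceeds 2.5 in absolute value. When the
MAD is zero (more than half the trials identical) the standard z-score is
the fallback, and a zero-SD distribution keeps everything. The statistic is
scale-invariant, which the tests assert directly.

**Channel screening.** The channel SNR is the peak of the 10-ms
boxcar-smoothed PSTH in the stimulus window, *measured above the
prestimulus mean*, divided by the SD of the smoothed prestimulus PSTH
(−150 to 0 ms); channels below 5 are excluded. Measuring the peak as a
height above baseline (rather than the raw peak) is the package's reading
of "peak height of the stimulus-evoked response": the raw ratio would pass
untuned channels whose baseline mean is simply large relative to its SD,
which contradicts the screen's purpose. Whether to smooth before taking the
peak is equally unstated; the 10-ms boxcar is exposed as `smoothMs`.

**Receptive fields.** A 2-D Gaussian with independent axis sigmas, free
amplitude and baseline is fitted by Levenberg–Marquardt least squares; the
RF size is `2*sqrt(sx*sy)` (the geometric mean resolves the unspecified
axis combination), fits with goodness below 0.6 are excluded, and the array
centre averages the remaining centres. Non-convergent fits are marked
unfitted (`rSquared = -Inf`) rather than erroring.

All analysis windows everywhere are half-open `[start, end)` in ms; edge
inclusion is never ambiguous this way, and a spike at a window boundary
belongs to exactly one window.

# The content modulation index

`computeCmi` evaluates `(FR_h − FR_l)/(FR_h + FR_l)` with the h/l pair
taken either from the same data (self-designation) or from another dataset
or epoch. Self-designation guarantees a non-negative value and inflates it
on finite data (the max-minus-min of noisy means is positive even under the
null); carried designation preserves the minuend/subtrahend roles so that
sign reversals are meaningful. Ties in the designation are broken by
condition-label order and flagged; electrodes whose two rates sum to zero
return `NA` and are excluded from population aggregates.

`cmiCrossval` holds back `1/k` of the correct trials per condition
(default `k = 20`), designates on the remainder, and evaluates on the
held-back portion plus trial-number-matched random subsets of incorrect and
fixation trials, averaging 200 iterations. When incorrect trials are rarer
than 5% of the total, the held-back fraction adapts to the
incorrect:correct ratio so the matched sets remain meaningful; sets smaller
than the matched size are used whole with a warning. The suite verifies
that the cross-validated estimate is unbiased under a null simulation while
the naive self-designated CMI is positively biased, and that it converges
to the configured `(FR_h − FR_l)/(FR_h + FR_l)` with 2000 trials.

Auxiliary statistics: PSTH normalization maps the spontaneous mean to 0 and
the stimulus peak to 1; the epoch ranking comparison is Spearman's rho
between per-condition mean-rate rankings of two epochs; the trial-by-trial
epoch correlation is Pearson's r computed *within* condition and then
averaged, because pooling conditions would manufacture correlation out of
condition-mean differences alone.

# Cross-temporal decoding

Trials are reduced to batches of `batchSize = 20` adjacent same-condition
trials (adjacency in acquisition order within condition; the final partial
batch is dropped), then windowed on a 200-ms/50-ms grid. The tuning
function of a training window is the per-condition mean spike count,
floored at `floor = 0.01` so its logarithm stays finite; a zero floor would
veto any condition with a silent electrode outright. Decoding maximizes
`log L(θ) = Σ n_i log f_i(θ) − Σ f_i(θ)`; the subtracted term is the bias
correction (summed tuning), and exact likelihood ties — measure-zero with
continuous batch means, but possible with degenerate tuning — are broken
uniformly at random under the run seed. The suite asserts exact agreement
with a brute-force Poisson MAP oracle and invariance to
content-uninformative electrodes.

Each repetition draws 15 training batches per condition without
replacement, tests on the remainder, and applies every training window's
tuning to every test window; 1000 repetitions are averaged in full runs
(the test suite and acceptance script use 1 to 100 repetitions, which is
sufficient at their problem sizes). The permutation null permutes condition
labels across batches and recomputes the grid; the one-tailed p-value is
`(1 + #{null ≥ observed})/(1 + nPerm)`. Below-chance cells are meaningful:
they indicate a coding format that is *systematically inconsistent* between
training and test windows, which is exactly what independent epoch rankings
produce.

The cross-task harness wraps a standard linear SVM. The regularization cost
is picked once from a small logarithmic grid (default 0.1, 1, 10) by
two-fold cross-validation on the first training draw and reused across the
100 iterations; a per-iteration Bayesian search would be slower and
non-deterministic across platforms, and with window-averaged rate vectors
the accuracy is flat over a wide cost range.

# Jitter-corrected connectivity

The raw correlogram counts same-trial spike pairs at each lag from −40 to
+40 ms, normalized by the geometric mean of the two units' total epoch
spike counts. Two implementation notes: the denominator uses the *total*
counts at every lag (not lag-truncated sums), which is what makes identical
trains give exactly 1 at lag 0; and no triangular correction for finite
window length is applied — the linear flank bias this leaves is common to
the raw and jittered correlograms and cancels in the subtraction. The
numerator is evaluated exactly from spike indices (integer arithmetic), so
the vectorized implementation agrees with a naive triple loop to the last
bit; the suite asserts this on random instances, along with the identity
`CCG_jk(τ) = CCG_kj(−τ)`.

Jitter resampling permutes the bins of each 25-ms block (aligned to the
epoch start) independently per trial: every spike is relocated uniformly
within its block *without replacement*, preserving per-trial block counts
exactly — and hence the across-trial PSTH at block resolution — while
keeping trains binary; independent uniform draws could collide two spikes
into one bin. Three Monte-Carlo rounds are averaged by default; an exact
mode replaces them with the correlogram of the block-mean profiles, which
is the analytic expectation for independently jittered trains and serves as
a deterministic oracle for the Monte-Carlo path.

Significance: noise SD over corrected values at |lag| ∈ [20, 40] ms
(corrected, not raw, flanks — the corrected flanks are the quantity whose
fluctuations the rule is calibrated against), significant iff the corrected
maximum over lags 1-20 ms strictly exceeds 7 × that SD; a zero flank SD
degenerates to requiring a strictly positive peak. The suite verifies
false-positive control under independence, power monotone in the injected
copy probability, removal of slow shared envelopes, and recovery of an
injected 3-ms lag. Pairs are then categorized stimulus-only / delay-only /
both, with all three proportions reported relative to the count of
stimulus-significant pairs (so delay-only can exceed 1); an empty
denominator flags the proportions undefined rather than returning 0/0.

# Association-task machinery

The early stage is the shortest session prefix accumulating 1000 correct
trials; the late stage is the longest suffix whose running mean accuracy
stays ≥ 90%, excluding the session that breaks the criterion (the backward
rule is ambiguous about that session; exclusion is the stricter reading and
`includeBreakingSession` restores the other). Antagonistic pairing joins
the strongest-delay-response condition of one task with the weakest of the
other, and vice versa. The stagewise contrast designates h/l on the early
stage only and carries it to the late stage and both control tasks, so the
late-stage CMI can go negative when the population ranking truly reverses;
|ΔCMI| measures proximity of each stage to each control.

The CMI-trajectory PCA centres each electrode's time course on its own
mean (uncentred components would mostly encode the grand mean time course),
takes the SVD of the pooled early+late matrix, projects any requested
dataset onto the first three components, and only then interpolates to a
10-ms grid and smooths with a 100-ms boxcar. Smoothing after projection —
not before — keeps the fitted subspace faithful to the raw data, and all
statistics are computed on raw electrode values, never on the smoothed
projections.

# Reproducibility and problem sizes

Every stochastic operation takes an explicit seed, evaluates under it in a
local RNG scope, and restores the caller's RNG state; identical
config + seed reproduce byte-identical sessions and pipeline artifacts,
which the suite checks at the file level. Pipeline CSVs carry a stamp line
with schema version, config hash (MD5 of the canonical YAML serialization)
and seed.

The test suite and acceptance script run at deliberately modest sizes —
sessions of 4 to 20 electrodes and 40 to 1600 trials, 1 to 200 decoding
repetitions, 99-permutation nulls, 1000 connectivity pair evaluations —
chosen so the weak-effect regimes are still detectable while a full run
completes in minutes on one CPU. Production analyses of real recordings
would scale the repetition counts (1000 decoding repetitions, more
permutations) without any code change.

# Known limitations

- The Bernoulli-per-bin generator cannot represent instantaneous rates
  above 1000 sp/s and slightly underestimates Poisson variance at high
  rates (a 1-ms bin caps at one spike).
- `detectMuaEvents`'s robust noise estimate assumes spikes are sparse; for
  spike-dominated traces (median |x| = 0) it falls back to the raw SD.
- The adaptive fold rule in `cmiCrossval` follows the smallest
  incorrect:correct ratio; with extremely few incorrect trials the matched
  evaluation sets become very small and the incorrect-set CMI
  correspondingly noisy — the warning, not an error, is deliberate.
- The per-task electrode-intersection rule for aggregating CMI across
  several tasks is exposed as data handling (the caller intersects
  electrode sets) rather than fixed policy, since the published aggregation
  is ambiguous.
- Receptive-field fitting can fail to converge on very noisy grids; such
  electrodes are excluded from the array centre rather than imputed.
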