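---
title: "Models and methods behind seqmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seqmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seqmem` analyzes hippocampal CA1 ensemble activity recorded while rats
judge the order of a learned five-odor sequence (ABCDE) at a nosepoke port:
in-sequence (InSeq) items are held for at least 1.2 s, out-of-sequence
(OutSeq) items answered by early withdrawal, and an incorrect response ends
the sequence. This vignette explains each model, its assumptions, the
tunable parameters, the design of the synthetic-session generator that the
test suite uses as its ground truth, and the numerical choices and known
limitations. Everything stated here about performance is computed by the
package's tests or by `scripts/acceptance.R`; nothing is quoted from
elsewhere.

## Conventions

All times are seconds from session start; trial-relative times are computed
on demand. Count bins are half-open `[t, t + tau)`, so a spike exactly on a
right edge belongs to the next bin. Theta phase is measured with 0 degrees
at the peak of the filtered trace and 180 degrees at the trough; the cycle
is partitioned into descending `[0, 120)`, trough `[120, 240)` and
ascending `[240, 360)` thirds, and cycles run peak-to-peak (ascending
zero-crossings), so the trough sits mid-cycle. Every stochastic operation
takes an explicit integer seed, and permutation/subsampling draws go
through the single `perm_stream()` engine, which makes all reported
p-values bit-reproducible.

## The synthetic-session generator

The generator (`sim_config()` + `simulate_session()`) is first-class,
tested code: it defines the study conditions under which every downstream
claim is verified by parameter recovery.

**Behavior.** Sequences of five positions; position 1 is always InSeq odor
A; positions 2-5 are replaced by a random OutSeq odor with probability
`p_outseq` (default 0.15 per position, which leaves roughly half of the
sequences all-InSeq). Hold durations: 1.2 s plus a short overshoot for
"hold" responses; a truncated normal with mean 0.75 s and SD 0.23 s for
withdrawals. Inter-odor intervals are log-normal with a 5 s median and a
hard 0.8 s floor. `p_incorrect` (default 0.10) is the OutSeq error rate;
InSeq errors are rare in well-trained animals and get their own small
default (`p_incorrect_inseq = 0.02`). An error terminates the sequence,
which is why later positions are sampled less often - an imbalance several
analyses must survive (see the class balancing note below).

**Time cells.** Each neuron has a preferred odor, a Gaussian firing field
(center `t0 ~ U(0, 1.2)` s, width 0.05-0.2 s), an in-field peak rate
(default 5-25 Hz, the range typical of CA1 pyramidal cells), and a
baseline (0.5-2 Hz). On a trial of odor `o`, a neuron preferring odor `q`
fires its field at gain `rho^|lag(o, q)|` with `lag` the odor-index
distance; `rho = 0.6` by default. Spikes are drawn as an exact
inhomogeneous Poisson process by thinning on each trial segment (candidate
times at the segment's analytic rate bound, accepted at `lambda(t)/bound`),
plus homogeneous baseline firing across the whole session. With all
modulations off, windowed counts are Poisson with the configured mean (the
test suite checks the Fano factor).

**Partial remapping.** A decoder trained on one odor's rate map and tested
on neighboring positions loses accuracy only through the gain decay if
field times are shared across odors, and pure gain scaling degrades
Poisson decoding surprisingly slowly. Real time cells also shift their
fields across contexts, so the generator adds a per-(neuron, odor) field
shift with SD `field_jitter * (1 - rho) * |lag|` (default
`field_jitter = 0.3` s). The factor `(1 - rho)` ties the remapping to the
same context-similarity parameter and vanishes at `rho = 1`, preserving
the invariant that a lag-symmetric generator produces a flat lag curve.

**Theta phase coding.** A fraction `theta_frac` of neurons are
theta-coded: their in-field rate is multiplied by a von Mises factor
normalized to unit mean (`exp(kappa cos(phase - mu)) / I0(kappa)`), so
phase coding does not change cycle-averaged rates and rate-based and
phase-based analyses stay orthogonal. Every theta neuron carries a
*present* lobe at 180 degrees on its preferred odor's trials. Neurons with
a `past` or `future` role carry one additional lobe: a past-role neuron
preferring `q` also fires at 60 degrees on the trial *following* `q` (its
odor is then the previous item), and a future-role neuron at 300 degrees
on the trial *preceding* `q`. The secondary lobe uses the time field of
the reactivated odor, so the population pattern at the descending phase of
a B trial mirrors the trough pattern of A trials - which is exactly what a
trough-trained decoder needs to read out "past = A". A design where roles
are exclusive (a future neuron firing only at 300 degrees on preceding
trials and nowhere else) cannot be decoded this way, because the
trough-trained model would never associate such a neuron with its odor.

**Precession.** When `precession_slope` is nonzero (degrees per cycle),
every lobe's preferred phase shifts linearly with the cycle index counted
from port entry; the index continues into negative values before entry, so
pre-trial predictive coding precesses on the same line.

**Predictive coding and outcome.** In the `pretrial_window` before port
entry the whole ensemble pre-activates a scaled preview of the expected
(InSeq) odor's evoked pattern: each cell fires at
`pretrial_gain * peak * rho^|lag(expected, pref)|` with its early-field
time course, optionally phase-locked (`pretrial_phase`). On trials the
animal will answer incorrectly this preview is damped by
`incorrect_pretrial_factor` (default 0.15) - the latent cause that the
outcome analyses (KL divergence, pre-trial KS tests) are designed to
recover. A whole-ensemble preview matters: if only preferred cells
pre-activated, the missing activity of all other cells would be strong
negative evidence for any discriminative decoder, and pre-entry windows
would be decoded as whatever class has the lowest training rates.
Outcome-modulated neurons (20% by default) add `outcome_gain * peak` after
withdrawal on incorrect trials.

**Reactivation schedule.** With `react_gain > 0`, upcoming odors' neurons
ramp up linearly within the trial (scaled by `react_decay^(k-1)` for the
odor `k` positions ahead) while the previous odor's neurons fade - the
within-trial reactivation whose decoding signature is a positive slope of
`P(next) - P(current)` across time windows.

**LFP and SWRs.** Each tetrode carries a 6 Hz cosine carrier plus Gaussian
noise; tetrode T1 (designated theta channel) gets a 1.2x carrier. When
`swr_rate > 0`, Gaussian-windowed 180 Hz ripple bursts and co-timed
negative sharp-wave deflections are injected on the designated ripple and
sharp-wave tetrodes with amplitude `swr_amp_sd` times the channel's
background SD (theta plus noise - scaling by the noise alone would make
nominally "6 SD" events marginal against the theta-dominated envelope).

**Presets.** `phase_coded_config()` is the condition for theta-sequence
analyses: 120 neurons (recorded ensembles are of this order), all
theta-coded with equal role proportions, balanced round-robin odor x role
tuning, wider fields (so cells are in-field during early cycles),
`kappa = 6`, `rho = 0.4`, no field jitter, and phase-locked pre-trial
coding over 0.6 s (three pre-entry cycles). Balanced tuning removes the
seed-to-seed variance in how many cells carry each odor x role
combination, which otherwise dominates the single-session decoding
contrasts.

## Bayesian time reconstruction

Under independent-Poisson spiking, the posterior over reconstructed time
bins given the counts `n_i` observed in an actual-time bin is

    P(time | n, odor)  proportional to  prod_i (tau f_i(time, odor))^(n_i) * exp(-tau sum_i f_i(time, odor))

with a uniform prior over the analysis window (all InSeq holds have the
same duration) and `f_i` the mean rate of neuron `i` in overlapping bins of
length `tau` advanced by `step` (50/5 ms for single odors, 1.5 s/150 ms for
full sequences in the original design; the desk-scale tests use 100/100
ms). Each actual-time bin is decoded independently - the model is
memoryless. Likelihoods are computed in log space with a rate floor of
`eps = 1e-3` Hz so that a nonzero count at a zero-rate bin cannot produce
an infinite log-likelihood; neurons whose training rate is zero everywhere
for the decoded odor are dropped from that decode.

*Accuracy* is the mean Pearson correlation between row `i` and column `i`
of the (square) posterior matrix; undefined pairs (zero variance) are
skipped, and a trial whose pairs are all undefined yields NaN and is
excluded with a log entry. *Chance* comes from permutations of the time
axis of the rate map. Because permuting the map's time axis simply permutes
the posterior's columns, the chance distribution is computed directly from
the observed posteriors (standardized rows x columns inner products), which
makes 1000 permutations cheap and - importantly for calibration - makes the
observed statistic exactly exchangeable with the permuted ones on
structureless data. The suite verifies both the brute-force equality of the
posterior (term-by-term oracle, < 1e-9) and the type-I rate of the
permutation test (about 5% across 200 null ensembles).

*Protocols.* Leave-one-out rate maps are computed incrementally from the
stored count tensor, so training and test sets are disjoint by
construction. The lag analysis trains per odor on intact (consecutive,
all-InSeq, all-correct) sequences and tests on the other positions; lag 0
is tested on correct InSeq trials outside the training set, falling back to
a held-out fifth of the training trials when a synthetic session has too
few non-consecutive trials. The outcome analysis decodes the 250 ms before
port entry of OutSeq trials (positions 2-4) under the joint time x odor
model and compares each trial's posterior with the mean InSeq posterior by
KL divergence (both distributions floored and renormalized), with a
two-sample Kolmogorov-Smirnov test between correct and incorrect trials
and an optional downsampled repetition.

## PSTHs

Rates are binned at 1 ms, smoothed with a Gaussian kernel (150 ms SD for
single-odor, 250 ms for full-sequence histograms) truncated at +/-4 SD with
reflected boundaries, averaged over trials, and normalized to the row peak;
neurons silent on all included trials are dropped. "Peak" is the argmax of
the smoothed normalized row, first bin winning ties, and peak sorting is a
stable permutation (ties broken by neuron id). The trial-similarity
analysis builds one PSTH per trial with the same smoothing and
normalization (the natural reading; using raw rates changes the scale of r
but not the same-vs-different contrast), vectorizes neurons in canonical
order, correlates all trial pairs, and compares same-odor vs different-odor
pair classes by one-way ANOVA with reference-class contrasts
(Holm-adjusted Welch tests).

## Autoencoder latent analysis

Inputs are 100 ms count vectors (10 ms bins per neuron) slid in 10 ms steps
across each 250 ms analysis window - 16 points per trial. The network is
encoder 500-500, linear 2-node bottleneck, mirrored decoder; rectified
units elsewhere, linear reconstruction output (the output regresses
standardized counts, which take both signs); loss is MSE; training is
plain SGD with momentum 0.9, learning rate 1e-3, batch 64, gradient-norm
clipping at 10 (early epochs of a deep bottleneck net under plain SGD can
otherwise diverge), with the per-batch gradient defined as the squared
error summed over features and averaged over the batch. One autoencoder is
trained per 250 ms window, never seeing labels; a leakage test confirms
that shuffling labels changes nothing upstream of classification. Training
is single-threaded and deterministic given the spec seed. The default
widths of 500 match the analysis design; the test suite trains 64-64
encoders (the input dimension at 60 neurons is 600, and the reduced widths
cut runtime roughly tenfold without changing any tested conclusion).

k-NN separability uses k = 2 on latent points with a 70/30 stratified trial
split: each test point takes its two nearest training points' label, a
disagreement resolved by the nearer neighbor (equidistant ties by training
index - note that with k = 2 this reduces to the nearest neighbor's label,
which is the deterministic reading of the rule), and the trial takes the
majority over its 16 point votes. Chance is the 2.5-97.5 percentile
interval of 100 label-shuffle accuracies with the split held fixed. The
lag analysis computes trial centroids, Mahalanobis distances under the
pooled centroid covariance (Euclidean fallback if singular), classes pairs
by odor distance (InSeq) or same-odor position distance (OutSeq), and
fits linear and quadratic trends.

## CNN odor decoding

Per tetrode, the down-averaged LFP trace and each unit's spike counts share
a 10 ms grid over the window; channels are z-scaled with moments fixed at
training. Eight width-5 filters are convolved per tetrode (weights not
shared across tetrodes), rectified, time-averaged, concatenated, and passed
through 64- and 32-unit rectified layers with dropout 0.5 to a softmax over
odors A-D. Training uses SGD with momentum on the 150-400 ms post-entry
window with a 15% stratified validation split and patience-10 early
stopping; the penultimate layer is the latent space, reduced to two
principal components with multinomial-logistic linear boundaries for
visualization. Filter counts, widths and hidden sizes are declared package
defaults - the architecture concept (tetrode-wise convolution over joint
LFP + spikes, time-averaged features, dropout, early stopping) is the
specified part.

Window statistics pool trials per 250 ms window by argmax class and use
Goodman simultaneous multinomial confidence intervals
(chi-square quantile at `1 - alpha/k`); non-overlapping intervals are
reported as significant, with per-window chi-square tests alongside, and
reactivation is quantified by the per-trial least-squares slope of a
probability difference (e.g. `P_C - P_B` on B trials) across windows with
a one-sample t test. The subject control builds leave-one-session-out
confusion matrices and applies the Cochran-Mantel-Haenszel test stratified
by true odor; note that CMH sums deviations across strata, so it detects
consistent biases (e.g. one session over-predicting a class) and not
self-canceling ones.

## Theta-cycle decoding

Phase comes from a 2nd-order 4-7 Hz Butterworth (zero-phase `filtfilt`)
followed by the analytic signal; the signal is reflection-padded by one
second per side so filter and Hilbert transients stay out of the analyzed
span (on a noiseless 6 Hz cosine the phase error excluding 0.5 s edges is
below 0.2 degrees). The FFT-based analytic signal pads to 2-3-5-smooth
lengths (R's mixed-radix FFT is quadratic in large prime factors). The
channel is the designated theta tetrode or, absent that, the channel with
maximal band power. Cycles are delimited by ascending 0-degree crossings;
cycle 1 is the first cycle starting at least 100 ms after port entry, and
trials whose cycle-1 amplitude falls in the lowest 20th percentile are
excluded.

The decoder is a multinomial LASSO (glmnet) on each neuron's firing rate in
the trough (120-240 degrees) of cycle 1 on correct InSeq trials, with the
penalty chosen by stratified 10-fold cross-validation; silent or
uninformative neurons get exactly zero weight. Because sequence truncation
oversamples early odors, training classes are subsampled to equal counts by
default (`balance_classes = TRUE`) - without this the multinomial
intercepts encode the class imbalance and the softmax drifts toward early
odors whenever evidence is weak, which contaminates the off-trough phases.
Decoding slides a 120-degree window in 10-degree steps; a bin's window may
wrap around the cycle edge but only borrows samples from the same cycle.
Rates use the true occupancy of each phase window (samples/fs), so
frequency jitter cannot masquerade as rate changes.

Role mapping on a trial at position p reads past = InSeq odor of p-1,
present = presented odor, future = InSeq odor of p+1; B and C trials are
pooled so all three roles fall inside the decoded classes A-D. Cycle-1
hypothesis tests collapse the 36 bins to the three phase thirds and use
paired one-sided t tests (past > future at descending, future > past at
ascending, present maximal at trough). Cross-cycle analyses z-normalize
each role over all bins, cycles and trials (a display-oriented transform;
the same tests are run on raw probabilities and the suite asserts the
trends on the z scale while reporting both), collapse across phase, and
fit linear and quadratic trends over the four equidistant cycles
{-2, 1, 3, 5}.

The single-cell map trains a univariate multinomial model per neuron on
the same trough rates, screens for phase modulation (one-way ANOVA of a
class probability across the three phases at alpha = 0.05 for at least one
odor), classifies each phase third by the role with the highest mean
z-scored decoding, and quantifies the diagonal by the correlation between
phase index and role index across neurons. The permutation null shuffles
each neuron's decoded roles across phases: this disturbs phase while
keeping each neuron's decoded multiset, whereas shuffling values across
neurons *within* a phase bin provably leaves the phase x role correlation
unchanged (the per-bin value multiset is invariant), so it cannot serve as
a null.

Ensemble precession aggregates the univariate present-odor decodings: per
cycle, each neuron's 36-bin profile is standardized (putting neurons on a
common scale - note that z-scoring *across neurons within a bin* would
make the across-neuron sum identically zero) and summed; the profile is
min-max normalized to [-1, 1] per cycle; the peak phase per cycle is
correlated with the cycle index; and the null permutes the order of theta
cycles within each trial (1000 draws by default). Spike-phase precession
per neuron uses a circular-linear correlation: the slope maximizing the
resultant length of `phase - 360 * a * t` is fit over +/-2 cycles per
trial duration (grid search plus local refinement), and the
circular-circular correlation between phase and the fitted circular
variable is tested with the standard asymptotic normal statistic; neurons
with fewer than 10 in-trial spikes are skipped and significance is read at
p < 0.01.

## SWR control

Band events are detected on the analytic-signal envelope of the filtered
trace (ripple: 150-250 Hz band-pass; sharp wave: > 4 Hz high-pass),
z-scored against the whole-channel mean and SD, thresholded at 3 SD, and
merged when separated by less than 15 ms (merging is idempotent). An SWR is
a temporal overlap between a sharp-wave event and a ripple event on their
designated tetrodes, with union boundaries. The phrase "instantaneous
power as the real component of the Hilbert-transformed trace" is not a
consistent power estimate (the real part of an analytic signal is the
signal itself); the standard envelope (modulus of the analytic signal) is
used instead. Trial exclusion removes trials whose odor period or
+/-250 ms flanks intersect any event, and the report is checked against a
brute-force interval-intersection oracle.

## Problem sizes and what the tests do and do not show

The acceptance suite runs at desk scale: 60-neuron, 25-40-sequence
sessions for rate-based analyses, 120-neuron phase-coded sessions for
theta analyses, 20-seed sweeps for recovery claims, 100-200 scaled-down
seeds for calibration claims, 100-1000 permutations per test, and reduced
autoencoder widths. These sizes were chosen so the complete suite runs in
tens of minutes on one CPU while leaving comfortable statistical margins;
they are stated here as the package's own study conditions.

The generator emulates the statistical structure the analyses assume -
Poisson time cells with graded odor context, unit-mean von Mises phase
gating, linear-in-cycle precession, pattern-preview predictive coding -
but not several features of real recordings: spike-sorting contamination,
non-Poisson variability (bursting, refractoriness), theta frequency drift
and asymmetric cycle shapes, behavioral covariates (sniffing, movement),
electrode drift, or genuinely conjunctive odor x time fields beyond the
gain-plus-shift model. Passing recovery tests therefore demonstrates that
the estimators are correct and well calibrated under the stated model, not
that the biological effects are of any particular size; dataset-specific
statistics from real recordings are out of scope by design.
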