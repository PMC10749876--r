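---
title: "Quantifying long-lasting sensory-context effects in auditory cortical populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying long-lasting sensory-context effects in auditory cortical populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxcode)
```

## The scientific problem

Neurons in auditory cortex (AC) do not respond to a sound in isolation: the
response to a 1-s *probe* sound depends on the *context* — the sound (or
silence) that immediately preceded it — for hundreds of milliseconds, far
beyond the 50–100 ms integration window of a classical spectro-temporal
receptive field (STRF).  `ctxcode` implements a complete analysis chain for
this phenomenon in trial-based population recordings:

1. **Stimulus design** — balanced sequences in which every ordered
   (context, probe) combination occurs exactly once.
2. **Effect quantification** — a cluster-mass permutation test on the
   Z-scored probe-PSTH difference between two contexts, with integral
   *amplitude* (Z-score·s) and last-significant-bin *duration* (ms).
3. **Population coding** — contextual *coverage* of single neurons, the
   site *union*, the *best neuron* and the first principal component
   (PC1); a *dense-code* control transform; and per-time-bin linear (SVM)
   decoding of context and probe identity.
4. **Category statistics** — context similarity/identity regression,
   Kruskal–Wallis/Dunn comparisons, spike-width cell typing, pupil-indexed
   arousal splits, jackknife uncertainty.
5. **Encoding models** — rectified-linear GLMs combining an 18 × 30 STRF
   with windowed self- and population-history terms, with
   temporal-scrambling controls that hold parameter count fixed.

Because no recordings are distributed with the package, a synthetic-data
generator (`simConfig()` / `simulatePopulation()`) produces population
recordings with *known* injected context effects, cell types, coupling and
arousal state; every downstream stage is validated against this ground
truth.

## Stimulus design by exact cover

For N sounds, a valid design is N sequences of N + 1 one-second sounds such
that the N(N+1) ordered (context, probe) events — context in {silence, 1..N},
probe in {1..N}, silence context realized at sequence starts — each occur
exactly once.  `designSequences()` solves this by decomposing the complete
digraph with self-loops on the N sounds (in- and out-degree N, hence
Eulerian) into a random Eulerian circuit, then cutting the circuit into N
paths of N edges whose start vertices are distinct; circuits are redrawn
under the seed until a valid cut exists.  The contract, not the algorithm,
is normative: `validateSequences()` re-checks every invariant and
`designSequences()` refuses to return an invalid set.

A contextual *instance* is a probe with an unordered pair of distinct
contexts; `enumerateInstances()` yields N·C(N+1, 2) of them — 40 for N = 4,
550 for N = 10.  (One passage of the source methods text quotes 50 for
N = 4; the combinatorics give 40, which this package uses.)

Descriptive sound metrics (`computeSoundMetrics()`) follow fixed
conventions: channels are treated as abutting bins on the log2-frequency
axis; *bandwidth* is the octave span between the 15th and 85th percentiles
of cumulative spectral power (so a flat spectrum spanning 6 octaves of bin
extent has bandwidth 4.2); *temporal stationarity* and *spectral
correlation* are computed over the channels inside that band.

## The synthetic-data generator

`simulatePopulation()` emulates the recorded preparation: tens of neurons,
20 repetitions of each sequence, 50-ms analysis bins (20 Hz) plus a 10-ms
(100 Hz) version for encoding models, Poisson spiking on deterministic
tuned rate profiles (sound-identity gains with an onset transient), a
two-component spike-width (PTD) mixture with modes at 0.25 and 0.70 ms (so
classification thresholds fall in the valley), region labels (A1/dPEG), an
optotag flag, a slow pupil trace with optional per-neuron arousal gain, and
optional lagged (150–300 ms) self- and cross-neuron coupling.

Context effects are *injected* at the level of (context → probe) events: a
sparse subset of (neuron, event) pairs receives an additive rate modulation
over the probe window, specified as a per-bin ΔZ target with configurable
amplitude (default 0.1–0.7 Z-score·s, matching the empirically observed
range), duration (100–800 ms, bin-quantized) and shape (exponential decay
by default, with late-onset and two-peak alternatives reflecting the
often non-monotonic profiles seen in cortex).  An instance's true effect
is the *difference* between its two contexts' injections.

Two design choices matter for testability:

* **Additive injection, empirical units.**  The injected modulation is
  additive on rate, and the returned ground truth restates it as the
  realized (clipped, pre-noise) expected-count difference divided by the
  neuron's empirical count SD — exactly the quantity the analysis
  estimates.  With noise disabled, the recovered amplitude and duration
  therefore equal the truth to machine precision; this is why an additive
  rather than multiplicative injection was chosen (a multiplicative one
  couples ΔZ to the time-varying probe rate and has no exact analysis-unit
  statement).
* **Clipping is part of the truth.**  Rates are clipped at zero *before*
  ground truth is computed, so strong negative modulations on low-rate
  neurons are recorded as what actually reached the spike generator (the
  clip count is reported as a warning).

What the generator does **not** emulate: real spectro-temporal receptive
fields (tuning is by sound identity, not a linear function of the
spectrogram), non-Poisson spiking statistics, slow non-stationarities other
than the pupil drift, and realistic correlated trial-to-trial variability.
Passing tests therefore demonstrate the correctness and calibration of the
*analysis*, not biological claims about real data.

## Cluster-mass quantification of context effects

Single-trial counts are Z-scored per neuron over the whole recording
(`zscoreNormalize()`); neurons whose split-half PSTH reliability is at or
below r = 0.1 can be excluded (`reliabilityFilter()`).  For each instance,
`clusterMassTest()`:

* computes a per-bin two-sample T score between the two contexts' probe
  responses (pooled variance by default; Welch behind a flag — the per-bin
  statistic is not fully specified by the method's name alone);
* forms clusters of contiguous same-sign bins with per-bin p < 0.05 and
  scores each by its summed T;
* builds the null by reshuffling the trial-to-context assignment
  (default 11,000 shuffles), recording the *maximum* absolute cluster
  score per shuffle, and assigns each observed cluster the add-one tail
  probability of its |score| (two-sided via the absolute value).

Degenerate bins with zero variance in both conditions get T = 0 when the
means agree and ±Inf when they differ — the noise-free limit — so
deterministic simulations run cleanly.  `effectMetrics()` integrates
|ΔZ| over significant bins (amplitude, Z-score·s) and takes the end time of
the last significant 50-ms bin (duration, ms; bin k ends at k·50 ms).
`correctInstances()` applies Bonferroni across instances (α = 0.05 family),
optionally multiplied by the neuron count for site-union use.

One numerical interaction deserves note: the permutation p-value cannot go
below 1/(nShuffles + 1), so Bonferroni thresholds such as 0.05/(40 × 6
neurons) are only reachable with enough shuffles (here ≥ 4,800).  The
package applies the correction to the permutation p exactly as computed and
leaves the shuffle budget to the caller; analyses in this vignette and in
the tests size it accordingly.

Because amplitude (an integral over significant bins) and duration (the
last such bin) are correlated by construction,
`amplitudeDurationAssociation()` permutes the bin order within each
profile — amplitude is invariant, duration is randomized — to build the
null for the observed amplitude–duration correlation.

## Sparse code, dense-code control, decoding

Coverage is the percentage of tested instances with a significant effect:
per neuron (`neuronCoverage()`), for the site union (`siteUnion()`, max
significant amplitude per instance, neuron-count-corrected), the best
neuron (`bestNeuron()`, ties broken by summed amplitude then id), and PC1
(`pc1Coverage()`: PCA on trial-averaged responses, single trials projected,
PC1 analyzed exactly like a neuron; its sign is fixed by positive
correlation with the mean population rate).

`densify()` imposes a matched *dense* code: each population context-
modulation vector m⃗(c, p, t) (trial-averaged deviation from the
context-averaged probe response) is rotated onto the equal-activity
diagonal.  The per-component target is sign(⟨m⟩ᵢ)·‖m⃗‖₂/√I, which preserves
each modulation's L2 norm (the ‖m⃗‖₂/I reading of the defining expression
is available behind `magnitude = "l2overI"`; the norm-preserving form is
the default because the dense code is meant to carry the *same overall
magnitude* of context modulation).  The rotated context component is then
rescaled toward the original across-context variance (ratio as printed by
default; square-root variant behind a flag).

Two bookkeeping subtleties, resolved here as package semantics:

* The rotation targets need not sum to zero across contexts, while
  recomputed modulations (deviations from a re-estimated probe mean)
  always do.  The transform therefore reports the imposed targets
  (`mTarget`) — these preserve ‖m⃗‖ exactly — and removes the resulting
  context-independent probe-mean offset at the end, so context-averaged
  probe responses are preserved exactly.  Recomputed modulations equal the
  context-centered targets and are identical across neurons to machine
  precision.
* The variance correction scales the probe-averaged context component, so
  neither ratio convention restores per-probe variance exactly; both are
  calibrated approximations and the choice is exposed.

`decodeTimecourse()` trains an independent linear SVM (e1071, C = 1,
features standardized with training-fold statistics, stratified 4-fold CV)
at every 50-ms bin, for context labels (chance 1/(N+1)) or probe labels
(chance 1/N).  On sparse-effect simulations, the dense transform reduces
context decoding toward chance while leaving probe decoding unchanged —
the defining behavioural contract of the control.

## Category-level and cell-type statistics

`assignCategories()` maps each instance context to similarity
(silence/same/different) and identity (vocalization/non-vocalization,
silence having none); instances pairing silence with a vocalization context
are flagged for exclusion from marginal comparisons.
`categoryRegression()` normalizes the metric by its grand mean (percent
scale), duplicates each instance row once per context label, and fits OLS
with the similarity × identity interaction against the
different/non-vocalization base.  Silence rows carry the base identity
level — silence has no identity of its own, and the fully-specified
silence × vocalization cell never occurs, so that interaction term drops
out with a warning rather than being silently imputed.

`groupCompare()` wraps `kruskal.test` and adds Dunn's pairwise z tests
(mean-rank differences with tie correction, Bonferroni-adjusted) — written
in-package because no pre-installed package provides them.
`classifySpikeWidth()` takes the KDE (Silverman bandwidth) valley between
the two dominant modes, keeps a 0.1-ms safety band unclassified, refuses
unimodal distributions, and accepts explicit thresholds such as
(0.37, 0.47) ms.  `pupilSplitMI()` median-splits trials per instance on
pupil size over the context+probe interval and computes the modulation
index (large − small)/(|large| + |small|) for mean rates and context
effects, overall and in the four 250-ms probe intervals, after the stated
responsiveness (Z ≥ 0.1) and effect-size (|ΔZ| ≥ 0.3, sign-flipped
positive) filters.  For an instance, the two context events of a repetition
occur in different sequences; their pupil medians are averaged to one
per-repetition value before splitting.  `jackknifeCI()` provides delete-one
or seeded grouped delete-d jackknife SEs (100 or 200 folds as used for the
summary figures).

## Encoding models

`buildEncodingDesign()` constructs, at 100 Hz, the 18-channel × 30-lag
(0–300 ms) stimulus block plus one windowed-average (150–300 ms lag) history
scalar for the modeled neuron and each neighbor.  The lag window starts at
150 ms so the history terms cannot proxy short-latency stimulus-driven
correlation; the STRF is extended to 300 ms so its far-past lags overlap
the history window and soak up any residual stimulus information.  The four
variants — STRF, Self, Pop, Full — share the identical parameter vector;
variants *remove* information by circularly shifting the relevant history
sources by independent random offsets of 10–60 s (shift, not shuffle, to
preserve short-term structure; shifts under 1 s after the modulo are
redrawn).

`fitEncodingModel()` minimizes the MSE of the rectified-linear output
(bias inside the rectifier, spike-threshold interpretation) with one fold
per stimulus sequence.  Optimization is ADAM (learning rate 1e-3, early
stopping on a deterministic 10% in-fold slice), initialized from a ridge
least-squares solution refined by a few active-set passes that solve the
linear region of the ReLU objective directly; on noise-free rectified
generative data this recovers the filter essentially exactly.  Performance
is the Pearson correlation of the concatenated held-out predictions with
the response.

`predictContextEffects()` evaluates a fitted model on the context-probe
data by teacher forcing (actual recorded histories as inputs), computes
|Δ| between predicted probe responses under each context on min–max
(0–1) normalized traces — normalized per neuron over the concatenated
recording, a convention this package fixes — integrates per 250-ms interval
(bins 1–25, 26–50, 51–75, 76–100 at 100 Hz), restricts to instances
significant in the cluster-mass analysis, and reports per-interval Pearson
r with a 200-fold jackknife SD.  `compareModels()` runs paired two-sided
Wilcoxon signed-rank tests on absolute prediction correlations with
Bonferroni over the six pairs; `summarizeCoupling()` averages fitted
neighbor weights by source class (outgoing) and target class (incoming).

In simulation, the dissociation behaves as designed: with cross-neuron
coupling, Full and Pop beat STRF; with self-dependence only, Self ≈ Full
beat STRF; scrambled variants never beat their unscrambled counterparts on
average.  A practical note from the generator: *negative* self-weights
(classical adaptation) at low baseline rates drive the rate into the clip
at zero and weaken the realized self-dependence, so the self-dependence
simulations use recurrent self-excitation, which is clip-free and produces
the same model-comparison signature.

## Problem sizes and reproducibility

Every stochastic step takes an explicit seed (simulation configs, shuffle
tests, fold assignments, scramble shifts), and `runPipeline()` writes CSVs
rounded to 6 significant digits plus a manifest with MD5 checksums, so a
rerun with the same config is byte-identical.  The analyses shipped in the
tests and the acceptance script run at deliberately compact sizes — sites
of 5–30 neurons, N = 4 sounds, 10–20 repetitions, 1,000–6,000 permutations
(6,000 where the union's neuron-count Bonferroni requires the resolution),
80–150 optimizer epochs — chosen so the full suite exercises every stage
end-to-end while remaining comfortable on a single CPU; all scale up by
configuration.

## Known limitations

* The generator's tuning is sound-identity-based, so absolute encoding-model
  prediction correlations are lower than for real AC neurons whose
  responses are partly linear in the spectrogram; model *comparisons* are
  unaffected, since all variants share the stimulus term.
* Cluster-level inference is per instance; the Bonferroni correction
  interacts with permutation resolution as described above.
* The dense-code variance correction is a calibrated approximation (both
  printed and square-root conventions are exposed).
* `pupilSplitMI()` uses the average of the two context events' pupil
  medians per repetition; with very slow pupil drift this is equivalent to
  the per-interval median, but it is a convention.
* Mixed-effects extensions, nonlinear decoders and cross-temporal
  generalization are out of scope.
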