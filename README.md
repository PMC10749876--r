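# ctxcode

Analysis of long-lasting sensory-context effects in auditory cortical
populations.

## The problem

A cortical neuron's response to a 1-s *probe* sound depends on the *context*
— the sound or silence that immediately preceded it — for hundreds of
milliseconds, well beyond the integration window of a spectro-temporal
receptive field (STRF). `ctxcode` is an R package for researchers studying
this contextual integration in trial-based population recordings. It
provides the full chain:

* **Balanced stimulus design.** For N sounds, N sequences of N+1 sounds in
  which every ordered (context, probe) event — silence included, at
  sequence starts — occurs exactly once (an exact-cover problem, solved by
  Eulerian decomposition of the complete digraph with self-loops). A
  *contextual instance* is a probe with an unordered pair of contexts:
  N·C(N+1, 2) instances (40 for N = 4, 550 for N = 10).
* **Context-effect quantification.** Per instance, the probe-PSTH
  difference between the two contexts in Z units, ΔZ(t), at 50-ms bins; a
  cluster-mass permutation test (per-bin two-sample T, contiguous same-sign
  significant bins summed, null = max |cluster score| over shuffles of the
  trial-to-context assignment); amplitude = ∫|ΔZ| over significant bins
  (Z-score·s) and duration = end of the last significant bin (ms);
  Bonferroni across instances.
* **Sparse-code analyses.** Contextual coverage per neuron, site union,
  best neuron, and the first principal component; a *dense-code* control
  that rotates each population context-modulation vector m⃗(c,p,t) onto the
  equal-activity diagonal (component sign(⟨m⟩)·‖m⃗‖₂/√I, norm-preserving)
  while keeping probe responses and trial variability; per-bin linear SVM
  decoding of context and probe identity.
* **Category and cell-type statistics.** Similarity/identity regression in
  percent-change units, Kruskal–Wallis with Dunn post hoc tests,
  spike-width (peak-to-trough delay) classification at the KDE valley,
  pupil median-split modulation indices (large−small)/(|large|+|small|),
  jackknife confidence intervals.
* **Encoding models.** Rectified-linear GLMs, `relu(STRF⊛stim + w_self·h_self
  + Σ w_pop·h_pop + b)`, with 18 × 30 STRFs (0–300 ms) and windowed
  (150–300 ms lag) self/population history; four variants (STRF, Self, Pop,
  Full) with identical parameter counts that differ only in which history
  inputs are temporally scrambled; ADAM fitting with per-sequence
  cross-validation; context-effect prediction per 250-ms probe interval.

No recordings ship with the package. A synthetic-data generator
(`simConfig()`, `simulatePopulation()`) emulates the recorded preparation
with *known* injected context effects, cell types, coupling, and arousal,
so every stage is testable against ground truth.

## Worked example

```r
library(ctxcode)

designSequences(4, seed = 1)
#> SequenceSet: 4 sequences of 5 sounds (seed 1)
#>   3 -> 1 -> 4 -> 1 -> 1
#>   1 -> 3 -> 2 -> 2 -> 4
#>   4 -> 4 -> 2 -> 1 -> 2
#>   2 -> 3 -> 4 -> 3 -> 3

cfg <- simConfig(nNeurons = 6, nSounds = 4, nReps = 20,
                 effectSparsity = 0.12, effectAmplitudeRange = c(0.6, 1.3),
                 seed = 5)
rec <- simulatePopulation(cfg)
rec
#> PopulationRecording: 6 neurons x 80 trials x 100 bins (dt 0.050 s)
#>   sequences: N = 4 sounds; assays: counts, fineCounts

eff <- quantifyContextEffects(rec, nShuffles = 6000, seed = 2)
sig <- eff[eff$significant, ]
head(sig[, c("neuronName", "instance", "amplitudeZs", "durationMs", "minClusterP")], 4)
#>    neuronName instance amplitudeZs durationMs  minClusterP
#> 51         n2   0:1->2  0.05006007        750 0.0001666389
#> 73         n2   0:3->4  0.13862788        150 0.0001666389
#> 76         n2   1:3->4  0.15788175        350 0.0001666389
#> 78         n2   2:3->4  0.11552323        150 0.0001666389
```

42 of the 240 (neuron × instance) tests are significant (17.5%), with mean
amplitude 0.464 ± 0.333 Z-score·s and mean duration 408 ± 181 ms — each row
is one contextual instance: e.g. `0:1->2` compares the response to probe 2
after silence versus after sound 1, and its duration is the end time of its
last significant 50-ms bin. Coverage summaries show the sparse-code
ordering:

```r
cov <- neuronCoverage(eff, 40)
un  <- siteUnion(eff, 40)    # neuron-count-corrected union
bestNeuron(eff)
#> coverage: mean neuron 17.5%, best neuron (n3) 45.0%, union 67.5%
```

(The union's Bonferroni threshold of 0.05/(40 instances × 6 neurons)
requires the 6,000-shuffle resolution used above.) Downstream,
`densify()` + `decodeTimecourse()` contrast sparse and dense context codes,
and `fitPopulationModels()` / `compareModels()` /
`predictContextEffects()` run the encoding-model program. `runPipeline()`
chains all stages deterministically and writes tidy CSVs with a checksummed
manifest. See the vignette (`vignettes/context-coding.Rmd`) for the methods
in full.

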