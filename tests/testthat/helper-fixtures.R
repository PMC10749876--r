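## Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixtureCache)) assign(name, builder(), .fixtureCache)
  get(name, .fixtureCache)
}

## Deterministic (noise-free) 4-sound recording with injected effects:
## ground truth is exactly recoverable.
noiseFreeRec <- function() fixture("noiseFreeRec", function() {
  suppressWarnings(simulatePopulation(simConfig(
    nNeurons = 5, nSounds = 4, nReps = 20, effectSparsity = 0.15,
    noiseModel = "none", seed = 11)))
})

noiseFreeEffects <- function() fixture("noiseFreeEffects", function() {
  quantifyContextEffects(noiseFreeRec(), nShuffles = 2000, seed = 2)
})

## Poisson-noise recording with strong (per-bin deltaZ >= 1) exponential
## effects, used for stochastic parameter recovery.
strongPoissonRec <- function() fixture("strongPoissonRec", function() {
  suppressWarnings(simulatePopulation(simConfig(
    nNeurons = 25, nSounds = 4, nReps = 20, effectSparsity = 0.08,
    effectAmplitudeRange = c(0.8, 1.6), effectDurationRange = c(100, 300),
    effectShapes = "exponential", seed = 7)))
})

strongPoissonEffectsProfiles <- function() fixture("strongPoissonEffectsProfiles", function() {
  quantifyContextEffects(strongPoissonRec(), nShuffles = 1000, seed = 5,
                         profiles = TRUE)
})

strongPoissonEffects <- function() strongPoissonEffectsProfiles()

## Moderate site used for population-code analyses.
siteRec <- function() fixture("siteRec", function() {
  suppressWarnings(simulatePopulation(simConfig(
    nNeurons = 8, nSounds = 4, nReps = 20, effectSparsity = 0.15,
    effectAmplitudeRange = c(0.6, 1.3), seed = 5)))
})

siteSeg <- function() fixture("siteSeg", function() {
  segmentInstances(zscoreNormalize(siteRec()), assayName = "zscore")
})

## small shared encoding world: 4 blocks of white-noise "spectrogram"
encWorld <- function() fixture("encWorld", function() {
  set.seed(12)
  TT <- 1600
  list(stim = matrix(runif(18 * TT, 0, 2), 18, TT),
       blocks = rep(1:4, each = TT / 4),
       resp = matrix(runif(5 * TT, 0, 0.3), 5, TT))
})

## instances where exactly one of the two contexts carries an injection
## (their true effect equals that injection's profile)
singleInjectionMerge <- function(rec, effects) {
  gt <- groundTruth(rec)$effectMap
  inj <- groundTruth(rec)$injectedEvents
  m <- merge(effects, gt, by = c("neuron", "probe", "contextA", "contextB"))
  key <- paste(inj$neuron, inj$context, inj$probe)
  nA <- paste(m$neuron, m$contextA, m$probe) %in% key
  nB <- paste(m$neuron, m$contextB, m$probe) %in% key
  m[(nA + nB) == 1L, , drop = FALSE]
}
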