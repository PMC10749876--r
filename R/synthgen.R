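#' Simulation configuration
#'
#' Defines the conditions of a synthetic population-recording experiment:
#' the stimulus design (N one-second sounds, silence-initial sequences,
#' repeated presentations), population size and firing statistics, the
#' injected ground-truth context effects, cell-type structure, arousal
#' (pupil) dynamics and optional neuron-to-neuron coupling.
#'
#' Defaults mirror the recorded preparation this generator emulates: 20
#' repetitions per sequence, 50-ms analysis bins (20 Hz), 10-ms
#' encoding-model bins (100 Hz), and context-effect amplitudes/durations in
#' the empirically observed range (about 0.1-0.7 Z-score*s and 100-800 ms).
#'
#' @param nNeurons number of simultaneously recorded neurons.
#' @param nReps repetitions of each sequence (default 20).
#' @param nSounds number of distinct sounds N (4 or 10 typical).
#' @param binDt analysis bin width in s (default 0.05).
#' @param fineDt encoding-model bin width in s (default 0.01).
#' @param baselineRate baseline firing rate, spikes/s.
#' @param tuningSd log-normal sd of per neuron-by-sound gain.
#' @param onsetGain transient onset amplification of sound responses.
#' @param effectSparsity fraction of (neuron, context-event) pairs carrying a
#'   true injected context modulation.  An injected event (context c before
#'   probe p) makes every instance pairing c with another context on p carry
#'   a true effect.
#' @param effectAmplitudeRange range of true amplitudes, Z-score*s.
#' @param effectDurationRange range of true durations, ms (bin-quantized).
#' @param effectShapes subset of \code{c("exponential", "late-onset",
#'   "multi-peak")} sampled per injected effect.
#' @param noiseModel \code{"poisson"} (default), \code{"gaussian"}, or
#'   \code{"none"} (deterministic expected counts; used for exact
#'   parameter-recovery checks).
#' @param gaussianSd count noise sd for the gaussian model.
#' @param dpegFraction fraction of neurons labeled dPEG (rest A1).
#' @param dpegAmplitudeScale,dpegDurationScale multiplicative offsets applied
#'   to injected effect amplitude/duration for dPEG neurons.
#' @param ptdModes,ptdSds,narrowFraction two-component spike
#'   peak-to-trough-delay mixture (ms) and narrow-spiking fraction.
#' @param optotagFraction fraction of narrow-spiking neurons optotagged.
#' @param pupilGainSd sd of per-neuron multiplicative pupil gain (0 disables
#'   arousal modulation of firing).
#' @param pupilDriftAmplitude,pupilDriftPeriod slow arousal drift across the
#'   session (a.u., trials).
#' @param pupilEvokedGain sound-evoked pupil dilation per unit mean sound
#'   drive.
#' @param coupling optional neurons x neurons lagged-influence matrix
#'   (spikes/s of target per spike/s of source, 150-300 ms lag window), or
#'   NULL.
#' @param selfWeight scalar self-history weight applied over the same lag
#'   window: positive values give recurrent self-excitation, negative
#'   values firing-rate adaptation (strong negative weights drive rates
#'   into the clip at zero, which weakens the realized dependence).
#' @param seed integer seed; the whole simulation is reproducible given the
#'   config.
#' @return object of class \code{SimConfig} (a validated list).
#' @export
simConfig <- function(nNeurons = 20L, nReps = 20L, nSounds = 4L,
                      binDt = 0.05, fineDt = 0.01,
                      baselineRate = 5, tuningSd = 0.4, onsetGain = 0.6,
                      effectSparsity = 0.1,
                      effectAmplitudeRange = c(0.1, 0.7),
                      effectDurationRange = c(100, 800),
                      effectShapes = c("exponential", "late-onset", "multi-peak"),
                      noiseModel = c("poisson", "gaussian", "none"),
                      gaussianSd = 0.3,
                      dpegFraction = 0.4,
                      dpegAmplitudeScale = 1.1, dpegDurationScale = 1.05,
                      ptdModes = c(0.25, 0.70), ptdSds = c(0.04, 0.08),
                      narrowFraction = 0.25, optotagFraction = 0.15,
                      pupilGainSd = 0,
                      pupilDriftAmplitude = 0.15, pupilDriftPeriod = 40,
                      pupilEvokedGain = 0.05,
                      coupling = NULL, selfWeight = 0,
                      seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  cfg <- list(nNeurons = as.integer(nNeurons), nReps = as.integer(nReps),
              nSounds = as.integer(nSounds), binDt = binDt, fineDt = fineDt,
              baselineRate = baselineRate, tuningSd = tuningSd,
              onsetGain = onsetGain, effectSparsity = effectSparsity,
              effectAmplitudeRange = effectAmplitudeRange,
              effectDurationRange = effectDurationRange,
              effectShapes = effectShapes, noiseModel = noiseModel,
              gaussianSd = gaussianSd, dpegFraction = dpegFraction,
              dpegAmplitudeScale = dpegAmplitudeScale,
              dpegDurationScale = dpegDurationScale,
              ptdModes = ptdModes, ptdSds = ptdSds,
              narrowFraction = narrowFraction,
              optotagFraction = optotagFraction,
              pupilGainSd = pupilGainSd,
              pupilDriftAmplitude = pupilDriftAmplitude,
              pupilDriftPeriod = pupilDriftPeriod,
              pupilEvokedGain = pupilEvokedGain,
              coupling = coupling, selfWeight = selfWeight,
              seed = as.integer(seed))
  if (cfg$nNeurons < 1L || cfg$nReps < 1L || cfg$nSounds < 1L)
    stop("counts must be >= 1")
  if (cfg$baselineRate < 0) stop("rates must be >= 0")
  if (cfg$effectSparsity < 0 || cfg$effectSparsity > 1)
    stop("effectSparsity must lie in [0, 1]")
  if (abs(cfg$binDt / cfg$fineDt - round(cfg$binDt / cfg$fineDt)) > 1e-9)
    stop("binDt must be an integer multiple of fineDt")
  if (!is.null(coupling) &&
      !(is.matrix(coupling) && all(dim(coupling) == cfg$nNeurons)))
    stop("coupling must be an nNeurons x nNeurons matrix or NULL")
  structure(cfg, class = "SimConfig")
}

## Z-per-bin effect profile of a given shape, scaled so that
## sum(|z|) * binDt == amplitude and the last nonzero bin is bin `dbins`.
.effectProfile <- function(shape, amplitude, dbins, binDt, sign = 1) {
  b <- seq_len(dbins)
  w <- switch(shape,
    "exponential" = exp(-(b - 1) / max(1, dbins / 2)),
    "late-onset" = {
      onset <- max(1L, floor(dbins / 3) + 1L)
      c(rep(0, onset - 1L), exp(-(seq_len(dbins - onset + 1L) - 1) / max(1, dbins / 3)))
    },
    "multi-peak" = {
      x <- (b - 1) / max(1, dbins - 1)
      0.2 + 0.8 * (exp(-((x - 0.15)^2) / 0.02) + 0.8 * exp(-((x - 0.7)^2) / 0.03))
    },
    stop("unknown effect shape: ", shape))
  w[dbins] <- max(w[dbins], 1e-3)      # duration bin must stay nonzero
  sign * amplitude * w / (sum(abs(w)) * binDt)
}

## deterministic fine-resolution rate trace (spikes/s) of one trial of one
## sequence, before noise/coupling: baseline everywhere, tuned gain with an
## onset transient during each sound.
.baseRates <- function(cfg, tuning, seqSounds) {
  nFine <- as.integer(round(1 / cfg$fineDt))
  tt <- (seq_len(nFine) - 0.5) * cfg$fineDt
  onset <- 1 + cfg$onsetGain * exp(-tt / 0.08)
  rates <- matrix(cfg$baselineRate, cfg$nNeurons, nFine * length(seqSounds))
  for (k in seq_along(seqSounds)) {
    s <- seqSounds[k]
    if (s == 0L) next
    idx <- ((k - 1L) * nFine + 1L):(k * nFine)
    rates[, idx] <- (cfg$baselineRate * tuning[, s]) %o% onset
  }
  rates
}

#' Simulate the pupil-indexed arousal trace
#'
#' Slow sinusoidal drift across the session plus a smooth within-trial
#' component evoked by sound drive, plus seeded smooth noise.  Returned at
#' the analysis bin rate, one row per trial in presentation order.
#'
#' @param config a \code{\link{simConfig}}.
#' @param soundDrive optional trials x bins matrix of mean population drive
#'   used for the evoked component (default flat).
#' @return matrix trials x bins of positive pupil size (a.u.), with
#'   attribute \code{"perTrial"} = per-trial mean.
#' @export
simulatePupil <- function(config, soundDrive = NULL) {
  nTrials <- config$nSounds * config$nReps
  nBins <- as.integer(round((config$nSounds + 1L) / config$binDt))
  withLocalSeed(config$seed + 7L, {
    drift <- 1 + config$pupilDriftAmplitude *
      sin(2 * pi * seq_len(nTrials) / config$pupilDriftPeriod)
    noise <- stats::filter(stats::rnorm(nTrials * nBins, sd = 0.02),
                           rep(1 / 10, 10), circular = TRUE)
    p <- matrix(drift, nTrials, nBins) + matrix(as.numeric(noise), nTrials, nBins)
    if (!is.null(soundDrive))
      p <- p + config$pupilEvokedGain * soundDrive / max(mean(soundDrive), 1e-9)
    pmax(p, 0.05)
  }) -> pupil
  attr(pupil, "perTrial") <- rowMeans(pupil)
  pupil
}

#' Simulate a population recording with known ground truth
#'
#' Generates a trial-based population recording under a
#' \code{\link{simConfig}}: an exact-cover \linkS4class{SequenceSet} is
#' designed, deterministic tuned firing-rate traces are built for every
#' trial, sparse context-dependent modulations with known amplitude
#' (Z-score*s), duration (ms) and temporal shape are injected additively on
#' the probe window of selected (context -> probe) events, optional
#' self-history and population-coupling terms are applied, and spike counts
#' are drawn under the configured noise model at the 100-Hz resolution
#' (aggregated to 50-ms analysis bins).
#'
#' Injected modulations are specified as per-bin deltaZ targets and
#' converted to count deltas using the neuron's predicted count sd; the
#' returned ground truth restates them in the empirical analysis units
#' (per-neuron mean/sd of realized single-trial counts), so that with
#' \code{noiseModel = "none"} downstream effect metrics recover the ground
#' truth exactly.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \linkS4class{PopulationRecording}; \code{metadata(x)$groundTruth}
#'   holds the injected-event table, the per-instance true effect map, the
#'   tuning matrix, the coupling matrix and pupil gains.
#' @export
simulatePopulation <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  N <- cfg$nSounds; I <- cfg$nNeurons; J <- cfg$nReps
  seqset <- designSequences(N, seed = cfg$seed)
  nFine <- as.integer(round(1 / cfg$fineDt))          # fine bins per second
  agg <- as.integer(round(cfg$binDt / cfg$fineDt))    # fine bins per analysis bin
  seqFine <- nFine * (N + 1L)                         # fine bins per trial
  seqBins <- seqFine %/% agg                          # analysis bins per trial
  nTrials <- N * J

  withLocalSeed(cfg$seed, {
    ## --- neuron metadata -------------------------------------------------
    region <- ifelse(stats::runif(I) < cfg$dpegFraction, "dPEG", "A1")
    narrow <- stats::runif(I) < cfg$narrowFraction
    ptd <- ifelse(narrow,
                  stats::rnorm(I, cfg$ptdModes[1], cfg$ptdSds[1]),
                  stats::rnorm(I, cfg$ptdModes[2], cfg$ptdSds[2]))
    ptd <- pmax(ptd, 0.05)
    optotagged <- narrow & stats::runif(I) < cfg$optotagFraction
    trueClass <- ifelse(narrow, "narrow", "broad")
    tuning <- matrix(exp(stats::rnorm(I * N, 0, cfg$tuningSd)), I, N)
    pupilGain <- if (cfg$pupilGainSd > 0) stats::rnorm(I, 0, cfg$pupilGainSd) else rep(0, I)

    ## --- per-sequence deterministic base rates ---------------------------
    baseBySeq <- lapply(seqset@sequences, function(s) .baseRates(cfg, tuning, s))

    ## predicted per-neuron count sd (for Z -> count conversion);
    ## coarse expectation per analysis bin:
    coarseMu <- do.call(cbind, lapply(baseBySeq, function(m) {
      mm <- m * cfg$fineDt
      t(apply(mm, 1L, function(x) colSums(matrix(x, nrow = agg))))
    }))
    noiseVar <- switch(cfg$noiseModel,
                       poisson = rowMeans(coarseMu),
                       gaussian = agg * cfg$gaussianSd^2,
                       none = 0)
    sd0 <- sqrt(apply(coarseMu, 1L, stats::var) * (ncol(coarseMu) - 1) / ncol(coarseMu) +
                noiseVar)
    sd0 <- pmax(sd0, 1e-6)

    ## --- injected context effects ---------------------------------------
    events <- sequenceEvents(seqset)                  # N(N+1) rows
    nb <- as.integer(round(1 / cfg$binDt))
    nEvents <- nrow(events)
    nInject <- round(cfg$effectSparsity * I * nEvents)
    injected <- if (nInject > 0) {
      pick <- sample.int(I * nEvents, nInject)
      data.frame(neuron = ((pick - 1L) %% I) + 1L,
                 event = ((pick - 1L) %/% I) + 1L)
    } else data.frame(neuron = integer(), event = integer())
    if (nrow(injected)) {
      injected$context <- events$context[injected$event]
      injected$probe <- events$probe[injected$event]
      injected$sequence <- events$sequence[injected$event]
      injected$position <- events$position[injected$event]
      injected$shape <- sample(cfg$effectShapes, nrow(injected), replace = TRUE)
      injected$sign <- sample(c(-1, 1), nrow(injected), replace = TRUE)
      amp <- stats::runif(nrow(injected), cfg$effectAmplitudeRange[1],
                          cfg$effectAmplitudeRange[2])
      dur <- stats::runif(nrow(injected), cfg$effectDurationRange[1],
                          cfg$effectDurationRange[2])
      isD <- region[injected$neuron] == "dPEG"
      amp[isD] <- amp[isD] * cfg$dpegAmplitudeScale
      dur[isD] <- dur[isD] * cfg$dpegDurationScale
      injected$amplitudeZs <- amp
      injected$durationMs <- pmin(pmax(round(dur / (cfg$binDt * 1000)), 1), seqBins) *
        cfg$binDt * 1000
      injected$durationMs <- pmin(injected$durationMs, 1000)
    }
    ## per-injection count-delta profile at analysis resolution
    profiles <- vector("list", nrow(injected))
    if (nrow(injected)) for (k in seq_len(nrow(injected))) {
      dbins <- as.integer(injected$durationMs[k] / (cfg$binDt * 1000))
      z <- .effectProfile(injected$shape[k], injected$amplitudeZs[k], dbins,
                          cfg$binDt, injected$sign[k])
      profiles[[k]] <- z * sd0[injected$neuron[k]]    # delta counts per bin
    }

    ## --- assemble modulated fine-rate traces per sequence ----------------
    rateBySeq <- lapply(seq_len(N), function(sq) baseBySeq[[sq]])
    if (nrow(injected)) for (k in seq_len(nrow(injected))) {
      sq <- injected$sequence[k]; pos <- injected$position[k]
      i <- injected$neuron[k]
      dc <- profiles[[k]]                              # per coarse bin counts
      dRateFine <- c(rep(dc / cfg$binDt, each = agg),  # spread evenly in bin
                     rep(0, nFine - length(dc) * agg))
      idx <- ((pos - 1L) * nFine + 1L):(pos * nFine)
      rateBySeq[[sq]][i, idx] <- rateBySeq[[sq]][i, idx] + dRateFine
    }
    ## negative rates are clipped here, before noise, so that ground truth
    ## can be restated from the realized (clipped) rate differences
    clipCount <- 0L
    for (sq in seq_len(N)) {
      neg <- rateBySeq[[sq]] < 0
      clipCount <- clipCount + sum(neg)
      if (any(neg)) rateBySeq[[sq]][neg] <- 0
    }
    ## realized expected coarse counts per (context, probe) event window
    eventCounts <- array(0, dim = c(I, N + 1L, N, nb))  # neuron x ctx x probe x bin
    for (r in seq_len(nrow(events))) {
      sq <- events$sequence[r]; pos <- events$position[r]
      idx <- ((pos - 1L) * nFine + 1L):(pos * nFine)
      mm <- rateBySeq[[sq]][, idx, drop = FALSE] * cfg$fineDt
      eventCounts[, events$context[r] + 1L, events$probe[r], ] <-
        t(rowsum(t(mm), rep(seq_len(nb), each = agg)))
    }

    ## --- pupil -----------------------------------------------------------
    presOrder <- sample.int(nTrials)   # presOrder[i] = presentation position of trial i
    trialSeq <- rep(seq_len(N), each = J)
    trialRep <- rep(seq_len(J), times = N)
    drive <- t(vapply(trialSeq, function(sq) {
      m <- colMeans(rateBySeq[[sq]]) * cfg$fineDt
      colSums(matrix(m, nrow = agg))
    }, numeric(seqBins)))
    pupilByPos <- simulatePupil(cfg, soundDrive = drive[order(presOrder), , drop = FALSE])
    pupil <- pupilByPos[presOrder, , drop = FALSE]     # rows back in trial order
    attr(pupil, "perTrial") <- rowMeans(pupil)
    pupilTrial <- rowMeans(pupil)

    ## --- draw counts ------------------------------------------------------
    fineCounts <- array(0, dim = c(I, nTrials, seqFine))
    lagLo <- as.integer(round(0.15 / cfg$fineDt))
    lagHi <- as.integer(round(0.30 / cfg$fineDt))
    hasHistory <- !is.null(cfg$coupling) || cfg$selfWeight != 0
    W <- if (is.null(cfg$coupling)) matrix(0, I, I) else cfg$coupling
    diag(W) <- diag(W) + cfg$selfWeight
    for (tr in seq_len(nTrials)) {
      lam <- rateBySeq[[trialSeq[tr]]]
      if (cfg$pupilGainSd > 0) {
        pg <- 1 + pupilGain %o% rep((pupilTrial[tr] - 1), seqFine)
        lam <- lam * pmax(pg, 0)
      }
      if (!hasHistory) {
        mu <- pmax(lam, 0) * cfg$fineDt
        fineCounts[, tr, ] <- switch(cfg$noiseModel,
          poisson = matrix(stats::rpois(length(mu), mu), I, seqFine),
          gaussian = pmax(mu + matrix(stats::rnorm(length(mu), 0, cfg$gaussianSd),
                                      I, seqFine), 0),
          none = mu)
      } else {
        ## sequential generation: rate depends on windowed mean of past counts
        cnt <- matrix(0, I, seqFine)
        for (b in seq_len(seqFine)) {
          h <- if (b > lagLo) {
            w0 <- max(1L, b - lagHi); w1 <- b - lagLo
            rowMeans(cnt[, w0:w1, drop = FALSE]) / cfg$fineDt
          } else rep(0, I)
          lb <- lam[, b] + as.numeric(W %*% h)
          nneg <- lb < 0
          clipCount <- clipCount + sum(nneg)
          lb <- pmax(lb, 0)
          mu <- lb * cfg$fineDt
          cnt[, b] <- switch(cfg$noiseModel,
            poisson = stats::rpois(I, mu),
            gaussian = pmax(mu + stats::rnorm(I, 0, cfg$gaussianSd), 0),
            none = mu)
        }
        fineCounts[, tr, ] <- cnt
      }
    }
    if (clipCount > 0)
      warning(sprintf("%d rate value(s) clipped at 0 during simulation", clipCount))

    ## aggregate to analysis bins
    counts <- array(0, dim = c(I, nTrials, seqBins))
    grp <- rep(seq_len(seqBins), each = agg)
    for (tr in seq_len(nTrials))
      counts[, tr, ] <- t(rowsum(t(matrix(fineCounts[, tr, ], I, seqFine)), grp))

    ## --- empirical normalization and ground truth ------------------------
    ## Truth is restated in the analysis units: the realized (clipped,
    ## pre-noise, nominal-arousal, no-coupling) expected-count difference
    ## between the two contexts of an instance, divided by the neuron's
    ## empirical count sd -- exactly what the downstream Z-scored PSTH
    ## difference estimates.
    empMean <- apply(counts, 1L, mean)
    empSd <- apply(counts, 1L, stats::sd)
    instances <- enumerateInstances(N)
    gtRows <- list()
    touched <- unique(injected$neuron)
    for (i in touched) {
      for (r in seq_len(nrow(instances))) {
        p <- instances$probe[r]
        dz <- (eventCounts[i, instances$contextA[r] + 1L, p, ] -
               eventCounts[i, instances$contextB[r] + 1L, p, ]) / empSd[i]
        nz <- which(abs(dz) > 1e-12)
        if (!length(nz)) next
        gtRows[[length(gtRows) + 1L]] <- data.frame(
          neuron = i, probe = p,
          contextA = instances$contextA[r], contextB = instances$contextB[r],
          instance = instances$instance[r],
          trueAmplitudeZs = sum(abs(dz[nz])) * cfg$binDt,
          trueDurationMs = max(nz) * cfg$binDt * 1000)
      }
    }
    effectMap <- if (length(gtRows)) do.call(rbind, gtRows) else
      data.frame(neuron = integer(), probe = integer(), contextA = integer(),
                 contextB = integer(), instance = character(),
                 trueAmplitudeZs = numeric(), trueDurationMs = numeric())

    neuronTable <- DataFrame(region = region, ptdMs = ptd,
                             optotagged = optotagged, trueClass = trueClass,
                             row.names = paste0("n", seq_len(I)))
    trialTable <- DataFrame(sequence = trialSeq, repetition = trialRep,
                            presentationOrder = presOrder,
                            row.names = paste0("t", seq_len(nTrials)))
    gt <- list(injectedEvents = injected, effectMap = effectMap,
               tuning = tuning, coupling = cfg$coupling,
               selfWeight = cfg$selfWeight, pupilGain = pupilGain,
               empMean = empMean, empSd = empSd, clipCount = clipCount)
    se <- SummarizedExperiment(
      assays = list(counts = counts, fineCounts = fineCounts),
      rowData = neuronTable, colData = trialTable)
    metadata(se) <- list(sequences = seqset, binDt = cfg$binDt,
                         fineDt = cfg$fineDt, pupil = pupil,
                         groundTruth = gt, config = cfg)
    new("PopulationRecording", se)
  })
}

#' Segment a recording into instance-aligned probe responses
#'
#' Rearranges the trial-by-time count array into the probe-window tensor
#' r[neuron, context, probe, repetition, bin]: for every (context, probe)
#' event of the sequence design, the 1-s probe window of every repetition at
#' the analysis rate.  Silence context is taken from sequence-initial sounds.
#'
#' @param rec a \linkS4class{PopulationRecording}.
#' @param assayName assay to segment (default \code{"counts"}; use a
#'   Z-scored assay for effect quantification).
#' @param fine logical; segment the 100-Hz assay instead (for encoding-model
#'   evaluation).
#' @return 5-D array neurons x (N+1) contexts x N probes x reps x bins, with
#'   context dimnames \code{"0"..."N"}.
#' @export
segmentInstances <- function(rec, assayName = "counts", fine = FALSE) {
  seqset <- metadata(rec)$sequences
  N <- seqset@nSounds
  dt <- if (fine) metadata(rec)$fineDt else metadata(rec)$binDt
  if (fine && !("fineCounts" %in% names(assays(rec))))
    stop("recording has no fine-resolution assay")
  a <- assays(rec)[[if (fine) "fineCounts" else assayName]]
  I <- dim(a)[1]
  nb <- as.integer(round(1 / dt))
  trialSeq <- colData(rec)$sequence
  reps <- colData(rec)$repetition
  ev <- sequenceEvents(seqset)
  J <- max(reps)
  out <- array(NA_real_, dim = c(I, N + 1L, N, J, nb),
               dimnames = list(rownames(rec), as.character(0:N),
                               as.character(seq_len(N)), NULL, NULL))
  for (r in seq_len(nrow(ev))) {
    trIdx <- which(trialSeq == ev$sequence[r])
    win <- ((ev$position[r] - 1L) * nb + 1L):(ev$position[r] * nb)
    for (tr in trIdx)
      out[, ev$context[r] + 1L, ev$probe[r], reps[tr], ] <- a[, tr, win]
  }
  if (anyNA(out)) stop("coverage error: some (context, probe) events missing from the design")
  out
}
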