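#' Z-score normalize a recording
#'
#' Normalizes each neuron's binned single-trial activity as a Z-score using
#' the mean and standard deviation taken across the entire recording
#' (spontaneous and evoked bins alike).  Neurons with zero variance cannot
#' be normalized and are dropped with a message.
#'
#' @param rec a \linkS4class{PopulationRecording}.
#' @return the recording with an additional \code{"zscore"} assay (and the
#'   zero-variance neurons removed from all assays); the excluded neuron
#'   names are recorded in \code{metadata(x)$excludedNeurons}.
#' @export
zscoreNormalize <- function(rec) {
  cnt <- spikeCounts(rec)
  m <- apply(cnt, 1L, mean)
  s <- apply(cnt, 1L, stats::sd)
  keep <- s > 0
  if (!all(keep))
    message(sprintf("excluding %d zero-variance neuron(s): %s",
                    sum(!keep), paste(rownames(rec)[!keep], collapse = ", ")))
  rec2 <- rec[keep, ]
  z <- sweep(sweep(spikeCounts(rec2), 1L, m[keep], "-"), 1L, s[keep], "/")
  assays(rec2, withDimnames = FALSE)[["zscore"]] <- z
  metadata(rec2)$excludedNeurons <- rownames(rec)[!keep]
  metadata(rec2)$zMean <- m[keep]
  metadata(rec2)$zSd <- s[keep]
  rec2
}

#' Split-half reliability filter
#'
#' Keeps neurons whose trial-averaged responses are reproducible: trials of
#' each sequence are split into random halves, PSTHs at the analysis rate
#' are computed for each half and concatenated across sequences, and the
#' neuron is kept if the Pearson correlation between half PSTHs exceeds the
#' threshold.
#'
#' @param rec a \linkS4class{PopulationRecording}.
#' @param threshold correlation threshold (default 0.1).
#' @param seed seed for the random half split.
#' @return integer indices of the retained neurons, with the per-neuron
#'   correlations as attribute \code{"reliability"}.
#' @export
reliabilityFilter <- function(rec, threshold = 0.1, seed = 1L) {
  cnt <- spikeCounts(rec)
  seqIdx <- trialData(rec)$sequence
  I <- dim(cnt)[1]
  withLocalSeed(seed, {
    psthA <- psthB <- NULL
    for (sq in sort(unique(seqIdx))) {
      tr <- which(seqIdx == sq)
      if (length(tr) < 2L) stop("need >= 2 trials per stimulus")
      half <- sample(tr, floor(length(tr) / 2))
      other <- setdiff(tr, half)
      pa <- apply(cnt[, half, , drop = FALSE], c(1L, 3L), mean)
      pb <- apply(cnt[, other, , drop = FALSE], c(1L, 3L), mean)
      psthA <- cbind(psthA, pa)
      psthB <- cbind(psthB, pb)
    }
    r <- vapply(seq_len(I), function(i) {
      if (stats::sd(psthA[i, ]) == 0 || stats::sd(psthB[i, ]) == 0) return(0)
      stats::cor(psthA[i, ], psthB[i, ])
    }, numeric(1))
    keep <- which(r > threshold)
    attr(keep, "reliability") <- r
    keep
  })
}

#' Cluster-mass permutation test between two context conditions
#'
#' Implements the cluster-based correction for multiple comparisons over
#' time: a two-sample T score is computed per time bin between the probe
#' responses following the two contexts; contiguous bins with per-bin
#' p < \code{binAlpha} and the same T sign form clusters scored by their
#' summed T; each cluster's p value is the permutation tail probability of
#' its absolute score under the null distribution of the maximum absolute
#' cluster score obtained by reshuffling the trial-to-context assignment.
#'
#' Bins where both conditions have zero variance get T = 0 when the means
#' agree (non-significant) and an infinite T when they differ (the
#' deterministic, noise-free limit).
#'
#' @param rA,rB trials x bins matrices of Z-scored probe responses under
#'   context A and B.
#' @param nShuffles number of random context-identity shuffles (default
#'   11000).
#' @param binAlpha per-bin cluster-forming alpha (default 0.05).
#' @param clusterAlpha cluster-level alpha defining the significance mask
#'   (default 0.05).
#' @param welch use the Welch rather than pooled-variance T (default FALSE).
#' @param seed permutation seed.
#' @param binDt bin width in seconds (for downstream metrics).
#' @return an \linkS4class{EffectProfile}.
#' @export
clusterMassTest <- function(rA, rB, nShuffles = 11000L, binAlpha = 0.05,
                            clusterAlpha = 0.05, welch = FALSE, seed = 1L,
                            binDt = 0.05) {
  rA <- as.matrix(rA); rB <- as.matrix(rB)
  if (ncol(rA) != ncol(rB)) stop("conditions must have equal bin counts")
  nA <- nrow(rA); nB <- nrow(rB)
  if (nA < 2L || nB < 2L) stop("need >= 2 trials per condition")
  B <- ncol(rA)
  X <- rbind(rA, rB)
  n <- nA + nB

  colStats <- function(idxA) {
    xa <- X[idxA, , drop = FALSE]
    xb <- X[-idxA, , drop = FALSE]
    mA <- colMeans(xa); mB <- colMeans(xb)
    ssA <- colSums(xa^2) - nA * mA^2
    ssB <- colSums(xb^2) - nB * mB^2
    .colT(mA, mB, pmax(ssA, 0), pmax(ssB, 0), nA, nB, welch = welch)
  }
  obs <- colStats(seq_len(nA))
  tcritObs <- stats::qt(1 - binAlpha / 2, obs$df)   # vector under Welch
  clusters <- .findClusters(obs$t, tcritObs)
  delta <- colMeans(rA) - colMeans(rB)

  if (nrow(clusters)) {
    ## vectorized permutation null of the max |cluster mass|
    nullMax <- withLocalSeed(seed, {
      S <- matrix(0, n, nShuffles)
      for (s in seq_len(nShuffles)) S[sample.int(n, nA), s] <- 1
      mA <- crossprod(X, S) / nA                 # B x nShuffles
      mB <- crossprod(X, 1 - S) / nB
      qA <- crossprod(X^2, S); qB <- crossprod(X^2, 1 - S)
      ssA <- pmax(qA - nA * mA^2, 0); ssB <- pmax(qB - nB * mB^2, 0)
      tdf <- .colT(mA, mB, ssA, ssB, nA, nB, welch = welch)
      tc <- stats::qt(1 - binAlpha / 2, tdf$df)  # matrix under Welch
      vapply(seq_len(nShuffles), function(s)
        .maxClusterMass(tdf$t[, s], if (is.matrix(tc)) tc[, s] else tc),
        numeric(1))
    })
    clusters$p <- vapply(clusters$mass, function(m)
      (1 + sum(nullMax >= abs(m))) / (nShuffles + 1), numeric(1))
  } else {
    clusters$p <- numeric(0)
  }
  sigMask <- rep(FALSE, B)
  for (k in seq_len(nrow(clusters)))
    if (clusters$p[k] < clusterAlpha)
      sigMask[clusters$start[k]:clusters$end[k]] <- TRUE
  new("EffectProfile", delta = delta, tscore = as.numeric(obs$t),
      sigMask = sigMask, clusters = clusters, binDt = binDt)
}

#' Amplitude and duration of a context effect
#'
#' Amplitude is the integral of |deltaZ| over the significant time bins
#' (Z-score*s); duration is the end time of the last significant bin (ms).
#' Both are zero when no cluster is significant.
#'
#' @param profile an \linkS4class{EffectProfile}.
#' @param bonferroniThreshold optional family-corrected cluster-p threshold;
#'   the \code{significant} flag is \code{min cluster p < threshold}.
#' @return list with \code{amplitude} (Z-score*s), \code{duration} (ms),
#'   \code{minClusterP}, \code{significant}.
#' @export
effectMetrics <- function(profile, bonferroniThreshold = 0.05) {
  sig <- profile@sigMask
  amplitude <- if (any(sig)) sum(abs(profile@delta[sig])) * profile@binDt else 0
  duration <- if (any(sig)) max(which(sig)) * profile@binDt * 1000 else 0
  minP <- if (nrow(profile@clusters)) min(profile@clusters$p) else NA_real_
  list(amplitude = amplitude, duration = duration, minClusterP = minP,
       significant = !is.na(minP) && minP < bonferroniThreshold)
}

#' Bonferroni correction across contextual instances
#'
#' Each neuron is tested over all its contextual instances (and, for
#' site-level unions, each neuron is itself a source of multiple
#' comparisons), so instance significance requires the minimum cluster p to
#' beat \code{familyAlpha / (nInstances * nExtraComparisons)}.
#'
#' @param effects data.frame with a \code{minClusterP} column (one row per
#'   neuron x instance).
#' @param nInstances number of instances tested per neuron.
#' @param familyAlpha family-wise error rate (default 0.05).
#' @param nExtraComparisons extra comparison factor, e.g. the number of
#'   neurons in a site union (default 1).
#' @return the data.frame with a logical \code{significant} column (and the
#'   threshold as attribute \code{"threshold"}).
#' @export
correctInstances <- function(effects, nInstances, familyAlpha = 0.05,
                             nExtraComparisons = 1L) {
  thr <- familyAlpha / (nInstances * nExtraComparisons)
  effects$significant <- !is.na(effects$minClusterP) & effects$minClusterP < thr
  attr(effects, "threshold") <- thr
  effects
}

#' Quantify context effects for every neuron and contextual instance
#'
#' Runs the full per-instance pipeline on a recording: Z-score
#' normalization, probe-window segmentation, the cluster-mass test for every
#' (neuron, probe, context pair), amplitude/duration metrics, and Bonferroni
#' correction across instances (times \code{nExtraComparisons} if given).
#'
#' @param rec a \linkS4class{PopulationRecording}.
#' @param nShuffles permutations per test (default 11000; reduce for quick
#'   exploration).
#' @param binAlpha,clusterAlpha,welch passed to \code{\link{clusterMassTest}}.
#' @param familyAlpha,nExtraComparisons passed to
#'   \code{\link{correctInstances}}.
#' @param seed base seed; each instance uses an offset substream.
#' @param neurons optional subset of neuron indices (after zero-variance
#'   exclusion).
#' @param profiles return the per-instance \linkS4class{EffectProfile}s as
#'   attribute \code{"profiles"} (needed by the amplitude-duration
#'   association test).
#' @return tidy data.frame: neuron, neuronName, probe, contextA, contextB,
#'   instance, amplitudeZs, durationMs, minClusterP, significant.
#' @export
quantifyContextEffects <- function(rec, nShuffles = 11000L, binAlpha = 0.05,
                                   clusterAlpha = 0.05, welch = FALSE,
                                   familyAlpha = 0.05, nExtraComparisons = 1L,
                                   seed = 1L, neurons = NULL,
                                   profiles = FALSE) {
  recz <- if ("zscore" %in% names(assays(rec))) rec else zscoreNormalize(rec)
  seg <- segmentInstances(recz, assayName = "zscore")
  N <- sequenceSet(rec)@nSounds
  inst <- enumerateInstances(N)
  I <- dim(seg)[1]
  if (is.null(neurons)) neurons <- seq_len(I)
  rows <- vector("list", length(neurons) * nrow(inst))
  profs <- if (profiles) vector("list", length(neurons) * nrow(inst)) else NULL
  k <- 0L
  for (i in neurons) {
    for (r in seq_len(nrow(inst))) {
      k <- k + 1L
      rA <- seg[i, inst$contextA[r] + 1L, inst$probe[r], , ]
      rB <- seg[i, inst$contextB[r] + 1L, inst$probe[r], , ]
      prof <- clusterMassTest(rA, rB, nShuffles = nShuffles,
                              binAlpha = binAlpha, clusterAlpha = clusterAlpha,
                              welch = welch, seed = seed + 7919L * k,
                              binDt = metadata(rec)$binDt)
      met <- effectMetrics(prof)
      rows[[k]] <- data.frame(neuron = i, neuronName = rownames(recz)[i],
                              probe = inst$probe[r],
                              contextA = inst$contextA[r],
                              contextB = inst$contextB[r],
                              instance = inst$instance[r],
                              amplitudeZs = met$amplitude,
                              durationMs = met$duration,
                              minClusterP = met$minClusterP)
      if (profiles) profs[[k]] <- prof
    }
  }
  out <- do.call(rbind, rows)
  out <- correctInstances(out, nInstances = nrow(inst),
                          familyAlpha = familyAlpha,
                          nExtraComparisons = nExtraComparisons)
  if (profiles) attr(out, "profiles") <- profs
  out
}

#' Shuffle-validated amplitude-duration association
#'
#' Amplitude (an integral over significant bins) and duration (the last
#' significant bin) are correlated by construction.  This test asks whether
#' the observed Pearson correlation across instances exceeds that intrinsic
#' baseline: the time bins of each effect profile (deltaZ together with its
#' significance mask) are randomly permuted, which preserves every
#' amplitude but randomizes every duration, and the correlation is
#' recomputed for each of \code{nShuffles} permutations.
#'
#' @param effects data.frame from \code{\link{quantifyContextEffects}} run
#'   with \code{profiles = TRUE} (or a list of profiles via
#'   \code{profileList}).
#' @param profileList optional list of \linkS4class{EffectProfile}s parallel
#'   to the rows of \code{effects}.
#' @param nShuffles permutations (default 1000).
#' @param seed permutation seed.
#' @param onlySignificant restrict to significant instances (default TRUE).
#' @return list with \code{r} (observed), \code{null} (numeric vector),
#'   \code{p} (add-one permutation tail), \code{nInstances}, and
#'   \code{degenerate} (TRUE when durations cannot vary under shuffling).
#' @export
amplitudeDurationAssociation <- function(effects, profileList = NULL,
                                         nShuffles = 1000L, seed = 1L,
                                         onlySignificant = TRUE) {
  if (is.null(profileList)) profileList <- attr(effects, "profiles")
  if (is.null(profileList))
    stop("need per-instance profiles (run quantifyContextEffects(profiles = TRUE))")
  use <- if (onlySignificant) which(effects$significant) else
    which(vapply(profileList, function(p) any(p@sigMask), logical(1)))
  if (length(use) < 3L) stop("need >= 3 significant instances")
  amp <- effects$amplitudeZs[use]
  dur <- effects$durationMs[use]
  if (stats::sd(dur) == 0 || stats::sd(amp) == 0)
    return(list(r = NA_real_, null = numeric(0), p = NA_real_,
                nInstances = length(use), degenerate = TRUE))
  robs <- stats::cor(amp, dur)
  masks <- lapply(profileList[use], function(p) p@sigMask)
  nb <- length(masks[[1L]])
  binDt <- profileList[[use[1L]]]@binDt
  null <- withLocalSeed(seed, vapply(seq_len(nShuffles), function(s) {
    ds <- vapply(masks, function(m) {
      perm <- sample.int(nb)
      mp <- m[perm]
      if (any(mp)) max(which(mp)) * binDt * 1000 else 0
    }, numeric(1))
    if (stats::sd(ds) == 0) return(NA_real_)
    stats::cor(amp, ds)
  }, numeric(1)))
  null <- null[!is.na(null)]
  degenerate <- length(null) == 0L
  p <- if (degenerate) NA_real_ else (1 + sum(null >= robs)) / (length(null) + 1)
  list(r = robs, null = null, p = p, nInstances = length(use),
       degenerate = degenerate)
}
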