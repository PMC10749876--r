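#' Per-neuron contextual coverage
#'
#' Coverage of the context space: the percentage of tested contextual
#' instances in which a neuron shows a significant context effect (after
#' Bonferroni correction).
#'
#' @param effects tidy effects table from
#'   \code{\link{quantifyContextEffects}} (with a \code{significant}
#'   column).
#' @param nInstances total instances tested per neuron.
#' @return data.frame: neuron, nSignificant, coveragePct, meanAmplitudeZs
#'   (mean over significant instances, NA if none).
#' @export
neuronCoverage <- function(effects, nInstances) {
  sp <- split(effects, effects$neuron)
  out <- do.call(rbind, lapply(sp, function(d) {
    ns <- sum(d$significant)
    data.frame(neuron = d$neuron[1L],
               nSignificant = ns,
               coveragePct = 100 * ns / nInstances,
               meanAmplitudeZs = if (ns) mean(d$amplitudeZs[d$significant]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Site union of context effects
#'
#' Pools the context effects of all neurons recorded at a site: for every
#' contextual instance the largest significant amplitude across neurons is
#' kept (zero when no neuron is significant).  Because every neuron is an
#' additional source of multiple comparisons, significance is re-corrected
#' with the neuron count included in the Bonferroni factor.
#'
#' @param effects tidy effects table (uncorrected p values in
#'   \code{minClusterP}).
#' @param nInstances instances tested per neuron.
#' @param familyAlpha family-wise alpha (default 0.05).
#' @return list with \code{perInstance} (instance, unionAmplitudeZs,
#'   nSignificantNeurons), \code{coveragePct}, and \code{threshold}.
#' @export
siteUnion <- function(effects, nInstances, familyAlpha = 0.05) {
  nNeurons <- length(unique(effects$neuron))
  if (nNeurons == 0L) stop("empty site")
  eff <- correctInstances(effects, nInstances, familyAlpha,
                          nExtraComparisons = nNeurons)
  sp <- split(eff, eff$instance)
  per <- do.call(rbind, lapply(sp, function(d) {
    sig <- d[d$significant, , drop = FALSE]
    data.frame(instance = d$instance[1L],
               unionAmplitudeZs = if (nrow(sig)) max(sig$amplitudeZs) else 0,
               nSignificantNeurons = nrow(sig))
  }))
  rownames(per) <- NULL
  list(perInstance = per,
       coveragePct = 100 * sum(per$nSignificantNeurons > 0) / nInstances,
       threshold = attr(eff, "threshold"))
}

#' Best neuron of a site
#'
#' The neuron with the greatest contextual coverage (number of significant
#' instances); ties are broken by the larger summed significant amplitude,
#' then by the lowest neuron id.
#'
#' @param effects tidy effects table with a \code{significant} column.
#' @return integer neuron id, with attributes \code{"nSignificant"} and
#'   \code{"coveragePct"} (over the instances present in the table) and
#'   \code{"allZero"} flagging a site with no significant instance at all.
#' @export
bestNeuron <- function(effects) {
  sp <- split(effects, effects$neuron)
  score <- t(vapply(sp, function(d)
    c(n = sum(d$significant),
      amp = sum(d$amplitudeZs[d$significant])), numeric(2)))
  ids <- as.integer(names(sp))
  ord <- order(-score[, "n"], -score[, "amp"], ids)
  best <- ids[ord[1L]]
  attr(best, "nSignificant") <- unname(score[ord[1L], "n"])
  attr(best, "allZero") <- all(score[, "n"] == 0)
  best
}

#' Context effects of the first population principal component
#'
#' Fits PCA on trial-averaged responses (time points x neurons,
#' concatenated over sequences), keeps the leading components explaining
#' the requested variance fraction, projects single-trial responses, and
#' analyzes the first component exactly like a single neuron through the
#' cluster-mass pipeline.  PC1's sign is fixed by positive correlation with
#' the mean population rate.
#'
#' @param rec a \linkS4class{PopulationRecording} (>= 2 neurons).
#' @param varianceFraction PC set retained for bookkeeping (default 0.9).
#' @param ... passed to \code{\link{quantifyContextEffects}} (nShuffles,
#'   seed, ...).
#' @return the PC1 effects table (as from
#'   \code{\link{quantifyContextEffects}}), with attributes
#'   \code{"nPCs"} (components needed for the variance fraction) and
#'   \code{"varExplained"}.
#' @export
pc1Coverage <- function(rec, varianceFraction = 0.9, ...) {
  cnt <- spikeCounts(rec)
  I <- dim(cnt)[1]
  if (I < 2L) stop("need >= 2 neurons")
  seqIdx <- trialData(rec)$sequence
  ## trial-averaged time x neuron matrix, concatenated over sequences
  avg <- do.call(rbind, lapply(sort(unique(seqIdx)), function(sq) {
    t(apply(cnt[, seqIdx == sq, , drop = FALSE], c(1L, 3L), mean))
  }))
  pc <- stats::prcomp(avg, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  nPCs <- which(cumsum(ve) >= varianceFraction)[1L]
  w <- pc$rotation[, 1L]
  ## project single trials
  nTrials <- dim(cnt)[2]; nBins <- dim(cnt)[3]
  proj <- matrix(0, nTrials, nBins)
  for (tr in seq_len(nTrials))
    proj[tr, ] <- as.numeric(crossprod(matrix(cnt[, tr, ], I) - pc$center, w))
  popRate <- apply(cnt, c(2L, 3L), mean)
  if (stats::cor(as.numeric(proj), as.numeric(popRate)) < 0) proj <- -proj
  ## wrap PC1 as a one-neuron recording (shifted to satisfy non-negativity;
  ## the analysis Z-scores it, so the shift is immaterial)
  arr <- array(proj - min(proj), dim = c(1L, nTrials, nBins),
               dimnames = list("PC1", colnames(rec), NULL))
  se <- SummarizedExperiment(assays = list(counts = arr),
                             colData = colData(rec))
  metadata(se) <- list(sequences = sequenceSet(rec),
                       binDt = metadata(rec)$binDt)
  pcrec <- new("PopulationRecording", se)
  out <- quantifyContextEffects(pcrec, ...)
  attr(out, "nPCs") <- nPCs
  attr(out, "varExplained") <- ve
  out
}

#' Impose a dense context code on an instance tensor
#'
#' Rotates each population context-modulation vector onto the equal-activity
#' diagonal so that context effects become identical across neurons while
#' total modulation magnitude, context-independent probe responses and
#' single-trial variability are preserved, then rescales the rotated context
#' component toward the original across-context variance of trial-averaged
#' responses.
#'
#' Steps, per probe p, context c, neuron i, trial j and time t:
#' mean probe response \code{rBar} (average over c, j); context modulation
#' \code{m = <r - rBar>_j}; rotation offsets \code{l = m - a} with diagonal
#' target \code{a = sign(<m>_i) * ||m||_2 / sqrt(I)} (L2-norm preserving;
#' the plain \code{||m||_2 / I} reading is available via
#' \code{magnitude = "l2overI"}); rotated responses \code{rTilde = r - l};
#' across-context variances \code{v}, \code{vTilde} of trial-averaged
#' responses; and variance-corrected \code{rHat} obtained by scaling the
#' (context-centered) rotated context component by \code{<v>_i / vTilde}
#' (\code{varianceRatio = "sqrt"} scales by the square root of the ratio
#' instead, the convention that would restore a variance exactly when the
#' scaled component carries all of it; the context component here is
#' probe-averaged, so either convention is a calibrated approximation).
#'
#' Because the rotation replaces each neuron's modulation by a common
#' target, recomputed modulations are identical across neurons exactly; the
#' targets preserve each population modulation's L2 norm exactly
#' (\code{mTarget}); and the context-averaged probe response of every
#' neuron is restored exactly after removing the context-independent
#' rotation offset.  Recomputed (re-centered) modulations differ from the
#' targets by their context mean, which the targets need not share.
#'
#' @param r 5-D array neurons x contexts x probes x trials x bins (from
#'   \code{\link{segmentInstances}}).
#' @param magnitude diagonal-target magnitude convention.
#' @param varianceRatio variance-correction convention.
#' @return list of class \code{"DenseTransform"} with elements \code{r},
#'   \code{rBar}, \code{m}, \code{l}, \code{mTarget} (imposed modulations),
#'   \code{rTilde}, \code{v}, \code{vTilde}, \code{rHat}.
#' @export
densify <- function(r, magnitude = c("l2sqrt", "l2overI"),
                    varianceRatio = c("printed", "sqrt")) {
  magnitude <- match.arg(magnitude)
  varianceRatio <- match.arg(varianceRatio)
  d <- dim(r)
  if (length(d) != 5L) stop("r must be neurons x contexts x probes x trials x bins")
  I <- d[1]; C <- d[2]; P <- d[3]; J <- d[4]; TT <- d[5]
  if (C < 2L) {                       # single context: identity transform
    return(structure(list(r = r, rBar = NULL, m = NULL, l = NULL,
                          rTilde = r, v = NULL, vTilde = NULL, rHat = r),
                     class = "DenseTransform"))
  }
  rBar <- apply(r, c(1L, 3L, 5L), mean)                   # I x P x T
  trialMean <- apply(r, c(1L, 2L, 3L, 5L), mean)          # I x C x P x T
  m <- sweep(trialMean, c(1L, 3L, 4L), rBar, "-")         # I x C x P x T
  norm <- sqrt(apply(m^2, c(2L, 3L, 4L), sum))            # C x P x T
  meanM <- apply(m, c(2L, 3L, 4L), mean)
  sgn <- ifelse(meanM >= 0, 1, -1)
  a <- switch(magnitude,
              l2sqrt = sgn * norm / sqrt(I),
              l2overI = sgn * norm / I)                   # C x P x T
  aFull <- aperm(array(a, dim = c(C, P, TT, I)), c(4L, 1L, 2L, 3L))
  l <- m - aFull
  lFull <- aperm(array(l, dim = c(I, C, P, TT, J)), c(1L, 2L, 3L, 5L, 4L))
  rTilde <- r - lFull
  varAcrossCtx <- function(x) {                            # x: I x C x P x T trial means
    apply(x^2, c(1L, 3L, 4L), mean) - apply(x, c(1L, 3L, 4L), mean)^2
  }
  v <- varAcrossCtx(trialMean)                             # I x P x T
  tmTilde <- apply(rTilde, c(1L, 2L, 3L, 5L), mean)
  vTilde <- varAcrossCtx(tmTilde)
  ## context component of the rotated responses (centered across contexts)
  ctx <- apply(rTilde, c(1L, 2L, 5L), mean)                # I x C x T
  ctxDev <- sweep(ctx, c(1L, 3L), apply(ctx, c(1L, 3L), mean), "-")
  ratio <- sweep(vTilde, c(2L, 3L), apply(v, c(2L, 3L), mean), function(vt, vm) {
    ifelse(vt > 1e-12, vm / vt, 1)
  })                                                      # I x P x T
  if (varianceRatio == "sqrt") ratio <- sqrt(ratio)
  ## rHat = rTilde + ctxDev * (ratio - 1), broadcast over (c, j)
  rHat <- rTilde
  for (p in seq_len(P)) {
    rp <- ratio[, p, , drop = FALSE]                      # I x 1 x T
    scale <- array(rp, dim = c(I, TT)) - 1                # I x T
    for (cc in seq_len(C)) {
      add <- ctxDev[, cc, ] * scale                       # I x T
      for (j in seq_len(J))
        rHat[, cc, p, j, ] <- rHat[, cc, p, j, ] + add
    }
  }
  ## The diagonal targets a_{c,p,t} need not sum to zero over contexts, so
  ## the rotation leaves a context-independent offset <a>_c on every probe
  ## mean; remove it so context-averaged probe responses are preserved
  ## exactly (the offset carries no context information).
  rBarHat <- apply(rHat, c(1L, 3L, 5L), mean)
  corr <- rBar - rBarHat                                  # I x P x T
  for (p in seq_len(P)) {
    cp <- matrix(corr[, p, ], I, TT)
    for (cc in seq_len(C)) for (j in seq_len(J))
      rHat[, cc, p, j, ] <- rHat[, cc, p, j, ] + cp
  }
  structure(list(r = r, rBar = rBar, m = m, l = l, mTarget = aFull,
                 rTilde = rTilde, v = v, vTilde = vTilde, rHat = rHat,
                 magnitude = magnitude, varianceRatio = varianceRatio),
            class = "DenseTransform")
}

#' Recompute context modulations from an instance tensor
#'
#' Helper for checking dense-code invariants: returns
#' \code{m[i, c, p, t] = <r - <r>_cj>_j}.
#'
#' @param r 5-D instance tensor.
#' @return 4-D array neurons x contexts x probes x bins.
#' @export
contextModulation <- function(r) {
  rBar <- apply(r, c(1L, 3L, 5L), mean)
  trialMean <- apply(r, c(1L, 2L, 3L, 5L), mean)
  sweep(trialMean, c(1L, 3L, 4L), rBar, "-")
}

#' Time-resolved linear decoding of context or probe identity
#'
#' Trains a separate linear support vector machine at every analysis time
#' bin to classify single-trial population vectors by preceding-context or
#' probe identity; features are standardized with training-fold statistics
#' and accuracy is stratified k-fold cross-validated.
#'
#' @param r 5-D instance tensor (neurons x contexts x probes x trials x
#'   bins), e.g. from \code{\link{segmentInstances}} or the \code{rHat} of
#'   \code{\link{densify}}.
#' @param labelKind \code{"context"} or \code{"probe"}.
#' @param nFolds folds (default 4).
#' @param cost SVM regularization (default 1).
#' @param seed fold-assignment seed.
#' @return data.frame: bin, accuracy, chance; attribute \code{"perFold"}
#'   holds the bins x folds accuracy matrix.
#' @export
decodeTimecourse <- function(r, labelKind = c("context", "probe"),
                             nFolds = 4L, cost = 1, seed = 1L) {
  labelKind <- match.arg(labelKind)
  d <- dim(r)
  I <- d[1]; C <- d[2]; P <- d[3]; J <- d[4]; TT <- d[5]
  ## flatten samples: every (c, p, j) combination
  grid <- expand.grid(c = seq_len(C), p = seq_len(P), j = seq_len(J),
                      KEEP.OUT.ATTRS = FALSE)
  y <- factor(if (labelKind == "context") grid$c else grid$p)
  if (nlevels(y) < 2L) stop("need >= 2 label classes")
  if (min(table(y)) < nFolds)
    stop("every class needs at least as many trials as folds")
  nS <- nrow(grid)
  folds <- withLocalSeed(seed, {
    f <- integer(nS)
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      f[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    f
  })
  acc <- matrix(NA_real_, TT, nFolds)
  for (tb in seq_len(TT)) {
    X <- matrix(0, nS, I)
    for (s in seq_len(nS))
      X[s, ] <- r[, grid$c[s], grid$p[s], grid$j[s], tb]
    for (fd in seq_len(nFolds)) {
      tr <- folds != fd
      mu <- colMeans(X[tr, , drop = FALSE])
      sd <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
      sd[sd == 0] <- 1
      Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
      fit <- e1071::svm(x = Xs[tr, , drop = FALSE], y = y[tr],
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, Xs[!tr, , drop = FALSE])
      acc[tb, fd] <- mean(pred == y[!tr])
    }
  }
  out <- data.frame(bin = seq_len(TT), accuracy = rowMeans(acc),
                    chance = 1 / nlevels(y))
  attr(out, "perFold") <- acc
  out
}
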