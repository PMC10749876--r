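#' Build the design matrix for one neuron's encoding model
#'
#' Predictors at the 100-Hz encoding-model resolution: the sound
#' spectrogram at lags 0-300 ms (18 channels x 30 10-ms lags), the neuron's
#' own windowed-average activity 150-300 ms in the past (one scalar), and
#' the windowed-average activity of every other simultaneously recorded
#' neuron over the same window (one scalar per neuron).  The four model
#' variants share this parameterization exactly; what differs is which
#' history sources are temporally scrambled (circular shift by an
#' independent random offset of 10-60 s per source): \code{STRF} scrambles
#' self and population, \code{Self} scrambles population only, \code{Pop}
#' scrambles self only, \code{Full} scrambles nothing.  Scrambling removes
#' the predictive value of a source while preserving parameter count.
#'
#' @param stim channels x time spectrogram matrix (100 Hz), time-aligned to
#'   \code{resp}.
#' @param resp neurons x time matrix of trial-averaged responses (100 Hz),
#'   peak-normalized per neuron.
#' @param target index of the modeled neuron.
#' @param variant one of \code{"STRF"}, \code{"Self"}, \code{"Pop"},
#'   \code{"Full"}.
#' @param blocks integer vector per time bin giving the stimulus-sequence
#'   id (used both as CV folds and to zero lagged predictors across block
#'   boundaries).
#' @param nLags STRF lags (default 30).
#' @param histWindow history lag window in bins (default 15:30, i.e.
#'   150-300 ms).
#' @param scrambleSeed seed for the scramble shifts.
#' @param minShiftS,maxShiftS scramble shift range in seconds; shifts are
#'   taken modulo the recording length, re-drawn if the effective shift is
#'   under 1 s.
#' @return list: \code{X} (time x predictors), \code{y} (target response),
#'   \code{groups} (list strf/self/pop of column indices), \code{blocks}.
#' @export
buildEncodingDesign <- function(stim, resp, target, variant = c("Full", "STRF", "Self", "Pop"),
                                blocks, nLags = 30L, histWindow = 15L:30L,
                                scrambleSeed = 1L, minShiftS = 10, maxShiftS = 60) {
  variant <- match.arg(variant)
  nCh <- nrow(stim); TT <- ncol(stim); I <- nrow(resp)
  stopifnot(ncol(resp) == TT, length(blocks) == TT)
  scrambleSelf <- variant %in% c("STRF", "Pop")
  scramblePop <- variant %in% c("STRF", "Self")

  shiftSeries <- function(x, shift) {
    s <- shift %% length(x)
    if (s == 0L) x else c(x[(s + 1L):length(x)], x[1L:s])
  }
  drawShift <- function() {
    for (k in 1:100) {
      s <- as.integer(round(stats::runif(1, minShiftS, maxShiftS) * 100)) %% TT
      if (s >= 100L && (TT - s) >= 100L) return(s)   # >= 1 s effective shift
    }
    max(1L, TT %/% 2L)
  }

  respUse <- resp
  withLocalSeed(scrambleSeed, {
    for (i in seq_len(I)) {
      doScr <- if (i == target) scrambleSelf else scramblePop
      s <- drawShift()   # always draw: keeps shift assignment variant-invariant
      if (doScr) respUse[i, ] <- shiftSeries(resp[i, ], s)
    }
  })

  ## lagged stimulus block, zeroed across block boundaries
  Xs <- matrix(0, TT, nCh * nLags)
  for (lag in 0:(nLags - 1L)) {
    idx <- seq_len(TT) - lag
    valid <- which(idx >= 1L)
    valid <- valid[blocks[idx[valid]] == blocks[valid]]
    cols <- lag * nCh + seq_len(nCh)
    Xs[valid, cols] <- t(stim[, idx[valid], drop = FALSE])
  }
  ## windowed-average history per source, zeroed across block boundaries
  histOf <- function(x) {
    out <- numeric(TT)
    for (t in seq_len(TT)) {
      w0 <- t - max(histWindow); w1 <- t - min(histWindow)
      if (w0 < 1L) next
      if (blocks[w0] != blocks[t]) next
      out[t] <- mean(x[w0:w1])
    }
    out
  }
  selfCol <- histOf(respUse[target, ])
  popIdx <- setdiff(seq_len(I), target)
  Xp <- vapply(popIdx, function(i) histOf(respUse[i, ]), numeric(TT))
  if (length(popIdx) == 1L) Xp <- matrix(Xp, ncol = 1L)
  if (length(popIdx) == 0L) Xp <- matrix(0, TT, 0L)
  X <- cbind(Xs, self = selfCol, Xp)
  groups <- list(strf = seq_len(ncol(Xs)),
                 self = ncol(Xs) + 1L,
                 pop = if (length(popIdx)) ncol(Xs) + 1L + seq_along(popIdx) else integer(0))
  attr(groups$pop, "sources") <- popIdx
  list(X = X, y = resp[target, ], groups = groups, blocks = blocks,
       variant = variant)
}

## full-batch ADAM on the rectified-linear MSE objective
.adamFit <- function(X, y, theta0, b0, lr = 1e-3, maxEpochs = 300L,
                     valFrac = 0.1, patience = 25L) {
  n <- nrow(X)
  nVal <- max(1L, floor(valFrac * n))
  valIdx <- unique(as.integer(round(seq(1L, n, length.out = nVal))))  # deterministic slice
  trIdx <- setdiff(seq_len(n), valIdx)
  Xt <- X[trIdx, , drop = FALSE]; yt <- y[trIdx]
  Xv <- X[valIdx, , drop = FALSE]; yv <- y[valIdx]
  th <- c(theta0, b0); p <- length(th)
  m <- v <- numeric(p)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lossOf <- function(Xm, ym, th) {
    pr <- pmax(Xm %*% th[-p] + th[p], 0)
    mean((pr - ym)^2)
  }
  best <- th; bestLoss <- lossOf(Xv, yv, th); wait <- 0L; converged <- FALSE
  ep <- 0L
  for (ep in seq_len(maxEpochs)) {
    z <- Xt %*% th[-p] + th[p]
    pr <- pmax(z, 0)
    g <- as.numeric(pr - yt) * (z > 0)
    grad <- c(as.numeric(crossprod(Xt, g)), sum(g)) * (2 / length(yt))
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    mh <- m / (1 - beta1^ep); vh <- v / (1 - beta2^ep)
    th <- th - lr * mh / (sqrt(vh) + eps)
    vl <- lossOf(Xv, yv, th)
    if (vl < bestLoss - 1e-10) { bestLoss <- vl; best <- th; wait <- 0L }
    else {
      wait <- wait + 1L
      if (wait >= patience) { converged <- TRUE; break }
    }
  }
  list(theta = best[-p], bias = best[p], converged = converged,
       valLoss = bestLoss, epochs = ep)
}

## ridge least-squares initialization of the linearized problem, refined by
## a few active-set passes: refit on the samples that are either above the
## rectifier threshold in the data or predicted to be, which solves the
## linear region of the ReLU objective directly.
.ridgeInit <- function(X, y, lambda = NULL, refine = 8L) {
  p <- ncol(X)
  if (is.null(lambda)) lambda <- 1e-5 * nrow(X)
  Xa <- cbind(X, 1)
  solveOn <- function(idx) {
    A <- crossprod(Xa[idx, , drop = FALSE]) + diag(lambda, p + 1L)
    tryCatch(as.numeric(solve(A, crossprod(Xa[idx, , drop = FALSE], y[idx]))),
             error = function(e) numeric(p + 1L))
  }
  th <- solveOn(seq_len(nrow(X)))
  for (it in seq_len(refine)) {
    z <- as.numeric(Xa %*% th)
    active <- y > 0 | z > 0
    if (sum(active) <= p + 1L) break
    thNew <- solveOn(which(active))
    if (max(abs(thNew - th)) < 1e-10) { th <- thNew; break }
    th <- thNew
  }
  list(theta = th[seq_len(p)], bias = th[p + 1L])
}

#' Fit a rectified-linear encoding model with sequence-wise cross-validation
#'
#' Minimizes the squared error of the rectified linear output
#' \code{relu(X w + b)} by ADAM gradient descent (ridge least-squares
#' initialization, early stopping on a 10\% in-fold validation slice).
#' One fold per stimulus sequence: each fold's model predicts its held-out
#' sequence, and overall performance is the Pearson correlation between the
#' concatenated held-out predictions and the response.
#'
#' @param design output of \code{\link{buildEncodingDesign}}.
#' @param lr ADAM learning rate (default 1e-3).
#' @param maxEpochs maximum epochs per fold (default 300).
#' @param patience early-stopping patience (epochs).
#' @return list of class \code{"EncodingModelFit"}: \code{predictionR},
#'   \code{prediction} (held-out, concatenated), \code{weights} /
#'   \code{bias} (full-data fit, for inspection and coupling summaries),
#'   \code{groups}, \code{variant}, \code{folds}, \code{converged}.
#' @export
fitEncodingModel <- function(design, lr = 1e-3, maxEpochs = 300L,
                             patience = 25L) {
  X <- design$X; y <- design$y; blocks <- design$blocks
  folds <- sort(unique(blocks))
  pred <- rep(NA_real_, length(y))
  conv <- logical(length(folds))
  for (k in seq_along(folds)) {
    tr <- blocks != folds[k]
    init <- .ridgeInit(X[tr, , drop = FALSE], y[tr])
    fit <- .adamFit(X[tr, , drop = FALSE], y[tr], init$theta, init$bias,
                    lr = lr, maxEpochs = maxEpochs, patience = patience)
    conv[k] <- fit$converged
    pred[!tr] <- pmax(X[!tr, , drop = FALSE] %*% fit$theta + fit$bias, 0)
  }
  r <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) 0 else stats::cor(pred, y)
  initF <- .ridgeInit(X, y)
  full <- .adamFit(X, y, initF$theta, initF$bias, lr = lr,
                   maxEpochs = maxEpochs, patience = patience)
  structure(list(predictionR = r, prediction = pred,
                 weights = full$theta, bias = full$bias,
                 groups = design$groups, variant = design$variant,
                 folds = folds, converged = all(conv)),
            class = "EncodingModelFit")
}

#' Assemble stimulus and response matrices for encoding models
#'
#' Concatenates, sequence by sequence, the 100-Hz sound spectrogram of each
#' sequence (from \code{\link{synthesizeSoundSpectrogram}}) and the
#' trial-averaged, peak-normalized population response.
#'
#' @param rec a \linkS4class{PopulationRecording} with a fine-resolution
#'   assay.
#' @param soundSeed seed passed to the spectrogram synthesizer.
#' @return list: \code{stim} (channels x time), \code{resp} (neurons x
#'   time), \code{blocks} (sequence id per bin), \code{peak} (per-neuron
#'   normalization factors).
#' @export
encodingData <- function(rec, soundSeed = 1L) {
  seqset <- sequenceSet(rec)
  fineDt <- metadata(rec)$fineDt
  fc <- fineCounts(rec)
  if (is.null(fc)) stop("recording has no fine-resolution assay")
  seqIdx <- trialData(rec)$sequence
  I <- dim(fc)[1]
  stimL <- list(); respL <- list(); blocks <- integer(0)
  for (sq in sort(unique(seqIdx))) {
    sounds <- seqset@sequences[[sq]]
    spec <- do.call(cbind, lapply(sounds, function(s)
      synthesizeSoundSpectrogram(s, dt = fineDt, seed = soundSeed)@values))
    avg <- apply(fc[, seqIdx == sq, , drop = FALSE], c(1L, 3L), mean)
    avg <- matrix(avg, nrow = I)
    stimL[[length(stimL) + 1L]] <- spec
    respL[[length(respL) + 1L]] <- avg
    blocks <- c(blocks, rep(sq, ncol(spec)))
  }
  stim <- do.call(cbind, stimL)
  resp <- do.call(cbind, respL)
  peak <- apply(resp, 1L, max)
  peak[peak == 0] <- 1
  resp <- resp / peak
  list(stim = stim, resp = resp, blocks = blocks, peak = peak)
}

#' Fit all four model variants for a set of neurons
#'
#' @param rec a \linkS4class{PopulationRecording}.
#' @param neurons neuron indices (default all).
#' @param variants subset of c("STRF", "Self", "Pop", "Full").
#' @param scrambleSeed,soundSeed seeds.
#' @param ... passed to \code{\link{fitEncodingModel}}.
#' @return list with \code{fits} (nested list fits[[neuron]][[variant]]) and
#'   \code{predictionR} (neurons x variants matrix).
#' @export
fitPopulationModels <- function(rec, neurons = NULL,
                                variants = c("STRF", "Self", "Pop", "Full"),
                                scrambleSeed = 1L, soundSeed = 1L, ...) {
  ed <- encodingData(rec, soundSeed = soundSeed)
  I <- nrow(ed$resp)
  if (is.null(neurons)) neurons <- seq_len(I)
  fits <- vector("list", length(neurons))
  names(fits) <- as.character(neurons)
  rmat <- matrix(NA_real_, length(neurons), length(variants),
                 dimnames = list(as.character(neurons), variants))
  for (k in seq_along(neurons)) {
    i <- neurons[k]
    fits[[k]] <- lapply(stats::setNames(variants, variants), function(vv) {
      des <- buildEncodingDesign(ed$stim, ed$resp, i, variant = vv,
                                 blocks = ed$blocks,
                                 scrambleSeed = scrambleSeed + i)
      fitEncodingModel(des, ...)
    })
    rmat[k, ] <- vapply(fits[[k]], function(f) f$predictionR, numeric(1))
  }
  structure(list(fits = fits, predictionR = rmat, data = ed),
            scrambleSeed = scrambleSeed)
}

#' Compare encoding-model variants
#'
#' Paired two-sided Wilcoxon signed-rank tests on the absolute
#' cross-validated prediction correlations of each pair of variants, with
#' Bonferroni correction over the pairs, plus each variant's mean
#' performance as a fraction of the Full model's.
#'
#' @param predictionR neurons x variants matrix.
#' @return list: \code{pairs} (data.frame model1, model2, p, pAdjusted),
#'   \code{fractionOfFull} (named numeric).
#' @export
compareModels <- function(predictionR) {
  v <- colnames(predictionR)
  if (nrow(predictionR) < 6L)
    warning("fewer than 6 neurons: paired p-values unreliable")
  cmb <- utils::combn(v, 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- abs(predictionR[, cmb[1L, k]]); b <- abs(predictionR[, cmb[2L, k]])
    p <- if (all(a == b)) 1 else
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
    data.frame(model1 = cmb[1L, k], model2 = cmb[2L, k], p = p)
  }))
  pairs$pAdjusted <- pmin(pairs$p * nrow(pairs), 1)
  frac <- if ("Full" %in% v) colMeans(abs(predictionR)) /
            mean(abs(predictionR[, "Full"])) else NULL
  list(pairs = pairs, fractionOfFull = frac)
}

#' Predicted versus actual context effects over probe-time intervals
#'
#' Uses a fitted model to predict every probe response under each of its
#' contexts (teacher forcing: the actual recorded self/population histories
#' enter the design), computes the absolute predicted context difference
#' per instance on 0-1 (min-max per neuron) normalized responses, does the
#' same for the actual responses, integrates |delta| over the four
#' non-overlapping 250-ms probe intervals, and correlates actual with
#' predicted amplitudes per interval across significant instances.
#'
#' @param models output of \code{\link{fitPopulationModels}}.
#' @param rec the recording the models were fit on.
#' @param effects effects table with \code{significant} flags (from the
#'   cluster-mass analysis of the same recording).
#' @param variant which variant's predictions to evaluate.
#' @param jackFolds jackknife folds for the per-interval correlation std.
#' @return list: \code{perInstance} (neuron, instance, interval, actual,
#'   predicted), \code{intervalR} (data.frame interval, r, jackknifeSd, n).
#' @export
predictContextEffects <- function(models, rec, effects, variant = "Full",
                                  jackFolds = 200L) {
  ed <- models$data
  seqset <- sequenceSet(rec)
  fineDt <- metadata(rec)$fineDt
  nb <- as.integer(round(1 / fineDt))
  ev <- sequenceEvents(seqset)
  neurons <- as.integer(names(models$fits))
  ## predicted + actual full traces, min-max normalized per neuron
  sig <- effects[effects$significant & effects$neuron %in% neurons, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(list(perInstance = data.frame(), intervalR = data.frame()))
  qnorm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(x * 0)
    (x - rng[1]) / diff(rng)
  }
  intervals <- list(i = 1:(nb %/% 4), ii = (nb %/% 4 + 1):(nb %/% 2),
                    iii = (nb %/% 2 + 1):(3 * nb %/% 4),
                    iv = (3 * nb %/% 4 + 1):nb)
  rows <- list()
  for (k in seq_along(neurons)) {
    i <- neurons[k]
    fit <- models$fits[[k]][[variant]]
    if (is.null(fit)) stop("variant not fitted: ", variant)
    des <- buildEncodingDesign(ed$stim, ed$resp, i, variant = variant,
                               blocks = ed$blocks,
                               scrambleSeed = attrScrambleSeed(models, i))
    predFull <- as.numeric(pmax(des$X %*% fit$weights + fit$bias, 0))
    actFull <- ed$resp[i, ]
    predN <- qnorm01(predFull); actN <- qnorm01(actFull)
    ## global bin offset of each sequence block
    runs <- rle(des$blocks)
    blockStart <- c(0, cumsum(runs$lengths))
    seqOffset <- function(sq) blockStart[which(runs$values == sq)]
    si <- sig[sig$neuron == i, , drop = FALSE]
    for (r in seq_len(nrow(si))) {
      p <- si$probe[r]
      getTrace <- function(ctx, x) {
        e <- ev[ev$context == ctx & ev$probe == p, ]
        off <- seqOffset(e$sequence[1L])
        x[(off + (e$position[1L] - 1L) * nb + 1L):(off + e$position[1L] * nb)]
      }
      dPred <- abs(getTrace(si$contextA[r], predN) - getTrace(si$contextB[r], predN))
      dAct <- abs(getTrace(si$contextA[r], actN) - getTrace(si$contextB[r], actN))
      for (nm in names(intervals)) {
        rows[[length(rows) + 1L]] <- data.frame(
          neuron = i, instance = si$instance[r], interval = nm,
          actual = sum(dAct[intervals[[nm]]]) * fineDt,
          predicted = sum(dPred[intervals[[nm]]]) * fineDt)
      }
    }
  }
  per <- do.call(rbind, rows)
  intervalR <- do.call(rbind, lapply(names(intervals), function(nm) {
    d <- per[per$interval == nm, , drop = FALSE]
    if (nrow(d) < 3L || stats::sd(d$actual) == 0 || stats::sd(d$predicted) == 0)
      return(data.frame(interval = nm, r = NA_real_, jackknifeSd = NA_real_,
                        n = nrow(d)))
    r <- stats::cor(d$actual, d$predicted)
    jk <- jackknifeCI(seq_len(nrow(d)),
                      statistic = function(idx) stats::cor(d$actual[idx], d$predicted[idx]),
                      nFolds = jackFolds)
    data.frame(interval = nm, r = r, jackknifeSd = jk$se, n = nrow(d))
  }))
  list(perInstance = per, intervalR = intervalR)
}

## scramble seed convention used by fitPopulationModels
attrScrambleSeed <- function(models, neuron) {
  ss <- attr(models, "scrambleSeed")
  if (is.null(ss)) ss <- 1L
  ss + neuron
}

#' Summarize fitted coupling weights by cell type
#'
#' For population-history models, averages the fitted neighbor weights by
#' the source neuron's class (outgoing connections) and by the target
#' neuron's class (incoming connections).
#'
#' @param models output of \code{\link{fitPopulationModels}}.
#' @param classes factor/character vector of cell classes per neuron (index
#'   = neuron id), e.g. from \code{\link{classifySpikeWidth}} plus an
#'   optotagged label.
#' @param variant which variant's weights to summarize (default "Full").
#' @return data.frame: class, meanIncoming, meanOutgoing, nIncoming,
#'   nOutgoing.
#' @export
summarizeCoupling <- function(models, classes, variant = "Full") {
  neurons <- as.integer(names(models$fits))
  rows <- list()
  for (k in seq_along(neurons)) {
    i <- neurons[k]
    fit <- models$fits[[k]][[variant]]
    srcs <- attr(fit$groups$pop, "sources")
    if (length(srcs) == 0L) next
    w <- fit$weights[fit$groups$pop]
    rows[[length(rows) + 1L]] <- data.frame(target = i, source = srcs, w = w)
  }
  if (length(rows) == 0L)
    return(data.frame(class = character(), meanIncoming = numeric(),
                      meanOutgoing = numeric(), nIncoming = integer(),
                      nOutgoing = integer()))
  tab <- do.call(rbind, rows)
  tab$srcClass <- as.character(classes[tab$source])
  tab$tgtClass <- as.character(classes[tab$target])
  cls <- sort(unique(c(tab$srcClass, tab$tgtClass)))
  out <- do.call(rbind, lapply(cls, function(cl) {
    inc <- tab$w[tab$tgtClass == cl]
    outg <- tab$w[tab$srcClass == cl]
    data.frame(class = cl,
               meanIncoming = if (length(inc)) mean(inc) else NA_real_,
               meanOutgoing = if (length(outg)) mean(outg) else NA_real_,
               nIncoming = length(inc), nOutgoing = length(outg))
  }))
  rownames(out) <- NULL
  out
}
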