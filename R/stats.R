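#' Assign similarity and identity categories to contextual instances
#'
#' Each context of an instance gets a similarity label relative to its probe
#' (\code{silence}, \code{same}, \code{different}) and, for non-silence
#' contexts, an identity label (\code{vocalization} /
#' \code{non-vocalization}) from the sound library.  Instances combining a
#' silence context with a vocalization context are flagged for optional
#' exclusion (their interaction confounds the marginal comparisons).
#'
#' @param instances data.frame with columns probe, contextA, contextB (as
#'   from \code{\link{enumerateInstances}} or an effects table).
#' @param library a \linkS4class{SoundLibrary}.
#' @return data.frame with one row per instance-context: instance, probe,
#'   context, similarity, identity (NA for silence), probeIsVocalization,
#'   excludeSilenceVocal.
#' @export
assignCategories <- function(instances, library) {
  ids <- library@soundIds
  voc <- library@isVocalization
  isVoc <- function(x) {
    out <- rep(NA, length(x))
    hit <- x != 0L
    if (any(!(x[hit] %in% ids))) stop("unknown sound id")
    out[hit] <- voc[match(x[hit], ids)]
    out
  }
  long <- rbind(
    data.frame(instance = instances$instance, probe = instances$probe,
               context = instances$contextA),
    data.frame(instance = instances$instance, probe = instances$probe,
               context = instances$contextB))
  long$similarity <- ifelse(long$context == 0L, "silence",
                     ifelse(long$context == long$probe, "same", "different"))
  vocCtx <- isVoc(long$context)
  long$identity <- ifelse(is.na(vocCtx), NA,
                   ifelse(vocCtx, "vocalization", "non-vocalization"))
  long$probeIsVocalization <- as.logical(isVoc(long$probe))
  ## flag instances pairing silence with a vocalization context
  bad <- unique(unlist(lapply(split(long, long$instance), function(d) {
    if (any(d$similarity == "silence") &&
        any(!is.na(d$identity) & d$identity == "vocalization")) d$instance[1L]
  })))
  long$excludeSilenceVocal <- long$instance %in% bad
  rownames(long) <- NULL
  long[order(long$instance), ]
}

#' Categorical regression of context-effect magnitude on context category
#'
#' Quantifies how effect amplitude (or duration) depends on context
#' similarity and identity.  The metric is normalized by its grand mean so
#' that coefficients read as percent change relative to the base category
#' (different / non-vocalization).  Every instance contributes one row per
#' context label (data repeated with multiple labels); silence-context rows
#' carry the base identity level, as silence has no identity of its own.
#' Fits ordinary least squares with the similarity x identity interaction.
#'
#' @param effects effects table (rows = neuron x instance) with the metric
#'   column and instance keys probe/contextA/contextB; typically restricted
#'   to significant instances beforehand.
#' @param labels output of \code{\link{assignCategories}}.
#' @param metric column to model (\code{"amplitudeZs"} or
#'   \code{"durationMs"}).
#' @param excludeSilenceVocal drop instances pairing silence and
#'   vocalization contexts (default FALSE; the full model keeps them and
#'   relies on the interaction term).
#' @param probeIdentity also include the probe-is-vocalization regressor.
#' @return list with \code{coefficients} (data.frame: term,
#'   percentChange, t, p), \code{fit} (the lm object), \code{nRows}.
#' @export
categoryRegression <- function(effects, labels, metric = "amplitudeZs",
                               excludeSilenceVocal = FALSE,
                               probeIdentity = FALSE) {
  key <- paste(labels$instance)
  df <- merge(effects, labels, by = "instance")
  if (excludeSilenceVocal) df <- df[!df$excludeSilenceVocal, , drop = FALSE]
  gm <- mean(effects[[metric]])
  if (!is.finite(gm) || gm == 0) stop("grand mean of metric is degenerate")
  df$y <- df[[metric]] / gm
  df$similarity <- factor(df$similarity,
                          levels = c("different", "silence", "same"))
  df$identity <- factor(ifelse(is.na(df$identity), "non-vocalization", df$identity),
                        levels = c("non-vocalization", "vocalization"))
  present <- levels(droplevels(df$similarity))
  if (length(present) < 2L && nlevels(droplevels(df$identity)) < 2L)
    stop("need >= 2 categories present")
  form <- if (probeIdentity) y ~ similarity * identity + probeIsVocalization
          else y ~ similarity * identity
  fit <- tryCatch(stats::lm(form, data = df), error = function(e) stop(e))
  sm <- summary(fit)$coefficients
  dropped <- setdiff(names(stats::coef(fit)), rownames(sm))
  if (length(dropped))
    warning("dropped collinear/absent terms: ", paste(dropped, collapse = ", "))
  co <- data.frame(term = rownames(sm),
                   percentChange = 100 * sm[, "Estimate"],
                   t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                   row.names = NULL)
  list(coefficients = co, fit = fit, nRows = nrow(df))
}

#' Kruskal-Wallis group comparison with Dunn post hoc tests
#'
#' Rank-based non-parametric comparison of a metric across groups (cortical
#' region, context similarity/identity, cortical layer, or cell type),
#' followed by pairwise Dunn z tests with tie correction and Bonferroni
#' adjustment.
#'
#' @param values numeric vector.
#' @param groups group labels (factor or character).
#' @return list with \code{kw} (htest from \code{kruskal.test}) and
#'   \code{dunn} (data.frame: group1, group2, z, p, pAdjusted).
#' @export
groupCompare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 values")
  kw <- stats::kruskal.test(values, groups)
  ## Dunn test: pairwise z on mean ranks with tie correction
  n <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (n - 1))
  meanRank <- tapply(rk, groups, mean)
  sizes <- table(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  dunn <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    se <- sqrt((n * (n + 1) / 12 - tieCorr) * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- (meanRank[[g1]] - meanRank[[g2]]) / se
    data.frame(group1 = g1, group2 = g2, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }))
  dunn$pAdjusted <- pmin(dunn$p * nrow(dunn), 1)
  rownames(dunn) <- NULL
  list(kw = kw, dunn = dunn)
}

#' Classify neurons by spike width
#'
#' Classifies neurons as narrow-spiking (putative inhibitory interneurons)
#' or broad-spiking (putative excitatory cells) from the spike peak-to-trough
#' delay (PTD).  The boundary is the valley minimum of a kernel density
#' estimate between the two dominant modes, with a safety band around it
#' left unclassified.
#'
#' @param ptd numeric vector of peak-to-trough delays (ms).
#' @param safety width of the unclassified band (ms, default 0.1, split
#'   symmetrically around the valley).
#' @param thresholds optional explicit \code{c(low, high)} thresholds (ms),
#'   bypassing the KDE (e.g. \code{c(0.37, 0.47)}).
#' @return list with \code{class} (factor narrow/unclassified/broad),
#'   \code{thresholds}, \code{valley} (NA when thresholds are given).
#' @export
classifySpikeWidth <- function(ptd, safety = 0.1, thresholds = NULL) {
  valley <- NA_real_
  if (is.null(thresholds)) {
    if (length(ptd) < 10L) stop("too few values for density estimation")
    de <- stats::density(ptd, bw = "nrd0")
    y <- de$y; x <- de$x
    ## local maxima of the KDE; minor shoulder wiggles are not modes
    pk <- which(diff(sign(diff(y))) == -2) + 1L
    pk <- pk[y[pk] > 0.1 * max(y)]
    if (length(pk) < 2L)
      stop("spike-width distribution is unimodal; classification refused")
    top2 <- pk[order(y[pk], decreasing = TRUE)][1:2]
    lo <- min(x[top2]); hi <- max(x[top2])
    mid <- x >= lo & x <= hi
    valley <- x[mid][which.min(y[mid])]
    ## a genuine valley must dip well below the smaller mode
    if (min(y[mid]) > 0.75 * min(y[top2]))
      stop("spike-width distribution is unimodal; classification refused")
    thresholds <- c(valley - safety / 2, valley + safety / 2)
  }
  if (thresholds[1] >= thresholds[2]) stop("low threshold must be < high")
  cls <- ifelse(ptd < thresholds[1], "narrow",
         ifelse(ptd > thresholds[2], "broad", "unclassified"))
  list(class = factor(cls, levels = c("narrow", "unclassified", "broad")),
       thresholds = thresholds, valley = valley)
}

#' Pupil modulation index
#'
#' \code{(large - small) / (|large| + |small|)}: 0 means no arousal effect;
#' positive values an increase under large pupil.  NA when the denominator
#' is zero.
#'
#' @param large,small the quantity under large/small pupil.
#' @return numeric in [-1, 1].
#' @examples
#' modulationIndex(2, 1)   # 1/3
#' modulationIndex(5, 5)   # 0
#' @export
modulationIndex <- function(large, small) {
  den <- abs(large) + abs(small)
  ifelse(den > 0, (large - small) / den, NA_real_)
}

#' Pupil median split and modulation indices
#'
#' For each contextual instance, trials are split at the median pupil size
#' over the interval containing both context and probe, and modulation
#' indices are computed for (a) the context-independent mean Z firing rate
#' per neuron-probe and (b) the mean deltaZ context effect of significant
#' instances, overall and in the four non-overlapping 250-ms intervals of
#' the probe window.  Non-responsive neuron-probes (mean Z < \code{minZ})
#' and small effects (mean |deltaZ| < \code{minDeltaZ}) are filtered; effect
#' signs are flipped positive before pooling.
#'
#' @param rec a \linkS4class{PopulationRecording} with a pupil trace.
#' @param effects effects table with a \code{significant} column.
#' @param minZ responsiveness filter (default 0.1).
#' @param minDeltaZ effect-size filter (default 0.3).
#' @return list with \code{rateMI} (neuron, probe, mi) and \code{effectMI}
#'   (neuron, instance, interval in overall/i/ii/iii/iv, mi).
#' @export
pupilSplitMI <- function(rec, effects, minZ = 0.1, minDeltaZ = 0.3) {
  pupil <- pupilTrace(rec)
  if (is.null(pupil)) stop("recording has no pupil trace")
  if (stats::sd(as.numeric(pupil)) == 0)
    stop("constant pupil: median split undefined")
  recz <- if ("zscore" %in% names(assays(rec))) rec else zscoreNormalize(rec)
  seg <- segmentInstances(recz, assayName = "zscore")
  N <- sequenceSet(rec)@nSounds
  nb <- dim(seg)[5]
  ev <- sequenceEvents(sequenceSet(rec))
  seqIdx <- trialData(rec)$sequence
  reps <- trialData(rec)$repetition
  ## per (context, probe, rep): pupil median over the context+probe window
  pupilCP <- array(NA_real_, dim = c(N + 1L, N, max(reps)))
  for (r in seq_len(nrow(ev))) {
    k <- ev$position[r]
    w0 <- max(1L, (k - 2L) * nb + 1L); w1 <- k * nb   # context + probe seconds
    for (tr in which(seqIdx == ev$sequence[r]))
      pupilCP[ev$context[r] + 1L, ev$probe[r], reps[tr]] <-
        stats::median(pupil[tr, w0:w1])
  }
  intervals <- list(overall = seq_len(nb),
                    i = 1:(nb %/% 4), ii = (nb %/% 4 + 1):(nb %/% 2),
                    iii = (nb %/% 2 + 1):(3 * nb %/% 4),
                    iv = (3 * nb %/% 4 + 1):nb)
  I <- dim(seg)[1]
  ## (a) context-independent firing-rate MI per neuron x probe
  rateRows <- list()
  for (i in seq_len(I)) for (p in seq_len(N)) {
    zbar <- mean(seg[i, , p, , ])
    if (is.na(zbar) || zbar < minZ) next
    pm <- as.numeric(pupilCP[, p, ])                 # per (context, rep)
    resp <- apply(seg[i, , p, , , drop = FALSE], c(2L, 4L), mean)  # C x reps
    largeSel <- pm >= stats::median(pm, na.rm = TRUE)
    lg <- mean(resp[largeSel], na.rm = TRUE)
    sm <- mean(resp[!largeSel], na.rm = TRUE)
    rateRows[[length(rateRows) + 1L]] <-
      data.frame(neuron = i, probe = p, mi = modulationIndex(lg, sm))
  }
  ## (b) context-effect MI per significant instance
  effRows <- list()
  sig <- effects[effects$significant, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    i <- sig$neuron[r]; p <- sig$probe[r]
    cA <- sig$contextA[r] + 1L; cB <- sig$contextB[r] + 1L
    pmA <- pupilCP[cA, p, ]; pmB <- pupilCP[cB, p, ]
    pm <- (pmA + pmB) / 2                            # instance interval median proxy
    largeSel <- pm >= stats::median(pm, na.rm = TRUE)
    dz <- seg[i, cA, p, , ] - seg[i, cB, p, , ]      # reps x bins
    if (mean(abs(rowMeans(dz))) < minDeltaZ) next
    flip <- sign(mean(dz)); if (flip == 0) flip <- 1
    dz <- dz * flip
    for (nm in names(intervals)) {
      lg <- mean(dz[largeSel, intervals[[nm]], drop = FALSE])
      smv <- mean(dz[!largeSel, intervals[[nm]], drop = FALSE])
      effRows[[length(effRows) + 1L]] <-
        data.frame(neuron = i, instance = sig$instance[r], interval = nm,
                   mi = modulationIndex(lg, smv))
    }
  }
  list(rateMI = if (length(rateRows)) do.call(rbind, rateRows) else
         data.frame(neuron = integer(), probe = integer(), mi = numeric()),
       effectMI = if (length(effRows)) do.call(rbind, effRows) else
         data.frame(neuron = integer(), instance = character(),
                    interval = character(), mi = numeric()))
}

#' Jackknife estimate and confidence interval
#'
#' Delete-one jackknife for n <= \code{nFolds}; otherwise values are
#' partitioned into \code{nFolds} seeded groups and a delete-d (grouped)
#' jackknife is used.  Returns the statistic, its jackknife standard error
#' and a normal-theory CI.
#'
#' @param values numeric vector (n >= 3).
#' @param statistic function of a numeric vector (default \code{mean}).
#' @param nFolds maximum folds (e.g. 100 or 200).
#' @param conf confidence level (default 0.95).
#' @param seed grouping seed.
#' @return list: estimate, se, ci (length 2), nFolds.
#' @export
jackknifeCI <- function(values, statistic = mean, nFolds = 100L,
                        conf = 0.95, seed = 1L) {
  n <- length(values)
  if (n < 3L) stop("need n >= 3")
  g <- min(nFolds, n)
  groups <- withLocalSeed(seed, sample(rep_len(seq_len(g), n)))
  est <- statistic(values)
  loo <- vapply(seq_len(g), function(k) statistic(values[groups != k]),
                numeric(1))
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = est, se = se, ci = c(est - zq * se, est + zq * se),
       nFolds = g)
}
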