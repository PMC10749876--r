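test_that("zscoreNormalize yields zero-mean unit-sd traces and drops flat neurons", {
  rec <- siteRec()
  recz <- zscoreNormalize(rec)
  z <- SummarizedExperiment::assays(recz)[["zscore"]]
  for (i in seq_len(dim(z)[1])) {
    expect_lt(abs(mean(z[i, , ])), 1e-9)
    expect_lt(abs(stats::sd(z[i, , ]) - 1), 1e-9)
  }
  ## affine-transformed copy of a neuron normalizes identically
  cnt <- spikeCounts(rec)
  cnt2 <- cnt
  cnt2[2, , ] <- 3 * cnt[1, , ] + 5
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt2), rowData = SummarizedExperiment::rowData(rec),
    colData = SummarizedExperiment::colData(rec))
  S4Vectors::metadata(se) <- S4Vectors::metadata(rec)
  rec2 <- new("PopulationRecording", se)
  z2 <- SummarizedExperiment::assays(zscoreNormalize(rec2))[["zscore"]]
  expect_equal(z2[2, , ], z2[1, , ], tolerance = 1e-9)

  ## constant-rate neuron is excluded with a message
  cnt3 <- cnt
  cnt3[3, , ] <- 2
  se3 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt3), rowData = SummarizedExperiment::rowData(rec),
    colData = SummarizedExperiment::colData(rec))
  S4Vectors::metadata(se3) <- S4Vectors::metadata(rec)
  expect_message(recz3 <- zscoreNormalize(new("PopulationRecording", se3)),
                 "zero-variance")
  expect_equal(dim(recz3)[1], dim(rec)[1] - 1L)
})

test_that("reliability filter keeps reproducible neurons and is vacuous at threshold -1", {
  rec <- noiseFreeRec()                          # deterministic: r = 1 everywhere
  keep <- reliabilityFilter(rec, threshold = 0.1, seed = 4)
  expect_equal(sort(keep), seq_len(dim(rec)[1]))
  expect_true(all(attr(keep, "reliability") > 0.99))

  recP <- siteRec()
  keepAll <- reliabilityFilter(recP, threshold = -1, seed = 4)
  expect_equal(sort(keepAll), seq_len(dim(recP)[1]))

  ## pure-noise neuron: reliability near zero, dropped at the 0.1 threshold
  cnt <- spikeCounts(recP)
  set.seed(1)
  cnt[1, , ] <- rpois(length(cnt[1, , ]), 0.5)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt), colData = SummarizedExperiment::colData(recP))
  S4Vectors::metadata(se) <- S4Vectors::metadata(recP)
  r <- attr(reliabilityFilter(new("PopulationRecording", se), seed = 4), "reliability")
  expect_lt(abs(r[1]), 0.15)
})

test_that("cluster-mass test: null identity, detection, and label symmetry", {
  set.seed(10)
  x <- matrix(rnorm(20 * 20), 20, 20)
  pr <- clusterMassTest(x, x, nShuffles = 200, seed = 1)
  expect_equal(nrow(pr@clusters), 0L)
  expect_false(any(pr@sigMask))
  expect_equal(pr@delta, rep(0, 20))

  ## injected deltaZ = 2 over bins 1-6, sd 0.3: detection is essentially sure
  a <- matrix(rnorm(20 * 20, sd = 0.3), 20, 20)
  b <- matrix(rnorm(20 * 20, sd = 0.3), 20, 20)
  a[, 1:6] <- a[, 1:6] + 2
  prA <- clusterMassTest(a, b, nShuffles = 500, seed = 2)
  expect_true(all(prA@sigMask[1:6]))
  expect_true(any(prA@clusters$p < 0.05))

  ## swapping conditions flips the sign, preserves |masses| exactly and
  ## p values up to permutation Monte-Carlo error
  prB <- clusterMassTest(b, a, nShuffles = 500, seed = 2)
  expect_equal(prB@delta, -prA@delta)
  expect_equal(prB@tscore, -prA@tscore)
  expect_equal(abs(prB@clusters$mass), abs(prA@clusters$mass))
  expect_true(all(abs(prB@clusters$p - prA@clusters$p) < 0.06))
  expect_equal(prB@sigMask, prA@sigMask)
})

test_that("effect metrics implement the integral-amplitude / last-bin-duration rule", {
  mk <- function(delta, sig) new("EffectProfile", delta = delta,
                                 tscore = delta, sigMask = sig,
                                 clusters = data.frame(start = 1L, end = 1L,
                                                       mass = 1, p = 0.01),
                                 binDt = 0.05)
  ## |dZ| = 1 on all 20 significant bins -> 1.0 Z*s, 1000 ms
  m1 <- effectMetrics(mk(rep(1, 20), rep(TRUE, 20)))
  expect_equal(m1$amplitude, 1.0)
  expect_equal(m1$duration, 1000)
  ## |dZ| = 0.8 on significant bins 4..12 (1-based) -> 0.36 Z*s, 600 ms
  sig <- rep(FALSE, 20); sig[4:12] <- TRUE
  m2 <- effectMetrics(mk(rep(0.8, 20), sig))
  expect_equal(m2$amplitude, 0.8 * 9 * 0.05)
  expect_equal(m2$duration, 600)
  ## empty mask -> all zero, not significant
  m3 <- effectMetrics(new("EffectProfile", delta = rep(1, 20), tscore = rep(0, 20),
                          sigMask = rep(FALSE, 20),
                          clusters = data.frame(start = integer(), end = integer(),
                                                mass = numeric(), p = numeric()),
                          binDt = 0.05))
  expect_equal(m3$amplitude, 0)
  expect_equal(m3$duration, 0)
  expect_false(m3$significant)
})

test_that("Bonferroni instance correction uses the family / instance / neuron factors", {
  eff <- data.frame(minClusterP = c(0.001, 0.0002, 0.04))
  c40 <- correctInstances(eff, nInstances = 40)
  expect_equal(attr(c40, "threshold"), 0.05 / 40)
  expect_true(c40$significant[1])               # 0.001 < 0.00125
  c550 <- correctInstances(eff, nInstances = 550)
  expect_equal(attr(c550, "threshold"), 0.05 / 550)
  expect_false(c550$significant[2])             # 0.0002 > 9.09e-5
  c1 <- correctInstances(eff, nInstances = 1)
  expect_true(all(c1$significant == (eff$minClusterP < 0.05)))
  cN <- correctInstances(eff, nInstances = 40, nExtraComparisons = 10)
  expect_equal(attr(cN, "threshold"), 0.05 / 400)
})

test_that("cluster test is calibrated on null data", {
  ## 200 null instances at 300 shuffles: any-cluster rate compatible with 5%
  set.seed(3)
  hits <- vapply(seq_len(200), function(k) {
    pr <- clusterMassTest(matrix(rnorm(400), 20), matrix(rnorm(400), 20),
                          nShuffles = 300, seed = k)
    nrow(pr@clusters) > 0 && min(pr@clusters$p) < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.10)
})

test_that("amplitude-duration association test randomizes duration only", {
  rec <- strongPoissonRec()
  eff <- strongPoissonEffectsProfiles()
  res <- amplitudeDurationAssociation(eff, nShuffles = 300, seed = 6)
  expect_false(res$degenerate)
  expect_true(res$r > 0)                        # shared-bins construction
  expect_true(res$p > 0 && res$p <= 1)
  ## null correlations exist and differ from the observed
  expect_gt(length(res$null), 250)
  ## profile amplitudes are bin-order invariant by definition of the metric
  profs <- attr(eff, "profiles")
  k <- which(eff$significant)[1]
  pr <- profs[[k]]
  perm <- sample(length(pr@delta))
  ampPerm <- sum(abs(pr@delta[perm][pr@sigMask[perm]])) * pr@binDt
  amp <- sum(abs(pr@delta[pr@sigMask])) * pr@binDt
  expect_equal(ampPerm, amp)
})

test_that("association test detects duration-proportional amplitudes", {
  ## instances where deltaZ = 1 over the first D bins: amplitude and
  ## duration are both proportional to D, so r is near 1 and the
  ## bin-shuffle null (which randomizes duration only) rejects
  set.seed(20)
  rows <- list(); profs <- list()
  for (k in seq_len(30)) {
    D <- sample(2:16, 1)
    a <- matrix(rnorm(20 * 20, sd = 0.3), 20, 20)
    b <- matrix(rnorm(20 * 20, sd = 0.3), 20, 20)
    a[, 1:D] <- a[, 1:D] + 1.2
    pr <- clusterMassTest(a, b, nShuffles = 300, seed = 100 + k)
    met <- effectMetrics(pr)
    rows[[k]] <- data.frame(amplitudeZs = met$amplitude,
                            durationMs = met$duration,
                            minClusterP = met$minClusterP,
                            significant = met$significant)
    profs[[k]] <- pr
  }
  eff <- do.call(rbind, rows)
  res <- amplitudeDurationAssociation(eff, profileList = profs,
                                      nShuffles = 500, seed = 3)
  expect_gt(res$r, 0.8)
  expect_lt(res$p, 0.05)
})

test_that("degenerate association inputs are flagged", {
  mkProf <- function(sigbin) {
    sig <- rep(FALSE, 20); sig[sigbin] <- TRUE
    new("EffectProfile", delta = as.numeric(sig), tscore = as.numeric(sig),
        sigMask = sig, clusters = data.frame(start = sigbin, end = sigbin,
                                             mass = 5, p = 0.001),
        binDt = 0.05)
  }
  eff <- data.frame(amplitudeZs = c(0.05, 0.05, 0.05),
                    durationMs = c(100, 100, 100),
                    significant = TRUE)
  profs <- list(mkProf(2), mkProf(2), mkProf(2))
  res <- amplitudeDurationAssociation(eff, profileList = profs,
                                      nShuffles = 50, seed = 1)
  expect_true(res$degenerate || is.na(res$r))
})
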