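test_that("coverage arithmetic matches counts of significant instances", {
  eff <- data.frame(neuron = rep(1:3, each = 40),
                    instance = rep(sprintf("i%02d", 1:40), 3),
                    amplitudeZs = 0.5, durationMs = 100,
                    minClusterP = 1, significant = FALSE)
  eff$significant[eff$neuron == 2][1:29] <- TRUE
  eff$significant[eff$neuron == 3][1:40] <- TRUE
  cov <- neuronCoverage(eff, 40)
  expect_equal(cov$coveragePct, c(0, 72.5, 100))
})

test_that("site union takes the max significant amplitude per instance", {
  ## hand-built: two neurons significant on disjoint instance sets (3 and 4)
  inst <- sprintf("i%02d", 1:10)
  eff <- data.frame(neuron = rep(1:2, each = 10), instance = rep(inst, 2),
                    amplitudeZs = 0, durationMs = 0, minClusterP = 1)
  eff$minClusterP[eff$neuron == 1][1:3] <- 1e-6
  eff$amplitudeZs[eff$neuron == 1][1:3] <- 0.3
  eff$minClusterP[eff$neuron == 2][4:7] <- 1e-6
  eff$amplitudeZs[eff$neuron == 2][4:7] <- 0.4
  un <- siteUnion(eff, 10)
  expect_equal(sum(un$perInstance$nSignificantNeurons > 0), 7L)
  expect_equal(un$coveragePct, 70)

  ## overlap: the larger amplitude wins
  eff$minClusterP[eff$neuron == 1][4] <- 1e-6
  eff$amplitudeZs[eff$neuron == 1][4] <- 0.5
  un2 <- siteUnion(eff, 10)
  expect_equal(un2$perInstance$unionAmplitudeZs[un2$perInstance$instance == "i04"], 0.5)

  ## a single-neuron site reduces to that neuron
  e1 <- eff[eff$neuron == 1, ]
  u1 <- siteUnion(e1, 10)
  expect_equal(100 * sum(correctInstances(e1, 10)$significant) / 10, u1$coveragePct)
  expect_error(siteUnion(eff[0, ], 10), "empty site")
})

test_that("best neuron maximizes coverage with amplitude then id tie-breaks", {
  eff <- data.frame(neuron = rep(1:3, each = 4),
                    instance = rep(letters[1:4], 3),
                    amplitudeZs = rep(c(0.2, 0.9, 0.2), each = 4),
                    durationMs = 100, minClusterP = 1,
                    significant = c(TRUE, TRUE, FALSE, FALSE,
                                    TRUE, TRUE, FALSE, FALSE,
                                    TRUE, FALSE, FALSE, FALSE))
  bn <- bestNeuron(eff)                         # tie 1 vs 2 on count; 2 has more amplitude
  expect_equal(as.integer(bn), 2L)
  effZero <- transform(eff, significant = FALSE)
  bz <- bestNeuron(effZero)
  expect_true(attr(bz, "allZero"))
})

test_that("dense-code transform satisfies its conservation laws", {
  seg <- siteSeg()
  dtf <- densify(seg)
  ## (a) recomputed context modulations identical across neurons
  mh <- contextModulation(dtf$rHat)
  expect_lt(max(apply(mh, c(2, 3, 4), stats::sd)), 1e-9)
  ## (b) imposed modulation targets preserve each population L2 norm
  n0 <- sqrt(apply(dtf$m^2, c(2, 3, 4), sum))
  nT <- sqrt(apply(dtf$mTarget^2, c(2, 3, 4), sum))
  expect_lt(max(abs(nT - n0) / pmax(n0, 1e-12)), 1e-6)
  ## (c) context-averaged probe responses preserved exactly
  rb0 <- apply(seg, c(1, 3, 5), mean)
  rb1 <- apply(dtf$rHat, c(1, 3, 5), mean)
  expect_lt(max(abs(rb1 - rb0)), 1e-9)
  ## single-trial deviations around the trial mean are untouched
  dev0 <- sweep(seg, c(1, 2, 3, 5), apply(seg, c(1, 2, 3, 5), mean), "-")
  dev1 <- sweep(dtf$rHat, c(1, 2, 3, 5), apply(dtf$rHat, c(1, 2, 3, 5), mean), "-")
  expect_equal(dev1, dev0, tolerance = 1e-9)
})

test_that("densify handles degenerate and toy geometries", {
  seg <- siteSeg()
  ## one neuron: the diagonal is the whole space, transform is identity
  one <- seg[1, , , , , drop = FALSE]
  d1 <- densify(one)
  expect_equal(d1$rHat, one, tolerance = 1e-9)
  ## single context: identity by definition
  sc <- seg[, 1, , , , drop = FALSE]
  expect_equal(densify(sc)$rHat, sc)
  ## 3-neuron toy: modulation vector (3, 0, 0) maps to sqrt(3) per component
  r <- array(0, dim = c(3, 2, 1, 2, 1))
  r[1, 1, 1, , 1] <- 3; r[1, 2, 1, , 1] <- -3   # m for ctx1 = (3,0,0)
  dt3 <- densify(r)
  expect_equal(dt3$mTarget[, 1, 1, 1], rep(sqrt(3), 3), tolerance = 1e-12)
  expect_equal(sqrt(sum(dt3$mTarget[, 1, 1, 1]^2)), 3)
})

test_that("per-bin SVM decoding separates structured labels and sits at chance otherwise", {
  set.seed(8)
  I <- 6; C <- 3; P <- 2; J <- 12; TT <- 3
  mu <- array(rnorm(I * C, sd = 4), dim = c(I, C))      # context-separated means
  r <- array(rnorm(I * C * P * J * TT, sd = 0.5), dim = c(I, C, P, J, TT))
  for (cc in seq_len(C)) r[, cc, , , ] <- r[, cc, , , ] + mu[, cc]
  dc <- decodeTimecourse(r, "context", seed = 2)
  expect_true(all(dc$accuracy >= 0.95))
  expect_equal(dc$chance[1], 1 / 3)
  ## no probe structure: probe decoding at chance (3 SE of binomial)
  dp <- decodeTimecourse(r, "probe", seed = 2)
  nSamp <- C * P * J
  se3 <- 3 * sqrt(0.5 * 0.5 / nSamp)
  expect_true(all(abs(dp$accuracy - 0.5) <= se3 + 0.1))
  expect_error(decodeTimecourse(r[, , , 1, , drop = FALSE], "context"),
               "folds")
})

test_that("PC1 of a dominant-neuron site mirrors that neuron's coverage", {
  rec <- siteRec()
  cnt <- spikeCounts(rec)
  ## amplify neuron 2 so it dominates the population variance
  cnt[2, , ] <- cnt[2, , ] * 6
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt), rowData = SummarizedExperiment::rowData(rec),
    colData = SummarizedExperiment::colData(rec))
  S4Vectors::metadata(se) <- S4Vectors::metadata(rec)
  recD <- new("PopulationRecording", se)
  pc <- pc1Coverage(recD, nShuffles = 1000, seed = 3)
  effN <- quantifyContextEffects(recD, nShuffles = 1000, seed = 3, neurons = 2)
  ## PC1 detects a similar instance set as the dominant neuron
  both <- merge(pc, effN, by = "instance")
  agree <- mean(both$significant.x == both$significant.y)
  expect_gt(agree, 0.8)
})
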