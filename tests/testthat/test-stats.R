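test_that("category assignment follows the similarity/identity rules", {
  lib <- soundLibrary(4, isVocalization = c(TRUE, FALSE, FALSE, FALSE))
  labs <- assignCategories(enumerateInstances(4), lib)
  ## every instance contributes exactly two labeled rows
  expect_equal(nrow(labs), 2L * 40L)
  ## silence context
  sil <- labs[labs$context == 0L, ]
  expect_true(all(sil$similarity == "silence"))
  expect_true(all(is.na(sil$identity)))
  ## same vs different, vocalization flags
  same <- labs[labs$context == labs$probe & labs$context != 0L, ]
  expect_true(all(same$similarity == "same"))
  expect_true(all(labs$identity[labs$context == 1L] == "vocalization", na.rm = TRUE))
  expect_true(all(labs$identity[labs$context %in% 2:4] == "non-vocalization", na.rm = TRUE))
  ## instances pairing silence and a vocalization context are flagged
  flagged <- unique(labs$instance[labs$excludeSilenceVocal])
  expect_true(all(grepl("^0:1->", flagged)))
  expect_error(assignCategories(data.frame(instance = "x", probe = 1,
                                           contextA = 0, contextB = 9), lib),
               "unknown sound id")
})

test_that("category regression recovers injected percent effects", {
  lib <- soundLibrary(6, isVocalization = c(TRUE, TRUE, rep(FALSE, 4)))
  inst <- enumerateInstances(6)
  labs <- assignCategories(inst, lib)
  ## synthetic metric: base 1, +10% for vocalization contexts, per instance
  set.seed(4)
  vocal <- tapply(!is.na(labs$identity) & labs$identity == "vocalization",
                  labs$instance, any)
  eff <- do.call(rbind, lapply(1:6, function(rep)
    data.frame(instance = names(vocal),
               amplitudeZs = (1 + 0.10 * vocal) * exp(rnorm(length(vocal), 0, 0.05)))))
  eff <- merge(eff, inst, by = "instance")
  ## the silence x vocalization interaction cell is structurally empty
  expect_warning(
    fitV <- categoryRegression(eff, labs, metric = "amplitudeZs",
                               excludeSilenceVocal = TRUE),
    "collinear")
  co <- fitV$coefficients
  voc <- co[co$term == "identityvocalization", ]
  expect_gt(voc$percentChange, 5)
  expect_lt(voc$percentChange, 15)
  expect_lt(voc$p, 0.001)
  ## null data: all category terms within noise of zero
  effNull <- eff
  set.seed(5)
  effNull$amplitudeZs <- exp(rnorm(nrow(effNull), 0, 0.05))
  expect_warning(fitN <- categoryRegression(effNull, labs), "collinear")
  coN <- fitN$coefficients
  terms <- coN[coN$term != "(Intercept)", ]
  expect_true(all(terms$p > 0.001))
  expect_true(all(abs(terms$percentChange) < 5))
  ## row bookkeeping: two labeled rows per instance row
  expect_equal(fitN$nRows, 2L * nrow(effNull))
})

test_that("Kruskal-Wallis + Dunn behave on identical, shifted and two-group data", {
  v <- rnorm(30)
  gc <- groupCompare(c(v, v, v), rep(c("a", "b", "c"), each = 30))
  expect_gt(gc$kw$p.value, 0.99)
  expect_true(all(abs(gc$dunn$z) < 1e-9))

  set.seed(6)
  x <- c(rnorm(200), rnorm(200, 2))              # 2 pooled-SD shift
  gs <- groupCompare(x, rep(c("a", "b"), each = 200))
  expect_lt(gs$kw$p.value, 1e-10)
  expect_true(all(gs$dunn$pAdjusted < 0.001))

  ## two groups: Dunn z^2 equals the KW chi-square statistic
  expect_equal(gs$dunn$z[1]^2, unname(gs$kw$statistic), tolerance = 1e-9)
  expect_error(groupCompare(1:5, rep("a", 5)), "groups")
})

test_that("spike-width classification finds the density valley between modes", {
  set.seed(7)
  ptd <- c(rnorm(200, 0.25, 0.04), rnorm(400, 0.70, 0.08))
  truth <- rep(c("narrow", "broad"), c(200, 400))
  res <- classifySpikeWidth(ptd)
  expect_gt(res$valley, 0.35)
  expect_lt(res$valley, 0.55)
  out <- res$class != "unclassified"
  expect_gt(mean(res$class[out] == truth[out]), 0.95)
  ## manual thresholds reproduce the fixed banding rule
  man <- classifySpikeWidth(ptd, thresholds = c(0.37, 0.47))
  expect_true(all(man$class[ptd < 0.37] == "narrow"))
  expect_true(all(man$class[ptd > 0.47] == "broad"))
  expect_true(all(man$class[ptd >= 0.37 & ptd <= 0.47] == "unclassified"))
  ## unimodal input is refused
  expect_error(classifySpikeWidth(rnorm(300, 0.5, 0.05)), "unimodal")
})

test_that("modulation index formula and symmetries", {
  expect_equal(modulationIndex(2, 1), 1 / 3)
  expect_equal(modulationIndex(5, 5), 0)
  expect_true(is.na(modulationIndex(0, 0)))
  x <- runif(20); y <- runif(20)
  expect_equal(modulationIndex(x, y), -modulationIndex(y, x))
  expect_equal(modulationIndex(3 * x, 3 * y), modulationIndex(x, y))
  expect_true(all(abs(modulationIndex(x, y)) <= 1))
})

test_that("pupil MI is centered near zero without arousal coupling", {
  rec <- strongPoissonRec()                       # pupilGainSd = 0
  eff <- strongPoissonEffects()
  ps <- pupilSplitMI(rec, eff)
  expect_gt(nrow(ps$effectMI), 20)
  overall <- ps$effectMI$mi[ps$effectMI$interval == "overall"]
  expect_lt(abs(mean(overall, na.rm = TRUE)), 0.1)
  expect_true(all(abs(ps$effectMI$mi) <= 1, na.rm = TRUE))
})

test_that("jackknife SE matches closed forms and handles grouping", {
  expect_equal(jackknifeCI(rep(2, 50), mean, nFolds = 100)$se, 0)
  ## mean of gaussians: jackknife SE approximates sigma/sqrt(n)
  set.seed(8)
  ratio <- replicate(20, {
    x <- rnorm(200)
    jackknifeCI(x, mean, nFolds = 200)$se / (1 / sqrt(200))
  })
  expect_lt(abs(mean(ratio) - 1), 0.10)
  ## grouped delete-d when n > folds, median statistic on skewed data
  x <- rexp(5000)
  jk <- jackknifeCI(x, stats::median, nFolds = 100, seed = 2)
  expect_equal(jk$nFolds, 100L)
  expect_true(is.finite(jk$se) && jk$se > 0)
  expect_true(jk$ci[1] < jk$estimate && jk$estimate < jk$ci[2])
  expect_error(jackknifeCI(1:2, mean), "n >= 3")
})
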