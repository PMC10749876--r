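#' Configuration for an end-to-end analysis run
#'
#' @param outDir output directory.
#' @param sim a \code{\link{simConfig}} defining the simulated experiment.
#' @param nShuffles cluster-test permutations.
#' @param familyAlpha family-wise alpha for instance correction.
#' @param decode run the decoding / dense-code stage.
#' @param encode run the encoding-model stage (slowest stage).
#' @param encodeNeurons neuron subset for the encoding stage (default all).
#' @param seed master seed for the analysis stages.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(outDir, sim = simConfig(), nShuffles = 1000L,
                      familyAlpha = 0.05, decode = TRUE, encode = FALSE,
                      encodeNeurons = NULL, seed = 1L) {
  structure(list(outDir = outDir, sim = sim, nShuffles = as.integer(nShuffles),
                 familyAlpha = familyAlpha, decode = decode, encode = encode,
                 encodeNeurons = encodeNeurons, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- sequence design and
#' simulation, context-effect quantification, coverage / site-union / best
#' neuron / PC1, optionally the dense-code transform with context and probe
#' decoding, optionally the encoding models -- and writes tidy CSV outputs
#' plus a JSON manifest (config echo, per-stage row counts, file checksums)
#' to the output directory.  Numeric CSV columns are rounded to 6
#' significant digits so that identical configs give byte-identical
#' outputs.
#'
#' @param config a \code{\link{runConfig}}.
#' @return the output directory, invisibly; the manifest as attribute
#'   \code{"manifest"}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$outDir, f)
  stages <- list()

  rec <- simulatePopulation(config$sim)
  seqset <- sequenceSet(rec)
  writeSequenceSet(seqset, outfile("sequences.json"))
  stages$design <- list(nSequences = seqset@nSounds)

  eff <- quantifyContextEffects(rec, nShuffles = config$nShuffles,
                                familyAlpha = config$familyAlpha,
                                seed = config$seed)
  utils::write.csv(.roundCols(eff), outfile("effects.csv"), row.names = FALSE)
  stages$quantify <- list(rows = nrow(eff), significant = sum(eff$significant))

  nInst <- nrow(enumerateInstances(seqset@nSounds))
  cov <- neuronCoverage(eff, nInst)
  un <- siteUnion(eff, nInst, config$familyAlpha)
  bn <- bestNeuron(eff)
  pc <- pc1Coverage(rec, nShuffles = config$nShuffles, seed = config$seed + 1L)
  covTable <- rbind(
    data.frame(entity = paste0("neuron", cov$neuron), coveragePct = cov$coveragePct),
    data.frame(entity = "union", coveragePct = un$coveragePct),
    data.frame(entity = "bestNeuron",
               coveragePct = cov$coveragePct[cov$neuron == as.integer(bn)]),
    data.frame(entity = "PC1", coveragePct = 100 * sum(pc$significant) / nInst))
  utils::write.csv(.roundCols(covTable), outfile("coverage.csv"), row.names = FALSE)
  stages$popcode <- list(rows = nrow(covTable))

  if (config$decode) {
    recz <- zscoreNormalize(rec)
    seg <- segmentInstances(recz, assayName = "zscore")
    dt <- densify(seg)
    res <- list()
    for (lk in c("context", "probe")) {
      for (ds in c("original", "dense")) {
        arr <- if (ds == "original") seg else dt$rHat
        dc <- decodeTimecourse(arr, lk, seed = config$seed + 2L)
        dc$labels <- lk; dc$data <- ds
        res[[paste(lk, ds)]] <- dc
      }
    }
    dec <- do.call(rbind, res)
    utils::write.csv(.roundCols(dec), outfile("decoding.csv"), row.names = FALSE)
    stages$decode <- list(rows = nrow(dec))
  }

  if (config$encode) {
    models <- fitPopulationModels(rec, neurons = config$encodeNeurons,
                                  scrambleSeed = config$seed + 3L)
    utils::write.csv(.roundCols(as.data.frame(models$predictionR)),
                     outfile("model_performance.csv"), row.names = FALSE)
    cmpt <- compareModels(models$predictionR)
    utils::write.csv(.roundCols(cmpt$pairs), outfile("model_comparison.csv"),
                     row.names = FALSE)
    pce <- predictContextEffects(models, rec, eff)
    if (nrow(pce$intervalR))
      utils::write.csv(.roundCols(pce$intervalR), outfile("context_prediction.csv"),
                       row.names = FALSE)
    stages$encode <- list(neurons = nrow(models$predictionR))
  }

  files <- list.files(config$outDir, pattern = "\\.(csv|json)$")
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = as.character(utils::packageVersion("ctxcode")),
    seed = config$seed,
    simSeed = config$sim$seed,
    stages = stages,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(outfile(f)))))
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out <- config$outDir
  attr(out, "manifest") <- manifest
  invisible(out)
}

#' Summarize a completed pipeline run
#'
#' Reads the CSV outputs of \code{\link{runPipeline}} and assembles summary
#' tables: the coverage distribution and ordering (union / best neuron /
#' mean single neuron), amplitude and duration summaries, decoding
#' accuracy by label kind and data set, and encoding-model performance if
#' present.
#'
#' @param runDir directory written by \code{\link{runPipeline}}.
#' @return list of data.frames; \code{notes} collects degenerate-case
#'   messages (e.g. no significant instances).
#' @export
runReport <- function(runDir) {
  rd <- function(f) {
    p <- file.path(runDir, f)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  eff <- rd("effects.csv")
  if (is.null(eff)) stop("dependency error: effects.csv missing (stage quantify)")
  notes <- character()
  sig <- eff[eff$significant, , drop = FALSE]
  if (nrow(sig) == 0L) notes <- c(notes, "no significant instances")
  effectSummary <- data.frame(
    nInstances = nrow(eff), nSignificant = nrow(sig),
    pctSignificant = 100 * nrow(sig) / nrow(eff),
    meanAmplitudeZs = if (nrow(sig)) mean(sig$amplitudeZs) else NA_real_,
    meanDurationMs = if (nrow(sig)) mean(sig$durationMs) else NA_real_)
  cov <- rd("coverage.csv")
  coverageSummary <- if (!is.null(cov)) {
    single <- cov[grepl("^neuron", cov$entity), ]
    data.frame(meanNeuronPct = mean(single$coveragePct),
               bestNeuronPct = cov$coveragePct[cov$entity == "bestNeuron"][1L],
               pc1Pct = cov$coveragePct[cov$entity == "PC1"][1L],
               unionPct = cov$coveragePct[cov$entity == "union"][1L])
  }
  dec <- rd("decoding.csv")
  decodingSummary <- if (!is.null(dec))
    stats::aggregate(accuracy ~ labels + data, dec, mean)
  perf <- rd("model_performance.csv")
  modelSummary <- if (!is.null(perf)) colMeans(perf)
  list(effects = effectSummary, coverage = coverageSummary,
       decoding = decodingSummary, models = modelSummary, notes = notes)
}
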