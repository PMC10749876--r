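#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- rowData colData
NULL

#' SoundLibrary: identities and flags of the sound set
#'
#' Holds the ordered integer identifiers of the sounds used to build
#' context-probe sequences, with silence reserved as identifier 0, and
#' per-sound metadata (display name, whether the sound is a conspecific
#' vocalization).  Vocalization flags drive the context-identity factor in
#' the category-level statistics.
#'
#' @slot soundIds integer vector 1..N.
#' @slot silenceId integer, always 0L.
#' @slot isVocalization logical vector parallel to \code{soundIds}.
#' @slot displayName character vector parallel to \code{soundIds}.
#' @export
setClass("SoundLibrary",
  representation(soundIds = "integer", silenceId = "integer",
                 isVocalization = "logical", displayName = "character"),
  prototype(silenceId = 0L))

setValidity("SoundLibrary", function(object) {
  msg <- character()
  n <- length(object@soundIds)
  if (n < 1L) msg <- c(msg, "library must contain at least one sound")
  if (anyDuplicated(object@soundIds)) msg <- c(msg, "sound ids must be unique")
  if (!identical(object@silenceId, 0L)) msg <- c(msg, "silenceId must be 0")
  if (any(object@soundIds == 0L)) msg <- c(msg, "sound ids must not collide with silence (0)")
  if (length(object@isVocalization) != n || length(object@displayName) != n)
    msg <- c(msg, "metadata vectors must parallel soundIds")
  if (length(msg)) msg else TRUE
})

#' Construct a SoundLibrary
#'
#' @param nSounds number of (non-silence) sounds, given ids \code{1:nSounds}.
#' @param isVocalization logical flags per sound (recycled; default all FALSE).
#' @param displayName optional names per sound.
#' @return A \linkS4class{SoundLibrary}.
#' @examples
#' soundLibrary(4, isVocalization = c(TRUE, FALSE, FALSE, FALSE))
#' @export
soundLibrary <- function(nSounds, isVocalization = FALSE, displayName = NULL) {
  nSounds <- as.integer(nSounds)
  if (length(nSounds) != 1L || is.na(nSounds) || nSounds < 1L)
    stop("nSounds must be a single integer >= 1")
  if (is.null(displayName)) displayName <- paste0("sound", seq_len(nSounds))
  new("SoundLibrary", soundIds = seq_len(nSounds), silenceId = 0L,
      isVocalization = rep_len(as.logical(isVocalization), nSounds),
      displayName = rep_len(as.character(displayName), nSounds))
}

#' SequenceSet: an exact-cover context-probe sequence design
#'
#' A set of N ordered sound sequences, each of N+1 one-second sounds, such
#' that every ordered (context, probe) event with context in {0..N} (0 =
#' silence, realized by the sequence-initial position) and probe in {1..N}
#' occurs exactly once across the whole set.
#'
#' @slot nSounds integer N.
#' @slot sequences list of N integer vectors, each of length N+1.
#' @slot seed integer seed used by the solver.
#' @export
setClass("SequenceSet",
  representation(nSounds = "integer", sequences = "list", seed = "integer"))

setValidity("SequenceSet", function(object) {
  rep <- validateSequences(object)
  if (rep$valid) TRUE else paste(rep$problems, collapse = "; ")
})

#' @describeIn SequenceSet-class display a compact summary
#' @param object a \code{SequenceSet}
#' @export
setMethod("show", "SequenceSet", function(object) {
  cat(sprintf("SequenceSet: %d sequences of %d sounds (seed %d)\n",
              object@nSounds, object@nSounds + 1L, object@seed))
  for (s in object@sequences)
    cat(" ", paste(s, collapse = " -> "), "\n")
})

#' Spectrogram: log-compressed spectro-temporal representation of one sound
#'
#' Channels-by-time matrix of log-compressed power on log-spaced frequency
#' channels, the input representation for the encoding models and for the
#' descriptive sound metrics.
#'
#' @slot values numeric matrix, channels x time.
#' @slot channelFreqs channel center frequencies (Hz), increasing.
#' @slot dt time-bin width in seconds.
#' @export
setClass("Spectrogram",
  representation(values = "matrix", channelFreqs = "numeric", dt = "numeric"))

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (nrow(object@values) < 2L) msg <- c(msg, "need at least 2 channels")
  if (length(object@channelFreqs) != nrow(object@values))
    msg <- c(msg, "channelFreqs must match the channel dimension")
  if (is.unsorted(object@channelFreqs, strictly = TRUE))
    msg <- c(msg, "channelFreqs must be strictly increasing")
  if (length(object@dt) != 1L || object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d channels (%.0f-%.0f Hz) x %d bins (dt %.3f s)\n",
              nrow(object@values), min(object@channelFreqs),
              max(object@channelFreqs), ncol(object@values), object@dt))
})

#' PopulationRecording: binned population spike counts with metadata
#'
#' Extends \code{SummarizedExperiment}: rows are neurons, columns are trials
#' (one trial = one presentation of one full sequence).  The
#' \code{"counts"} assay is a 3-D array (neurons x trials x time bins) at the
#' analysis rate (50-ms bins, 20 Hz); the optional \code{"fineCounts"} assay
#' is the same at the encoding-model rate (10-ms bins, 100 Hz).  Neuron
#' metadata (region, spike peak-to-trough delay, optotag flag) lives in
#' \code{rowData}; trial metadata (sequence index, repetition, presentation
#' order) in \code{colData}.  The generating \linkS4class{SequenceSet}, the
#' pupil trace and (for simulations) the ground truth live in
#' \code{metadata}.
#'
#' @export
setClass("PopulationRecording", contains = "SummarizedExperiment")

setValidity("PopulationRecording", function(object) {
  msg <- character()
  a <- assays(object)
  if (!("counts" %in% names(a))) return("missing 'counts' assay")
  cnt <- a[["counts"]]
  if (length(dim(cnt)) != 3L) msg <- c(msg, "'counts' must be neurons x trials x time")
  if (any(cnt < 0, na.rm = TRUE)) msg <- c(msg, "counts must be non-negative")
  if (!is(metadata(object)$sequences, "SequenceSet"))
    msg <- c(msg, "metadata$sequences must be a SequenceSet")
  if (is.null(metadata(object)$binDt)) msg <- c(msg, "metadata$binDt missing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PopulationRecording", function(object) {
  cnt <- assays(object)[["counts"]]
  cat(sprintf("PopulationRecording: %d neurons x %d trials x %d bins (dt %.3f s)\n",
              dim(cnt)[1], dim(cnt)[2], dim(cnt)[3], metadata(object)$binDt))
  cat(sprintf("  sequences: N = %d sounds; assays: %s\n",
              metadata(object)$sequences@nSounds,
              paste(names(assays(object)), collapse = ", ")))
})

#' EffectProfile: one contextual instance's time-resolved context effect
#'
#' Per 50-ms bin of the probe window: the probe-PSTH difference between the
#' two contexts in Z units, the two-sample T score, the post-cluster-test
#' significance mask, and the cluster table (start/end bin, summed T score,
#' permutation p value).
#'
#' @slot delta numeric, deltaZ per bin (context A minus context B).
#' @slot tscore numeric, per-bin T score.
#' @slot sigMask logical, bins belonging to significant clusters.
#' @slot clusters data.frame with columns start, end, mass, p.
#' @slot binDt numeric, bin width (s).
#' @export
setClass("EffectProfile",
  representation(delta = "numeric", tscore = "numeric", sigMask = "logical",
                 clusters = "data.frame", binDt = "numeric"))

setValidity("EffectProfile", function(object) {
  msg <- character()
  n <- length(object@delta)
  if (length(object@tscore) != n || length(object@sigMask) != n)
    msg <- c(msg, "delta/tscore/sigMask must have the same length")
  if (nrow(object@clusters) &&
      (any(object@clusters$start < 1L) || any(object@clusters$end > n)))
    msg <- c(msg, "cluster bounds out of range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EffectProfile", function(object) {
  cat(sprintf("EffectProfile: %d bins (dt %.0f ms), %d cluster(s), %d significant bin(s)\n",
              length(object@delta), 1000 * object@binDt,
              nrow(object@clusters), sum(object@sigMask)))
})
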