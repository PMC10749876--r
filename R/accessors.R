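#' Accessors for PopulationRecording
#'
#' @param x a \linkS4class{PopulationRecording}.
#' @return \code{spikeCounts}: neurons x trials x bins array at the analysis
#'   rate; \code{fineCounts}: same at the encoding-model rate;
#'   \code{sequenceSet}: the \linkS4class{SequenceSet} used;
#'   \code{pupilTrace}: trials x bins pupil matrix; \code{groundTruth}: list
#'   of injected effects and generative parameters (simulations only);
#'   \code{neuronData}/\code{trialData}: metadata DataFrames; \code{binDt}:
#'   analysis bin width (s).
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))
#' @rdname recording-accessors
#' @export
setMethod("spikeCounts", "PopulationRecording",
          function(x) assays(x)[["counts"]])

#' @rdname recording-accessors
#' @export
setGeneric("fineCounts", function(x) standardGeneric("fineCounts"))
#' @rdname recording-accessors
#' @export
setMethod("fineCounts", "PopulationRecording",
          function(x) assays(x)[["fineCounts"]])

#' @rdname recording-accessors
#' @export
setGeneric("sequenceSet", function(x) standardGeneric("sequenceSet"))
#' @rdname recording-accessors
#' @export
setMethod("sequenceSet", "PopulationRecording",
          function(x) metadata(x)$sequences)

#' @rdname recording-accessors
#' @export
setGeneric("pupilTrace", function(x) standardGeneric("pupilTrace"))
#' @rdname recording-accessors
#' @export
setMethod("pupilTrace", "PopulationRecording",
          function(x) metadata(x)$pupil)

#' @rdname recording-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname recording-accessors
#' @export
setMethod("groundTruth", "PopulationRecording",
          function(x) metadata(x)$groundTruth)

#' @rdname recording-accessors
#' @export
neuronData <- function(x) rowData(x)

#' @rdname recording-accessors
#' @export
trialData <- function(x) colData(x)

#' @rdname recording-accessors
#' @export
binDt <- function(x) metadata(x)$binDt

#' Accessors for SequenceSet
#'
#' @param x a \linkS4class{SequenceSet}.
#' @return \code{nSounds}: integer N; \code{sequences}: list of integer
#'   vectors of length N+1.
#' @name sequence-accessors
NULL

#' @rdname sequence-accessors
#' @export
setGeneric("nSounds", function(x) standardGeneric("nSounds"))
#' @rdname sequence-accessors
#' @export
setMethod("nSounds", "SequenceSet", function(x) x@nSounds)

#' @rdname sequence-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname sequence-accessors
#' @export
setMethod("sequences", "SequenceSet", function(x) x@sequences)
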