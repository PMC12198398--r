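# Accessor generics: user code reads slots through these, never with @.

#' @name accessors
#' @title Accessors for gazecluster result objects
#' @description Small accessor functions for the package's S4 containers.
#' @param x,object a gazecluster S4 object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("gcm", function(x) standardGeneric("gcm"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("clusterCount", function(x) standardGeneric("clusterCount"))

#' @rdname accessors
#' @export
setGeneric("smoothedGCM", function(x) standardGeneric("smoothedGCM"))

#' @rdname accessors
#' @export
setGeneric("smoothedClusterCount",
           function(x) standardGeneric("smoothedClusterCount"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("frameParams", function(x) standardGeneric("frameParams"))

#' @rdname accessors
#' @export
setGeneric("iscValues", function(x) standardGeneric("iscValues"))

#' @rdname accessors
#' @export
setGeneric("componentWeights", function(x) standardGeneric("componentWeights"))

#' @rdname accessors
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname accessors
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @rdname accessors
#' @export
setGeneric("isExcluded", function(x) standardGeneric("isExcluded"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setMethod("gcm", "AttentionSeries", function(x) x@gcm)

#' @rdname accessors
#' @export
setMethod("membership", "AttentionSeries", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("clusterCount", "AttentionSeries", function(x) x@clusterCount)

#' @rdname accessors
#' @export
setMethod("clusterCount", "GazeClustering",
          function(x) x@params$n_clusters)

#' @rdname accessors
#' @export
setMethod("smoothedGCM", "AttentionSeries", function(x) x@smoothedGCM)

#' @rdname accessors
#' @export
setMethod("smoothedClusterCount", "AttentionSeries",
          function(x) x@smoothedClusterCount)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "GazeClustering", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("frameParams", "GazeClustering", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("iscValues", "CorrCAModel", function(x) x@isc)

#' @rdname accessors
#' @export
setMethod("componentWeights", "CorrCAModel", function(x) x@W)

#' @rdname accessors
#' @export
setMethod("coefTable", "FitResult", function(x) x@coefficients)

#' @rdname accessors
#' @export
setMethod("varComponents", "FitResult", function(x) x@varcomp)

#' @rdname accessors
#' @export
setMethod("isExcluded", "EpochSet", function(x) x@excluded)

#' @rdname accessors
#' @export
setMethod("subjectId", "GazeRecording", function(x) x@subject)

#' @rdname accessors
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subject)

#' @rdname accessors
#' @export
setMethod("samplingRate", "GazeRecording", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)

#' Video geometry of a FrameGazeMatrix
#'
#' @param x a [FrameGazeMatrix-class].
#' @return `videoFps`/`videoDuration` return scalars; `screenDims` the
#'   (width, height) pixel pair.
#' @export
videoFps <- function(x) S4Vectors::metadata(x)$fps

#' @rdname videoFps
#' @export
videoDuration <- function(x) S4Vectors::metadata(x)$duration

#' @rdname videoFps
#' @export
screenDims <- function(x) S4Vectors::metadata(x)$screen
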