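#' @import methods
#' @importFrom stats approx cor cov fitted mad pnorm pt qt rnorm runif rpois sd var setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# ---------------------------------------------------------------------------
# Stimulus / simulation classes
# ---------------------------------------------------------------------------

#' FocusTrack: one meaningful focus of a scene
#'
#' A focus is a point of the screen that attentive observers may track. Its
#' position over time is given by a vectorized path function; the focus only
#' exists during its active intervals.
#'
#' @slot path function of time (seconds, vectorized) returning a two-column
#'   matrix of (x, y) pixel positions.
#' @slot active two-column matrix of half-open (start, end) second intervals
#'   during which the focus is on screen.
#' @slot salience non-negative weight used when assigning attentive observers
#'   to simultaneously active foci.
#' @exportClass FocusTrack
setClass("FocusTrack",
         representation(path = "function", active = "matrix",
                        salience = "numeric"))

setValidity("FocusTrack", function(object) {
  if (ncol(object@active) != 2L) return("'active' must have two columns")
  if (any(object@active[, 2] <= object@active[, 1]))
    return("active intervals must have end > start")
  if (length(object@salience) != 1L || object@salience < 0)
    return("'salience' must be a single non-negative weight")
  TRUE
})

#' SceneScript: synthetic video stimulus description
#'
#' @slot duration video duration in seconds.
#' @slot fps frames per second.
#' @slot screen integer vector (width, height) in pixels.
#' @slot foci list of [FocusTrack-class] objects.
#' @slot segments data.frame (start, end, label) of non-overlapping content
#'   segments emulating period-of-interest annotations.
#' @exportClass SceneScript
setClass("SceneScript",
         representation(duration = "numeric", fps = "numeric",
                        screen = "numeric", foci = "list",
                        segments = "data.frame"))

setValidity("SceneScript", function(object) {
  if (object@duration <= 0) return("duration must be positive")
  if (object@fps <= 0) return("fps must be positive")
  if (length(object@screen) != 2L || any(object@screen <= 0))
    return("screen must be positive (width, height)")
  if (!all(vapply(object@foci, is, logical(1), "FocusTrack")))
    return("foci must all be FocusTrack objects")
  # every focus position must be on-screen while active
  for (f in object@foci) {
    for (i in seq_len(nrow(f@active))) {
      tt <- seq(f@active[i, 1], min(f@active[i, 2], object@duration),
                length.out = 25)
      p <- f@path(tt)
      if (any(p[, 1] < 0 | p[, 1] >= object@screen[1] |
              p[, 2] < 0 | p[, 2] >= object@screen[2]))
        return("focus path leaves the screen during an active interval")
    }
  }
  if (nrow(object@segments)) {
    s <- object@segments[order(object@segments$start), ]
    if (any(s$start < 0) || any(s$end > object@duration))
      return("segments must lie within [0, duration]")
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)]))
      return("segments must not overlap")
  }
  TRUE
})

#' ObserverProfile: behavioural profile of one simulated viewer
#'
#' @slot stateFun function of time (seconds, vectorized) returning a list with
#'   `state` (character: "attentive", "wandering", "off_screen") and `focus`
#'   (integer focus index, NA unless attentive).
#' @slot fixationNoiseSd fixation scatter around the tracked focus, pixels.
#' @slot blinkRate blinks per minute.
#' @slot blinkDurMean,blinkDurSd blink duration distribution, milliseconds.
#' @slot saccadeLag latency with which gaze follows a moving focus, ms.
#' @slot wanderStepSd random-walk step standard deviation, pixels per sample.
#' @exportClass ObserverProfile
setClass("ObserverProfile",
         representation(stateFun = "function", fixationNoiseSd = "numeric",
                        blinkRate = "numeric", blinkDurMean = "numeric",
                        blinkDurSd = "numeric", saccadeLag = "numeric",
                        wanderStepSd = "numeric"))

setValidity("ObserverProfile", function(object) {
  if (object@fixationNoiseSd < 0) return("fixationNoiseSd must be >= 0")
  if (object@blinkRate < 0) return("blinkRate must be >= 0")
  if (object@blinkDurMean <= 0) return("blinkDurMean must be positive")
  TRUE
})

#' GroundTruth: generating state of a simulated session
#'
#' @slot stateMatrix character matrix (frames x subjects) of intended states.
#' @slot focusCount integer vector, active foci per frame.
#' @slot attentionFraction numeric per subject, fraction of frames intended
#'   attentive.
#' @slot blinkLog list per subject of data.frames (onset, offset) in ms.
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(stateMatrix = "matrix", focusCount = "integer",
                        attentionFraction = "numeric", blinkLog = "list"))

setValidity("GroundTruth", function(object) {
  af <- object@attentionFraction
  if (any(af < 0 | af > 1, na.rm = TRUE))
    return("attention fractions must lie in [0, 1]")
  if (any(object@focusCount < 0)) return("focus counts must be >= 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Recording classes
# ---------------------------------------------------------------------------

#' GazeRecording: one subject's raw gaze sample stream
#'
#' @slot subject subject identifier.
#' @slot rate sampling rate in Hz.
#' @slot t sample times in ms since video onset, strictly increasing.
#' @slot x,y gaze position in pixels (NA allowed).
#' @slot pupil pupil size in arbitrary units (0/NA during blinks).
#' @slot valid logical; FALSE marks samples treated as missing downstream.
#' @exportClass GazeRecording
setClass("GazeRecording",
         representation(subject = "character", rate = "numeric",
                        t = "numeric", x = "numeric", y = "numeric",
                        pupil = "numeric", valid = "logical"))

setValidity("GazeRecording", function(object) {
  n <- length(object@t)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@pupil) != n || length(object@valid) != n)
    return("t, x, y, pupil and valid must have equal length")
  if (n > 1L && any(diff(object@t) <= 0))
    return("sample times must be strictly increasing")
  if (object@rate <= 0) return("sampling rate must be positive")
  TRUE
})

setMethod("show", "GazeRecording", function(object) {
  cat("GazeRecording '", object@subject, "': ", length(object@t),
      " samples at ", object@rate, " Hz, ",
      sprintf("%.1f%%", 100 * mean(!object@valid)), " invalid\n", sep = "")
})

#' @describeIn GazeRecording-class number of samples
#' @param x a GazeRecording
#' @export
setMethod("length", "GazeRecording", function(x) length(x@t))

#' FrameGazeMatrix: per-frame x per-subject aggregated gaze positions
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] with two
#' assays `x` and `y` (frames in rows, subjects in columns, NA = missing) and
#' the video geometry in `metadata` (fps, duration, screen).
#'
#' @exportClass FrameGazeMatrix
#' @import SummarizedExperiment
setClass("FrameGazeMatrix", contains = "SummarizedExperiment")

setValidity("FrameGazeMatrix", function(object) {
  if (!all(c("x", "y") %in% SummarizedExperiment::assayNames(object)))
    return("assays 'x' and 'y' are required")
  md <- S4Vectors::metadata(object)
  for (k in c("fps", "duration", "screen"))
    if (is.null(md[[k]])) return(paste0("metadata '", k, "' is required"))
  if (nrow(object) != round(md$duration * md$fps))
    return("number of frames must equal round(duration * fps)")
  xs <- SummarizedExperiment::assay(object, "x")
  ys <- SummarizedExperiment::assay(object, "y")
  w <- md$screen[1]; h <- md$screen[2]
  if (any(xs < 0 | xs >= w, na.rm = TRUE) ||
      any(ys < 0 | ys >= h, na.rm = TRUE))
    return("stored positions must lie on-screen")
  TRUE
})

# ---------------------------------------------------------------------------
# Clustering result classes
# ---------------------------------------------------------------------------

#' GazeClustering: per-frame DBSCAN labelling of all subjects
#'
#' @slot labels integer matrix (frames x subjects); NA = no valid position,
#'   0 = noise/outlier, k >= 1 = member of cluster k (ids canonical by
#'   smallest member index within each frame).
#' @slot params data.frame with one row per frame: `n_valid`, `min_pts`,
#'   `epsilon` (NA when clustering was skipped), `n_clusters`.
#' @slot fps frames per second.
#' @slot duration video duration, seconds.
#' @exportClass GazeClustering
setClass("GazeClustering",
         representation(labels = "matrix", params = "data.frame",
                        fps = "numeric", duration = "numeric"))

setValidity("GazeClustering", function(object) {
  if (nrow(object@labels) != nrow(object@params))
    return("one params row per frame is required")
  TRUE
})

setMethod("show", "GazeClustering", function(object) {
  cat("GazeClustering: ", nrow(object@labels), " frames x ",
      ncol(object@labels), " subjects; cluster count range ",
      paste(range(object@params$n_clusters), collapse = "-"), "\n", sep = "")
})

#' AttentionSeries: gaze-cluster-membership time courses
#'
#' @slot membership integer matrix (frames x subjects): 1 in a cluster,
#'   0 noise, NA missing.
#' @slot gcm per-subject summary: fraction of non-missing frames spent inside
#'   a cluster (NA when a subject has no non-missing frame).
#' @slot clusterCount integer per frame.
#' @slot grid seconds of the smoothed 1 s grid (window centers).
#' @slot smoothedGCM matrix (grid x subjects), moving-window averaged
#'   membership.
#' @slot smoothedClusterCount numeric per grid second.
#' @exportClass AttentionSeries
setClass("AttentionSeries",
         representation(membership = "matrix", gcm = "numeric",
                        clusterCount = "integer", grid = "numeric",
                        smoothedGCM = "matrix",
                        smoothedClusterCount = "numeric"))

setValidity("AttentionSeries", function(object) {
  if (any(object@gcm < 0 | object@gcm > 1, na.rm = TRUE))
    return("GCM summaries must lie in [0, 1]")
  TRUE
})

setMethod("show", "AttentionSeries", function(object) {
  cat("AttentionSeries: ", ncol(object@membership), " subjects, ",
      nrow(object@membership), " frames; mean GCM ",
      sprintf("%.3f", mean(object@gcm, na.rm = TRUE)), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# CorrCA / EEG classes
# ---------------------------------------------------------------------------

#' CorrCAModel: correlated component analysis fit
#'
#' @slot Rb pooled between-subject covariance (channels x channels).
#' @slot Rw pooled within-subject covariance.
#' @slot W weight matrix, one unit-norm column per component, sorted by
#'   descending inter-subject correlation; sign fixed so the largest-magnitude
#'   entry is positive.
#' @slot isc per-component inter-subject correlation
#'   \eqn{(w^T R_b w) / (w^T R_w w)}.
#' @exportClass CorrCAModel
setClass("CorrCAModel",
         representation(Rb = "matrix", Rw = "matrix", W = "matrix",
                        isc = "numeric"))

setMethod("show", "CorrCAModel", function(object) {
  cat("CorrCAModel: ", ncol(object@W), " components over ", nrow(object@W),
      " channels; ISC_1 = ", sprintf("%.3f", object@isc[1]), "\n", sep = "")
})

#' EEGRecording: one subject's multichannel EEG stream
#'
#' @slot subject subject identifier.
#' @slot rate sampling rate, Hz.
#' @slot data channels x samples amplitude matrix, microvolts.
#' @slot channels channel names.
#' @slot markers data.frame (label, sample) of event markers (1-based sample
#'   indices).
#' @exportClass EEGRecording
setClass("EEGRecording",
         representation(subject = "character", rate = "numeric",
                        data = "matrix", channels = "character",
                        markers = "data.frame"))

setValidity("EEGRecording", function(object) {
  if (object@rate <= 0) return("rate must be positive")
  if (nrow(object@data) != length(object@channels))
    return("one channel name per data row is required")
  if (nrow(object@markers) &&
      (any(object@markers$sample < 1) ||
       any(object@markers$sample > ncol(object@data))))
    return("marker sample indices out of range")
  TRUE
})

#' EpochSet: fixed-length epochs with artifact flags
#'
#' @slot epochs array (epochs x channels x samples).
#' @slot badChannel logical matrix (epochs x channels), peak-to-peak above
#'   the rejection limit.
#' @slot badEpoch logical per epoch (more than the allowed channels bad).
#' @slot excluded single logical: bad-epoch fraction above the subject limit.
#' @slot rate sampling rate, Hz.
#' @exportClass EpochSet
setClass("EpochSet",
         representation(epochs = "array", badChannel = "matrix",
                        badEpoch = "logical", excluded = "logical",
                        rate = "numeric"))

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet: ", dim(object@epochs)[1], " epochs x ",
      dim(object@epochs)[2], " channels; ", sum(object@badEpoch),
      " bad; subject ", if (object@excluded) "EXCLUDED" else "retained",
      "\n", sep = "")
})

# ---------------------------------------------------------------------------
# Statistics classes
# ---------------------------------------------------------------------------

#' FitResult: coefficient table of an OLS or mixed-model fit
#'
#' @slot coefficients data.frame with columns `term`, `estimate`, `se`, `t`,
#'   `df`, `p`.
#' @slot varcomp named numeric; for mixed models `sigma2_intercept` and
#'   `sigma2_residual`, for OLS `sigma2_residual` only.
#' @slot logREML restricted log-likelihood (NA for OLS fits).
#' @slot nobs,nsubjects problem sizes.
#' @exportClass FitResult
setClass("FitResult",
         representation(coefficients = "data.frame", varcomp = "numeric",
                        logREML = "numeric", nobs = "integer",
                        nsubjects = "integer"))

setValidity("FitResult", function(object) {
  cf <- object@coefficients
  need <- c("term", "estimate", "se", "t", "df", "p")
  if (!all(need %in% names(cf)))
    return("coefficient table must have term/estimate/se/t/df/p")
  if (any(cf$p < 0 | cf$p > 1, na.rm = TRUE)) return("p-values must be in [0,1]")
  if (any(object@varcomp < 0, na.rm = TRUE))
    return("variance components must be >= 0")
  TRUE
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@nobs, " observations, ", object@nsubjects,
      " subjects)\n", sep = "")
  cf <- object@coefficients
  cf$estimate <- round(cf$estimate, 4); cf$se <- round(cf$se, 4)
  cf$t <- round(cf$t, 2); cf$p <- signif(cf$p, 3)
  print(cf, row.names = FALSE)
  if (!is.na(object@logREML))
    cat("sigma2_intercept =", signif(object@varcomp[["sigma2_intercept"]], 4),
        " sigma2_residual =", signif(object@varcomp[["sigma2_residual"]], 4),
        " logREML =", round(object@logREML, 2), "\n")
})
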