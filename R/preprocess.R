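# Eye-tracking preprocessing: blink detection and padding, off-screen
# masking, subject-level quality exclusion, gap interpolation, and
# aggregation of samples to the video-frame grid.

#' Detect blinks from the pupil trace
#'
#' Blink cores are maximal runs where the pupil signal is missing or zero
#' (the standard zero-pupil convention of video eye trackers). Each core is
#' extended while the per-sample pupil change is abrupt — larger in magnitude
#' than `velocityK` times the MAD of all pupil differences — then padded by
#' `padMs` on both sides to absorb the eyelid-induced gaze distortion, and
#' overlapping intervals are merged.
#'
#' @param pupil numeric pupil series (a.u.); NA or 0 marks a closed eye.
#' @param samplingRate Hz.
#' @param velocityK multiplier of MAD(diff(pupil)) for edge refinement
#'   (default 5).
#' @param padMs padding applied before onset and after offset, ms
#'   (default 60).
#' @param t optional sample times in ms; defaults to a regular grid starting
#'   at 0.
#' @return data.frame of half-open `(onset, offset)` intervals in ms, sorted
#'   and non-overlapping. An all-missing series yields one interval covering
#'   the whole recording with `attr(, "allMissing") = TRUE`.
#' @export
detectBlinks <- function(pupil, samplingRate, velocityK = 5, padMs = 60,
                         t = NULL) {
  if (length(pupil) == 0L) stop("pupil series must be non-empty")
  if (samplingRate <= 0) stop("sampling rate must be positive")
  n <- length(pupil)
  dt <- 1000 / samplingRate
  if (is.null(t)) t <- (seq_len(n) - 1L) * dt
  closed <- is.na(pupil) | pupil == 0
  if (all(closed)) {
    out <- data.frame(onset = t[1], offset = t[n] + dt)
    attr(out, "allMissing") <- TRUE
    warning("pupil series entirely missing; whole recording flagged")
    return(out)
  }
  if (!any(closed))
    return(data.frame(onset = numeric(0), offset = numeric(0)))

  # pupil velocity among open-eye samples only: differences touching the
  # closed run are the closure step itself, not a pre/post-blink transient
  open_pupil <- pupil
  open_pupil[closed] <- NA_real_
  dp <- diff(open_pupil)
  thr <- velocityK * mad(dp, na.rm = TRUE)

  r <- rle(closed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ks <- which(r$values)
  onset <- integer(0); offset <- integer(0)
  for (k in ks) {
    s <- starts[k]; e <- ends[k]
    # extend backward/forward while consecutive open samples change abruptly
    while (s > 2L && !is.na(dp[s - 2L]) && abs(dp[s - 2L]) > thr) s <- s - 1L
    while (e < n - 1L && !is.na(dp[e + 1L]) && abs(dp[e + 1L]) > thr)
      e <- e + 1L
    onset <- c(onset, s); offset <- c(offset, e)
  }
  # half-open [t(first), t(last) + one sample), then pad and merge
  iv <- mergeIntervals(t[onset] - padMs,
                       t[offset] + dt + padMs)
  iv
}

#' Mask blink and off-screen samples
#'
#' Marks as invalid every sample inside a padded blink interval and every
#' sample whose position falls outside the half-open screen ranges
#' `[0, width) x [0, height)` (or is already missing). Valid samples are
#' untouched, so the operation is idempotent.
#'
#' @param rec a [GazeRecording-class].
#' @param blinks blink interval table from [detectBlinks()] (may be empty).
#' @param screen (width, height) in pixels.
#' @return the recording with its `valid` mask updated.
#' @export
maskSamples <- function(rec, blinks, screen) {
  stopifnot(is(rec, "GazeRecording"))
  if (any(screen <= 0)) stop("screen dimensions must be positive")
  inBlink <- inAnyInterval(rec@t, blinks$onset, blinks$offset)
  off <- is.na(rec@x) | is.na(rec@y) |
    rec@x < 0 | rec@x >= screen[1] | rec@y < 0 | rec@y >= screen[2]
  rec@valid <- rec@valid & !inBlink & !off
  rec
}

#' Flag outlier subjects on blink count and missing-data fraction
#'
#' Both criteria are z-scored across subjects (sample mean and sd,
#' denominator n - 1) and a subject is excluded when it scores more than two
#' standard deviations *above* the mean on at least one criterion. A
#' zero-variance criterion gives z = 0 for everyone and excludes nobody.
#'
#' @param blinkCount integer per subject.
#' @param missingFraction numeric per subject, in \[0, 1\].
#' @param subjects subject ids (default S001, ...).
#' @param zLimit exclusion threshold (default 2).
#' @return data.frame (subject, blink_count, missing_fraction, z_blink,
#'   z_missing, excluded), one row per subject.
#' @export
excludeOutlierSubjects <- function(blinkCount, missingFraction,
                                   subjects = NULL, zLimit = 2) {
  n <- length(blinkCount)
  if (n < 3L) stop("at least three subjects are required")
  if (length(missingFraction) != n)
    stop("blinkCount and missingFraction must have equal length")
  if (any(missingFraction < 0 | missingFraction > 1))
    stop("missing fractions must lie in [0, 1]")
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(n))
  zb <- zscoreSafe(blinkCount)
  zm <- zscoreSafe(missingFraction)
  data.frame(subject = subjects, blink_count = blinkCount,
             missing_fraction = missingFraction,
             z_blink = zb, z_missing = zm,
             excluded = zb > zLimit | zm > zLimit)
}

#' Fill missing gaze samples by linear interpolation
#'
#' Replaces every invalid run by linear interpolation between the neighboring
#' valid samples, separately in x and y; leading and trailing runs take the
#' nearest valid value. The result has no missing samples and is intended
#' only as input to the inter-subject correlation (which cannot handle gaps)
#' — clustering always works on the masked, uninterpolated data. Apply
#' [maskSamples()] first so blink-edge artifacts and off-screen samples do
#' not anchor the interpolation.
#'
#' @param rec a [GazeRecording-class].
#' @return the recording with all samples valid.
#' @export
interpolateGaps <- function(rec) {
  stopifnot(is(rec, "GazeRecording"))
  ok <- rec@valid & !is.na(rec@x) & !is.na(rec@y)
  if (sum(ok) < 2L) stop("at least two valid samples are required")
  if (all(ok)) return(rec)
  rec@x <- approx(rec@t[ok], rec@x[ok], xout = rec@t, rule = 2)$y
  rec@y <- approx(rec@t[ok], rec@y[ok], xout = rec@t, rule = 2)$y
  rec@valid <- rep(TRUE, length(rec@t))
  rec
}

#' Aggregate gaze recordings onto the video frame grid
#'
#' Frame i (0-based) covers the half-open window `[i/fps, (i+1)/fps)`
#' seconds; a cell holds the mean of the subject's valid samples in that
#' window and is missing when the window has none.
#'
#' @param recs list of [GazeRecording-class] objects sharing the video onset
#'   as time origin.
#' @param fps frames per second.
#' @param duration video duration, seconds.
#' @param screen (width, height) pixels.
#' @return a [FrameGazeMatrix-class] with `round(duration * fps)` rows.
#' @export
aggregateToFrames <- function(recs, fps, duration, screen) {
  nFrames <- round(duration * fps)
  nsub <- length(recs)
  ids <- vapply(recs, subjectId, character(1))
  X <- matrix(NA_real_, nFrames, nsub, dimnames = list(NULL, ids))
  Y <- X
  for (j in seq_len(nsub)) {
    r <- recs[[j]]
    if (max(r@t) < (duration * 1000) - 1000 / r@rate)
      warning("recording '", r@subject,
              "' is shorter than the video; trailing frames missing")
    ok <- r@valid & !is.na(r@x) & !is.na(r@y)
    if (!any(ok)) next
    f <- floor(r@t[ok] / 1000 * fps)
    keep <- f >= 0 & f < nFrames
    f <- as.integer(f[keep]) + 1L
    xs <- r@x[ok][keep]; ys <- r@y[ok][keep]
    cnt <- tabulate(f, nFrames)
    sx <- rowsum(xs, f)
    sy <- rowsum(ys, f)
    idx <- as.integer(rownames(sx))
    X[idx, j] <- sx[, 1] / cnt[idx]
    Y[idx, j] <- sy[, 1] / cnt[idx]
  }
  frameGazeMatrix(X, Y, fps = fps, duration = duration, screen = screen)
}

#' Construct a FrameGazeMatrix from assay matrices
#'
#' @param x,y frames x subjects matrices of pixel positions (NA = missing).
#' @param fps frames per second.
#' @param duration seconds.
#' @param screen (width, height) pixels.
#' @return a [FrameGazeMatrix-class].
#' @export
frameGazeMatrix <- function(x, y, fps, duration, screen) {
  nFrames <- nrow(x)
  rd <- S4Vectors::DataFrame(frame = seq_len(nFrames) - 1L,
                             t_center = (seq_len(nFrames) - 0.5) / fps)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = x, y = y), rowData = rd,
    metadata = list(fps = fps, duration = duration, screen = screen))
  new("FrameGazeMatrix", se)
}

#' Quality report for a list of recordings
#'
#' Convenience wrapper running blink detection and masking on every
#' recording, then the outlier-exclusion rule across subjects.
#'
#' @param recs list of [GazeRecording-class].
#' @param screen (width, height) pixels.
#' @param duration video duration, seconds (missing fraction is measured over
#'   samples within the video only).
#' @param velocityK,padMs passed to [detectBlinks()].
#' @param zLimit passed to [excludeOutlierSubjects()].
#' @return list with `report` (the exclusion table), `masked` (the masked
#'   recordings) and `blinks` (per-subject interval tables).
#' @export
preprocessGaze <- function(recs, screen, duration, velocityK = 5,
                           padMs = 60, zLimit = 2) {
  blinks <- vector("list", length(recs))
  masked <- vector("list", length(recs))
  nb <- integer(length(recs)); mf <- numeric(length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    blinks[[i]] <- detectBlinks(r@pupil, r@rate, velocityK = velocityK,
                                padMs = padMs, t = r@t)
    masked[[i]] <- maskSamples(r, blinks[[i]], screen)
    inVideo <- r@t >= 0 & r@t < duration * 1000
    nb[i] <- nrow(blinks[[i]])
    mf[i] <- mean(!masked[[i]]@valid[inVideo])
  }
  report <- excludeOutlierSubjects(nb, mf,
                                   subjects = vapply(recs, subjectId,
                                                     character(1)),
                                   zLimit = zLimit)
  list(report = report, masked = masked, blinks = blinks)
}
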