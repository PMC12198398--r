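# Synthetic multi-observer session generator.
#
# The generator plants a known attention structure (who looks where, when,
# blinks, off-screen excursions, a shared EEG component) so every downstream
# stage of the pipeline can be validated against ground truth.

#' Construct a focus track
#'
#' @param path either a function of time (seconds, vectorized) returning a
#'   two-column (x, y) matrix, or a length-2 numeric giving a static position.
#' @param active matrix of (start, end) second intervals; default one interval
#'   covering `c(0, Inf)` truncated by the scene.
#' @param salience non-negative assignment weight (default 1).
#' @return a [FocusTrack-class].
#' @export
focusTrack <- function(path, active = NULL, salience = 1) {
  if (is.numeric(path) && length(path) == 2L) {
    pos <- path
    path <- function(t) cbind(rep(pos[1], length(t)), rep(pos[2], length(t)))
  }
  if (is.null(active)) active <- matrix(c(0, Inf), nrow = 1)
  if (is.vector(active)) active <- matrix(active, ncol = 2, byrow = TRUE)
  new("FocusTrack", path = path, active = active, salience = salience)
}

#' Construct a circularly moving focus
#'
#' Convenience wrapper producing a focus that orbits `center` with the given
#' radius and period; useful to give attentive gaze a correlated time course.
#'
#' @param center (x, y) pixel center.
#' @param radius orbit radius, pixels.
#' @param period seconds per revolution.
#' @param phase initial phase, radians.
#' @inheritParams focusTrack
#' @return a [FocusTrack-class].
#' @export
orbitingFocus <- function(center, radius, period, phase = 0,
                          active = NULL, salience = 1) {
  path <- function(t) {
    a <- 2 * pi * t / period + phase
    cbind(center[1] + radius * cos(a), center[2] + radius * sin(a))
  }
  focusTrack(path, active = active, salience = salience)
}

#' Construct a scene script
#'
#' @param duration seconds.
#' @param fps frames per second.
#' @param screen (width, height) in pixels.
#' @param foci list of [FocusTrack-class] objects.
#' @param segments data.frame (start, end, label); optional.
#' @return a [SceneScript-class].
#' @export
sceneScript <- function(duration, fps, screen, foci,
                        segments = data.frame(start = numeric(0),
                                              end = numeric(0),
                                              label = character(0))) {
  if (duration <= 0) stop("duration must be positive")
  if (fps <= 0) stop("fps must be positive")
  foci <- lapply(foci, function(f) {
    f@active[f@active[, 2] > duration, 2] <- duration
    f@active <- f@active[f@active[, 1] < duration, , drop = FALSE]
    f
  })
  new("SceneScript", duration = duration, fps = fps, screen = screen,
      foci = foci, segments = segments)
}

#' Construct an observer profile
#'
#' @param state a single state ("attentive", "wandering", "off_screen"), or a
#'   function of time (seconds, vectorized) returning
#'   `list(state = character, focus = integer)`.
#' @param focus focus index tracked while attentive (ignored for the function
#'   form).
#' @param fixationNoiseSd fixation scatter, pixels (default 15).
#' @param blinkRate blinks per minute (default 12, a typical relaxed-viewing
#'   rate).
#' @param blinkDurMean,blinkDurSd blink duration, ms (default 150 / 40).
#' @param saccadeLag gaze-following latency, ms (default 0).
#' @param wanderStepSd random-walk step sd, pixels per sample (default 25,
#'   calibrated to a 500 Hz stream).
#' @return an [ObserverProfile-class].
#' @export
observerProfile <- function(state = "attentive", focus = 1L,
                            fixationNoiseSd = 15, blinkRate = 12,
                            blinkDurMean = 150, blinkDurSd = 40,
                            saccadeLag = 0, wanderStepSd = 25) {
  if (is.character(state)) {
    st <- match.arg(state, c("attentive", "wandering", "off_screen"))
    fx <- as.integer(focus)
    stateFun <- function(t) list(state = rep(st, length(t)),
                                 focus = rep(if (st == "attentive") fx else NA_integer_,
                                             length(t)))
  } else stateFun <- state
  new("ObserverProfile", stateFun = stateFun,
      fixationNoiseSd = fixationNoiseSd, blinkRate = blinkRate,
      blinkDurMean = blinkDurMean, blinkDurSd = blinkDurSd,
      saccadeLag = saccadeLag, wanderStepSd = wanderStepSd)
}

# number of active foci at times tt, and activity matrix
fociActive <- function(scene, tt) {
  act <- vapply(scene@foci, function(f)
    inAnyInterval(tt, f@active[, 1], f@active[, 2]), logical(length(tt)))
  if (length(tt) == 1L) act <- matrix(act, nrow = 1)
  act
}

#' Simulate a multi-observer gaze session
#'
#' Generates one raw gaze recording per observer. Attentive samples scatter
#' (Gaussian, sd `fixationNoiseSd`) around the assigned focus position,
#' clipped to the screen; wandering samples follow a reflecting Gaussian
#' random walk; off-screen states park the gaze outside the screen bounds.
#' Blinks arrive as a Poisson process and appear as runs of zero pupil with a
#' vertical gaze distortion at their edges (the eyelid artifact that the
#' 60 ms padding rule is meant to absorb).
#'
#' @param scene a [SceneScript-class].
#' @param observers list of [ObserverProfile-class] objects.
#' @param samplingRate Hz; must be at least twice the scene fps (default 500).
#' @param seed integer seed; identical inputs and seed give identical output.
#' @return list with `recordings` (list of [GazeRecording-class]) and
#'   `truth` (a [GroundTruth-class]).
#' @export
simulateGazeSession <- function(scene, observers, samplingRate = 500, seed) {
  stopifnot(is(scene, "SceneScript"))
  if (scene@duration <= 0 || samplingRate <= 0)
    stop("duration and sampling rate must be positive")
  if (samplingRate < 2 * scene@fps)
    stop("samplingRate must be at least twice the scene fps")
  if (length(observers) < 1L) stop("at least one observer is required")
  withSeed(seed, {
    n <- round(scene@duration * samplingRate)
    tt <- (seq_len(n) - 1L) / samplingRate        # seconds
    t_ms <- tt * 1000
    w <- scene@screen[1]; h <- scene@screen[2]
    nFrames <- round(scene@duration * scene@fps)
    frameCenters <- (seq_len(nFrames) - 0.5) / scene@fps
    activeAtCenters <- fociActive(scene, frameCenters)
    focusCount <- as.integer(rowSums(activeAtCenters))

    nameFor <- function(i) sprintf("S%03d", i)
    recs <- vector("list", length(observers))
    stateMat <- matrix(NA_character_, nFrames, length(observers),
                       dimnames = list(NULL, vapply(seq_along(observers),
                                                    nameFor, character(1))))
    attFrac <- numeric(length(observers))
    blinkLog <- vector("list", length(observers))

    for (oi in seq_along(observers)) {
      ob <- observers[[oi]]
      st <- ob@stateFun(tt)
      state <- st$state; focus <- st$focus
      if (!all(state %in% c("attentive", "wandering", "off_screen")))
        stop("observer state must be attentive, wandering or off_screen")

      x <- numeric(n); y <- numeric(n)

      # attentive: track the assigned focus (with saccade lag), add scatter
      ia <- which(state == "attentive")
      if (length(ia)) {
        fi <- focus[ia]
        if (anyNA(fi)) stop("attentive state without a focus index")
        tl <- pmax(tt[ia] - ob@saccadeLag / 1000, 0)
        for (f in sort(unique(fi))) {
          if (f < 1L || f > length(scene@foci))
            stop("observer state references focus ", f,
                 " but the scene has ", length(scene@foci), " foci")
          sel <- fi == f
          tf <- tl[sel]
          ft <- scene@foci[[f]]
          if (!all(inAnyInterval(tt[ia][sel], ft@active[, 1], ft@active[, 2])))
            stop("observer state references focus ", f,
                 " outside its active intervals")
          p <- ft@path(tf)
          x[ia[sel]] <- p[, 1]; y[ia[sel]] <- p[, 2]
        }
        if (ob@fixationNoiseSd > 0) {
          x[ia] <- x[ia] + rnorm(length(ia), 0, ob@fixationNoiseSd)
          y[ia] <- y[ia] + rnorm(length(ia), 0, ob@fixationNoiseSd)
        }
        # a fixating eye stays on the screen: clip scatter to the bounds
        eps <- 1e-6
        x[ia] <- pmin(pmax(x[ia], 0), w - eps)
        y[ia] <- pmin(pmax(y[ia], 0), h - eps)
      }

      # wandering: one continuous reflecting random walk for the session
      iw <- which(state == "wandering")
      if (length(iw)) {
        steps_x <- rnorm(n, 0, ob@wanderStepSd)
        steps_y <- rnorm(n, 0, ob@wanderStepSd)
        wx <- reflectWalk(runif(1, 0, w) + cumsum(steps_x), w)
        wy <- reflectWalk(runif(1, 0, h) + cumsum(steps_y), h)
        x[iw] <- wx[iw]; y[iw] <- wy[iw]
      }

      # off-screen: park outside the half-open screen ranges
      io <- which(state == "off_screen")
      if (length(io)) {
        x[io] <- -60 + rnorm(length(io), 0, 5)
        y[io] <- -60 + rnorm(length(io), 0, 5)
        x[io] <- pmin(x[io], -1); y[io] <- pmin(y[io], -1)
      }

      # pupil: slow drift around 1000 a.u.
      pupil <- 1000 + 30 * sin(2 * pi * tt / 60) + rnorm(n, 0, 5)

      # blinks: Poisson arrivals, truncated-normal durations
      nb <- rpois(1, ob@blinkRate * scene@duration / 60)
      bl <- data.frame(onset = numeric(0), offset = numeric(0))
      if (nb > 0) {
        onset <- sort(runif(nb, 0, scene@duration * 1000))
        dur <- pmax(rnorm(nb, ob@blinkDurMean, ob@blinkDurSd), 20)
        bl <- mergeIntervals(onset, pmin(onset + dur,
                                         scene@duration * 1000))
        core <- inAnyInterval(t_ms, bl$onset, bl$offset)
        pupil[core] <- 0
        x[core] <- NA_real_; y[core] <- NA_real_
        # eyelid artifact: downward shift just before, upward just after
        pre <- inAnyInterval(t_ms, bl$onset - 30, bl$onset) & !core
        post <- inAnyInterval(t_ms, bl$offset, bl$offset + 30) & !core
        y[pre] <- y[pre] + 120
        y[post] <- y[post] - 120
      }
      blinkLog[[oi]] <- bl

      valid <- !is.na(x) & !is.na(y)
      recs[[oi]] <- new("GazeRecording", subject = nameFor(oi),
                        rate = samplingRate, t = t_ms, x = x, y = y,
                        pupil = pupil, valid = valid)

      stateAtCenters <- ob@stateFun(frameCenters)$state
      stateMat[, oi] <- stateAtCenters
      attFrac[oi] <- mean(stateAtCenters == "attentive")
    }

    truth <- new("GroundTruth", stateMatrix = stateMat,
                 focusCount = focusCount, attentionFraction = attFrac,
                 blinkLog = blinkLog)
    list(recordings = recs, truth = truth)
  })
}

# reflect an unbounded walk into [0, limit)
reflectWalk <- function(p, limit) {
  m <- p %% (2 * limit)
  out <- ifelse(m < limit, m, 2 * limit - m)
  pmin(out, limit - 1e-6)
}

#' Simulate a multi-subject EEG-like session with a planted shared component
#'
#' Each subject's channels-by-time matrix is a fixed random mixing of one
#' shared band-limited time course — scaled per subject by a state-dependent
#' signal-to-noise ratio — plus independent unit-variance channel noise. The
#' planted component is returned so recovery can be scored against truth.
#'
#' @param nSubjects number of subjects.
#' @param nChannels number of channels (>= 2).
#' @param duration seconds.
#' @param rate Hz.
#' @param snrByState named non-negative SNR per state, e.g.
#'   `c(attentive = 2, wandering = 0.1)`; `Inf` means zero noise.
#' @param states per-subject state labels (recycled); default all attentive.
#' @param seed integer seed.
#' @return list with `data` (list of channels x samples matrices),
#'   `component` (the planted shared time course), `mixing` (channel mixing
#'   vector), `snr` (per-subject values), `states`.
#' @export
simulateEEGSession <- function(nSubjects, nChannels, duration, rate,
                               snrByState = c(attentive = 2),
                               states = "attentive", seed) {
  if (nChannels < 2L) stop("at least two channels are required")
  if (rate <= 0 || duration <= 0) stop("rate and duration must be positive")
  if (any(snrByState < 0)) stop("SNR values must be non-negative")
  states <- rep_len(states, nSubjects)
  if (!all(states %in% names(snrByState)))
    stop("every state needs an entry in snrByState")
  withSeed(seed, {
    n <- round(duration * rate)
    # band-limited shared source: smoothed white noise, unit variance
    src <- stats::filter(rnorm(n + 200), rep(1 / 25, 25), sides = 2)
    src <- src[101:(100 + n)]
    src <- (src - mean(src)) / sd(src)
    mixing <- rnorm(nChannels)
    mixing <- mixing / sqrt(sum(mixing^2))
    snr <- unname(snrByState[states])
    data <- vector("list", nSubjects)
    for (i in seq_len(nSubjects)) {
      noise <- matrix(rnorm(nChannels * n), nChannels, n)
      if (is.infinite(snr[i])) {
        data[[i]] <- outer(mixing, src)
      } else {
        data[[i]] <- snr[i] * outer(mixing, src) + noise
      }
    }
    list(data = data, component = src, mixing = mixing, snr = snr,
         states = states)
  })
}

#' Simulate subject-level outcome scores from planted attention
#'
#' Post-knowledge and mental effort are linear in the z-scored true attention
#' fraction with slope `effectSize`, plus an optional prior-knowledge slope
#' and Gaussian noise. The generating coefficients are returned so fitted
#' standardized slopes can be compared to truth.
#'
#' @param truth a [GroundTruth-class] (only `attentionFraction` is used), or a
#'   numeric vector of attention fractions.
#' @param effectSize standardized slope of attention on both outcomes.
#' @param noiseSd residual sd in score units (>= 0).
#' @param priorSlope standardized slope of prior knowledge on post knowledge
#'   (default 0).
#' @param intercept outcome intercept (default 0).
#' @param seed integer seed.
#' @return data.frame (subject, attention, prior, post, effort) with the
#'   generating coefficients in `attr(, "coefficients")`.
#' @export
simulateOutcomes <- function(truth, effectSize, noiseSd, priorSlope = 0,
                             intercept = 0, seed) {
  if (!is.finite(effectSize)) stop("effectSize must be finite")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  att <- if (is(truth, "GroundTruth")) truth@attentionFraction else truth
  nsub <- length(att)
  withSeed(seed, {
    za <- zscoreSafe(att)
    prior <- rnorm(nsub)
    zp <- zscoreSafe(prior)
    post <- intercept + effectSize * za + priorSlope * zp +
      rnorm(nsub, 0, noiseSd)
    effort <- intercept + effectSize * za + rnorm(nsub, 0, noiseSd)
    out <- data.frame(subject = sprintf("S%03d", seq_len(nsub)),
                      attention = att, prior = prior, post = post,
                      effort = effort)
    attr(out, "coefficients") <- c(intercept = intercept,
                                   attention = effectSize,
                                   prior = priorSlope)
    out
  })
}

#' Synthetic period-of-interest annotation table
#'
#' Builds a content-segment table with the structure of an annotated
#' instructional video: five content categories, one of them the reference
#' category irrelevant to knowledge acquisition, chopped into short segments.
#' By default it mirrors the published annotation scale — 72 segments with
#' per-category totals of 92, 184, 238, 343 and 90 seconds over a 946.56 s
#' video. The table is synthetic: segment boundaries are an evenly
#' interleaved stand-in, not the real transcript.
#'
#' @param duration video duration in seconds.
#' @param counts named integer vector of segments per category.
#' @param totals named numeric vector of total seconds per category.
#' @return data.frame (start, end, label) sorted by start, non-overlapping.
#' @export
syntheticPOITable <- function(duration = 946.56,
                              counts = c(game_world_explained = 4,
                                         code_explained = 9,
                                         code_explanation_summarized = 23,
                                         code_typed_in = 21,
                                         code_executed = 15),
                              totals = c(game_world_explained = 92,
                                         code_explained = 184,
                                         code_explanation_summarized = 238,
                                         code_typed_in = 343,
                                         code_executed = 90)) {
  stopifnot(identical(names(counts), names(totals)))
  labels <- rep(names(counts), counts)
  # deterministic interleave so alike categories are spread over the video
  ord <- order(unlist(lapply(counts, function(k) seq_len(k) / (k + 1))))
  labels <- labels[ord]
  lens <- unlist(lapply(names(counts),
                        function(l) rep(totals[[l]] / counts[[l]], counts[[l]])))
  lens <- lens[ord]
  tot <- sum(lens)
  if (tot > duration) lens <- lens * duration / tot
  gap <- (duration - sum(lens)) / length(lens)
  start <- cumsum(c(0, lens[-length(lens)] + gap))
  data.frame(start = start, end = start + lens, label = labels)
}

#' Simulate a long GCM table from a known mixed model
#'
#' Draws smoothed-GCM rows directly from a random-intercept linear model on
#' the second grid, for parameter-recovery and type-I-error studies of
#' [fitLMMRandomIntercept()]. Residuals are independent across rows.
#'
#' @param nSubjects number of subjects.
#' @param duration seconds covered by the POI table / grid.
#' @param beta named fixed-effect vector on the standardized scale; names must
#'   match the model terms of [fitLMMRandomIntercept()] (missing terms are 0).
#' @param sigmaIntercept sd of the subject random intercept.
#' @param sigmaResid residual sd.
#' @param poi POI table; default [syntheticPOITable()] rescaled to `duration`.
#' @param seed integer seed.
#' @return list with `long` (the row table), `beta` (full generating vector),
#'   and `subjects` (per-subject covariates).
#' @export
simulateGCMLong <- function(nSubjects, duration, beta = c(),
                            sigmaIntercept = 0.5, sigmaResid = 1,
                            poi = NULL, seed) {
  if (is.null(poi)) {
    poi <- syntheticPOITable()
    poi$start <- poi$start * duration / 946.56
    poi$end <- poi$end * duration / 946.56
  }
  withSeed(seed, {
    subj <- data.frame(subject = sprintf("S%03d", seq_len(nSubjects)),
                       prior = rnorm(nSubjects), post = rnorm(nSubjects))
    grid <- 0:(floor(duration) - 1)
    lab <- poiLabelAt(grid, poi)
    keep <- !is.na(lab)
    g <- grid[keep]; lab <- lab[keep]
    long <- data.frame(
      subject = rep(subj$subject, each = length(g)),
      t = rep(g, nSubjects),
      poi = factor(rep(lab, nSubjects), levels = poiLevels(poi)),
      prior = rep(subj$prior, each = length(g)),
      post = rep(subj$post, each = length(g)))
    X <- lmmDesign(long)
    b <- setNames(numeric(ncol(X)), colnames(X))
    unknown <- setdiff(names(beta), names(b))
    if (length(unknown)) stop("unknown beta terms: ",
                              paste(unknown, collapse = ", "))
    b[names(beta)] <- beta
    u <- rnorm(nSubjects, 0, sigmaIntercept)
    long$gcm <- as.vector(X %*% b) + u[match(long$subject, subj$subject)] +
      rnorm(nrow(long), 0, sigmaResid)
    list(long = long, beta = b, subjects = subj)
  })
}
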