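# Gaze cluster membership: per-frame DBSCAN with adaptive parameters.
#
# The two DBSCAN parameters are chosen per frame from the data available in
# that frame: the minimum cluster size is 5% of the subjects with a valid
# position (but at least 4), and the neighborhood radius is read off the
# k-nearest-neighbor distance curve as the first value exceeding one
# standard deviation above its mean.

#' Minimum cluster size for a frame
#'
#' `max(4, ceiling(0.05 * nValid))`: five percent of the available data
#' points, but never fewer than four.
#'
#' @param nValid number of subjects with a valid gaze position in the frame.
#' @param floorPts minimum allowed value (default 4).
#' @param fraction fraction of available points (default 0.05).
#' @return integer minimum cluster size.
#' @export
selectMinPts <- function(nValid, floorPts = 4L, fraction = 0.05) {
  if (nValid < 0) stop("nValid must be >= 0")
  as.integer(max(floorPts, ceiling(fraction * nValid)))
}

#' Adaptive DBSCAN radius from the k-distance curve
#'
#' Computes every point's Euclidean distance to its k-th nearest neighbor
#' (excluding itself), sorts the distances ascending, and returns the first
#' one strictly above an outlier threshold for the k-distance set — the
#' first value that stands one clear deviation beyond the bulk of the curve.
#'
#' Two threshold estimators are provided. `"robust"` (the default) puts the
#' cutoff at `median + 2.5 * mad`, the conventional robust outlier fence;
#' because median and MAD ignore the scattered tail, the radius stays on the
#' scale of the coherent fixation clouds even when a sizable minority of
#' viewers scatter across the screen. `"classic"` uses `mean + 1 * sd`;
#' moment estimates are themselves inflated by scattered viewers, which
#' pushes the radius toward outlier-scale distances and attaches wandering
#' gaze to clusters (kept for comparison).
#'
#' If no k-distance exceeds the threshold (a homogeneous curve, e.g. a
#' single fixation cloud), the maximum k-distance is returned so the cloud
#' stays whole; if that is still zero (all points coincident), the smallest
#' positive representable distance is used so a downstream DBSCAN still
#' forms one cluster.
#'
#' @param points two-column matrix of (x, y) pixel positions.
#' @param k neighbor rank of the k-distance curve.
#' @param method threshold estimator, `"robust"` or `"classic"`.
#' @param distMatrix optional precomputed Euclidean distance matrix.
#' @return epsilon in pixels, with the k-distance diagnostics in
#'   `attr(, "kdist")` and the threshold in `attr(, "threshold")`.
#' @export
selectEpsilon <- function(points, k, method = c("robust", "classic"),
                          distMatrix = NULL) {
  method <- match.arg(method)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= k) stop("need more points than k")
  d <- distMatrix %||% as.matrix(stats::dist(points))
  # k-th nearest neighbor distance per point; row position 1 is self (0)
  kd <- numeric(n)
  for (i in seq_len(n))
    kd[i] <- sort.int(d[, i], partial = k + 1L)[k + 1L]
  thr <- if (method == "robust") stats::median(kd) + 2.5 * mad(kd)
         else mean(kd) + sd(kd)
  kds <- sort.int(kd, method = "quick")
  above <- kds[kds > thr]
  eps <- if (length(above)) above[1] else max(kd)
  if (eps == 0) eps <- .Machine$double.xmin
  structure(eps, kdist = kds, threshold = thr)
}

#' Deterministic DBSCAN labelling
#'
#' Classical density-based clustering: a point is a core point when its
#' epsilon-neighborhood (Euclidean distance <= eps, the point itself
#' included) holds at least `minPts` points; clusters are maximal sets of
#' density-connected points; non-core points within eps of a core point join
#' that core's cluster; everything else is noise. Clusters are grown from
#' unvisited core points in ascending index order, so a border point within
#' reach of several clusters joins the one expanded first, and the labelling
#' is deterministic. Final ids are canonicalized: clusters are numbered 1..C
#' by their smallest member index.
#'
#' @param points two-column matrix of (x, y) positions.
#' @param eps neighborhood radius (> 0).
#' @param minPts minimum neighborhood size for a core point (>= 1).
#' @param distMatrix optional precomputed Euclidean distance matrix.
#' @return integer labels per point: 0 = noise, k >= 1 = cluster id.
#' @export
dbscanLabels <- function(points, eps, minPts, distMatrix = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  if (eps <= 0) stop("eps must be positive")
  if (minPts < 1L) stop("minPts must be >= 1")
  d <- distMatrix %||% as.matrix(stats::dist(points))
  nb <- d <= eps
  core <- rowSums(nb) >= minPts
  labels <- integer(n)                    # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      reach <- which(nb[p, ])
      for (q in reach) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  canonicalizeLabels(labels)
}

# renumber cluster ids 1..C by the smallest member index
canonicalizeLabels <- function(labels) {
  ids <- setdiff(unique(labels), 0L)
  if (length(ids) == 0L) return(labels)
  firsts <- vapply(ids, function(k) min(which(labels == k)), integer(1))
  remap <- integer(max(ids))
  remap[ids[order(firsts)]] <- seq_along(ids)
  pos <- labels != 0L
  labels[pos] <- remap[labels[pos]]
  labels
}

#' Cluster one frame of the gaze matrix
#'
#' Chooses `minPts` with [selectMinPts()], sets the k-distance rank `k` equal
#' to `minPts`, chooses epsilon with [selectEpsilon()], and runs
#' [dbscanLabels()]. Subjects without a valid position get NA; when the
#' number of valid subjects is not larger than k, no density estimate is
#' possible and all valid subjects are labelled noise.
#'
#' @param x,y numeric vectors of one frame's per-subject positions (NA =
#'   missing).
#' @param floorPts,fraction passed to [selectMinPts()].
#' @param epsilonMethod threshold estimator for [selectEpsilon()].
#' @return list with `labels` (NA / 0 / cluster id per subject), `n_valid`,
#'   `min_pts`, `epsilon` (NA when skipped) and `n_clusters`.
#' @export
clusterFrame <- function(x, y, floorPts = 4L, fraction = 0.05,
                         epsilonMethod = "robust") {
  ok <- !is.na(x) & !is.na(y)
  nValid <- sum(ok)
  labels <- rep(NA_integer_, length(x))
  minPts <- selectMinPts(nValid, floorPts, fraction)
  if (nValid == 0L)
    return(list(labels = labels, n_valid = 0L, min_pts = minPts,
                epsilon = NA_real_, n_clusters = 0L))
  if (nValid <= minPts) {
    labels[ok] <- 0L
    return(list(labels = labels, n_valid = nValid, min_pts = minPts,
                epsilon = NA_real_, n_clusters = 0L))
  }
  pts <- cbind(x[ok], y[ok])
  d <- as.matrix(stats::dist(pts))
  eps <- selectEpsilon(pts, k = minPts, method = epsilonMethod,
                       distMatrix = d)
  lab <- dbscanLabels(pts, eps = as.numeric(eps), minPts = minPts,
                      distMatrix = d)
  labels[ok] <- lab
  list(labels = labels, n_valid = nValid, min_pts = minPts,
       epsilon = as.numeric(eps), n_clusters = max(lab, 0L))
}

#' Cluster every frame of a FrameGazeMatrix
#'
#' @param fgm a [FrameGazeMatrix-class].
#' @param floorPts,fraction passed to [selectMinPts()].
#' @param epsilonMethod threshold estimator for [selectEpsilon()].
#' @return a [GazeClustering-class].
#' @export
clusterFrames <- function(fgm, floorPts = 4L, fraction = 0.05,
                          epsilonMethod = "robust") {
  stopifnot(is(fgm, "FrameGazeMatrix"))
  X <- SummarizedExperiment::assay(fgm, "x")
  Y <- SummarizedExperiment::assay(fgm, "y")
  nFrames <- nrow(X); nsub <- ncol(X)
  labels <- matrix(NA_integer_, nFrames, nsub, dimnames = dimnames(X))
  nv <- integer(nFrames); mp <- integer(nFrames)
  ep <- rep(NA_real_, nFrames); nc <- integer(nFrames)
  for (i in seq_len(nFrames)) {
    fc <- clusterFrame(X[i, ], Y[i, ], floorPts, fraction, epsilonMethod)
    labels[i, ] <- fc$labels
    nv[i] <- fc$n_valid; mp[i] <- fc$min_pts
    ep[i] <- fc$epsilon; nc[i] <- fc$n_clusters
  }
  new("GazeClustering", labels = labels,
      params = data.frame(frame = seq_len(nFrames) - 1L, n_valid = nv,
                          min_pts = mp, epsilon = ep, n_clusters = nc),
      fps = videoFps(fgm), duration = videoDuration(fgm))
}

#' Attention series from a frame clustering
#'
#' Per frame, a subject's membership is 1 when its label is a cluster id, 0
#' when it is noise, and missing when the subject had no valid position. The
#' GCM summary is the fraction of non-missing frames spent inside a cluster
#' (subjects with no non-missing frame get NA). The per-frame cluster count
#' and the per-subject membership are smoothed onto a one-second grid with
#' [smoothSeries()].
#'
#' @param clustering a [GazeClustering-class].
#' @param window,step smoothing window and step, seconds (defaults 5 and 1).
#' @return an [AttentionSeries-class].
#' @export
computeAttentionSeries <- function(clustering, window = 5, step = 1) {
  stopifnot(is(clustering, "GazeClustering"))
  lab <- clustering@labels
  memb <- ifelse(is.na(lab), NA_integer_, as.integer(lab >= 1L))
  gcmv <- colMeans(memb, na.rm = TRUE)
  gcmv[is.nan(gcmv)] <- NA_real_
  cc <- as.integer(clustering@params$n_clusters)
  dur <- clustering@duration; fps <- clustering@fps
  grid <- seq(0, by = step, length.out = floor(dur / step))
  sm <- apply(memb, 2L, smoothSeries, fps = fps, duration = dur,
              window = window, step = step)
  if (is.null(dim(sm))) sm <- matrix(sm, nrow = length(grid))
  colnames(sm) <- colnames(memb)
  scc <- smoothSeries(cc, fps = fps, duration = dur, window = window,
                      step = step)
  new("AttentionSeries", membership = memb, gcm = gcmv,
      clusterCount = cc, grid = grid, smoothedGCM = sm,
      smoothedClusterCount = scc)
}

#' Moving-window average of a per-frame series onto a one-second grid
#'
#' The value at grid second g is the mean of the non-missing frame values
#' whose frame centers fall in the half-open window
#' `[g - window/2, g + window/2)`; windows are truncated at the edges of the
#' series and a window without values yields NA.
#'
#' @param values one value per frame (NA allowed).
#' @param fps frames per second.
#' @param duration series duration in seconds; the grid is
#'   `0, step, ..., floor(duration/step) - 1` steps.
#' @param window window width, seconds (default 5).
#' @param step grid step, seconds (default 1).
#' @return numeric vector over the grid.
#' @export
smoothSeries <- function(values, fps, duration, window = 5, step = 1) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  n <- length(values)
  grid <- seq(0, by = step, length.out = floor(duration / step))
  # frame i (1-based) has center (i - 0.5)/fps, so
  #   center >= g - w/2  <=>  i >= (g - w/2) * fps + 0.5   and
  #   center <  g + w/2  <=>  i <  (g + w/2) * fps + 0.5;
  # windows are contiguous index ranges, so running sums give the means
  lo <- pmax(ceiling((grid - window / 2) * fps + 0.5), 1)
  hi <- pmin(ceiling((grid + window / 2) * fps + 0.5) - 1, n)
  cs <- cumsum(ifelse(is.na(values), 0, values))
  cn <- cumsum(!is.na(values))
  out <- rep(NA_real_, length(grid))
  ok <- hi >= lo & hi >= 1
  below <- pmax(lo[ok] - 1, 1)           # never index with 0
  hasPrev <- lo[ok] > 1
  s <- cs[hi[ok]] - ifelse(hasPrev, cs[below], 0)
  k <- cn[hi[ok]] - ifelse(hasPrev, cn[below], 0)
  out[ok] <- ifelse(k > 0, s / k, NA_real_)
  out
}
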