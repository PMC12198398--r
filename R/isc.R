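# Inter-subject correlation via correlated component analysis.
#
# CorrCA finds channel-weight vectors w maximizing the ratio of pooled
# between-subject to pooled within-subject covariance,
# (w' Rb w) / (w' Rw w), through the generalized eigenproblem
# Rb w = lambda Rw w. Component 1 carries the highest inter-subject
# correlation; a leave-one-out time-resolved ISC course is provided on the
# same one-second grid as the smoothed gaze-cluster-membership series.

# normalize a subject stack to a list of channels x samples matrices
asSubjectStack <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[1]),
                    function(i) matrix(stack[i, , ], dim(stack)[2]))
  stopifnot(is.list(stack), length(stack) >= 1L)
  d <- dim(stack[[1]])
  for (m in stack)
    if (!identical(dim(m), d))
      stop("all subjects must share channel and sample counts")
  if (any(vapply(stack, anyNA, logical(1))))
    stop("subject stack must not contain missing values; interpolate first")
  stack
}

#' Fit a correlated component analysis model
#'
#' The pooled within-subject covariance Rw is the mean of the per-subject
#' channel covariances (each subject mean-centered, denominator n - 1); the
#' pooled between-subject covariance Rb is the mean cross-covariance over
#' ordered subject pairs, symmetrized. Components solve the generalized
#' eigenproblem Rb w = lambda Rw w, with diagonal loading
#' `gamma * trace(Rw)/channels` added to Rw for rank safety. Per-component
#' ISC is `(w' Rb w) / (w' Rw w)` with the unloaded Rw.
#'
#' @param stack list of channels x samples matrices (one per subject), or a
#'   subjects x channels x samples array; no missing values.
#' @param gamma diagonal-loading factor (default 1e-6).
#' @return a [CorrCAModel-class].
#' @export
corrcaFit <- function(stack, gamma = 1e-6) {
  stack <- asSubjectStack(stack)
  nsub <- length(stack)
  if (nsub < 2L) stop("at least two subjects are required")
  D <- nrow(stack[[1]]); n <- ncol(stack[[1]])
  if (n <= D) stop("more samples than channels are required")

  centered <- lapply(stack, function(m) m - rowMeans(m))
  Rw <- matrix(0, D, D)
  Ssum <- matrix(0, D, n)
  Cwsum <- matrix(0, D, D)
  for (m in centered) {
    Ci <- tcrossprod(m) / (n - 1)
    Rw <- Rw + Ci
    Cwsum <- Cwsum + Ci
    Ssum <- Ssum + m
  }
  Rw <- Rw / nsub
  # sum over ordered pairs i != j of cross-covariances, via the pooled sum
  Rb <- (tcrossprod(Ssum) / (n - 1) - Cwsum) / (nsub * (nsub - 1))
  Rb <- (Rb + t(Rb)) / 2

  load <- gamma * sum(diag(Rw)) / D
  Rwl <- Rw + diag(load, D)
  ew <- eigen(Rwl, symmetric = TRUE)
  if (any(ew$values <= 0)) {
    flat <- which(diag(Rw) <= .Machine$double.eps * max(diag(Rw)))
    stop("within-subject covariance is rank deficient; offending channels: ",
         paste(flat, collapse = ", "))
  }
  Wh <- ew$vectors %*% diag(1 / sqrt(ew$values), D) %*% t(ew$vectors)
  M <- Wh %*% Rb %*% Wh
  M <- (M + t(M)) / 2
  eb <- eigen(M, symmetric = TRUE)
  W <- Wh %*% eb$vectors
  # canonical form: unit norm, largest-magnitude entry positive
  for (j in seq_len(ncol(W))) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  isc <- vapply(seq_len(ncol(W)), function(j) {
    w <- W[, j]
    as.numeric((w %*% Rb %*% w) / (w %*% Rw %*% w))
  }, numeric(1))
  o <- order(isc, decreasing = TRUE)
  new("CorrCAModel", Rb = Rb, Rw = Rw, W = W[, o, drop = FALSE],
      isc = isc[o])
}

#' Project subjects onto a CorrCA component
#'
#' @param stack subject stack as in [corrcaFit()].
#' @param model a [CorrCAModel-class].
#' @param component component index (default 1).
#' @return matrix subjects x samples of component projections.
#' @export
corrcaProject <- function(stack, model, component = 1L) {
  stack <- asSubjectStack(stack)
  w <- model@W[, component]
  if (length(w) != nrow(stack[[1]]))
    stop("model was fitted on a different channel space")
  t(vapply(stack, function(m) as.numeric(w %*% m), numeric(ncol(stack[[1]]))))
}

#' Time-resolved inter-subject correlation of the first component
#'
#' Subjects are projected onto the first component; for every second of a
#' one-second grid, each subject's projection within the centered
#' `[g - window/2, g + window/2)` window is correlated (Pearson) with the
#' mean projection of all other subjects, and the window's value is the mean
#' over subjects. The window grid matches [smoothSeries()] exactly. Subjects
#' with zero variance in a window are omitted from that window's mean.
#'
#' @param stack subject stack as in [corrcaFit()].
#' @param model a [CorrCAModel-class] fitted on the same channels.
#' @param rate sampling rate of the stack, Hz.
#' @param duration series duration, seconds (default inferred from samples).
#' @param window,step window and step in seconds (defaults 5 and 1).
#' @return numeric ISC value per grid second.
#' @export
iscTimecourse <- function(stack, model, rate, duration = NULL,
                          window = 5, step = 1) {
  stack <- asSubjectStack(stack)
  P <- corrcaProject(stack, model)
  nsub <- nrow(P); n <- ncol(P)
  if (is.null(duration)) duration <- n / rate
  centers <- (seq_len(n) - 0.5) / rate
  grid <- seq(0, by = step, length.out = floor(duration / step))
  tot <- colSums(P)
  out <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    g <- grid[i]
    sel <- centers >= g - window / 2 & centers < g + window / 2
    if (sum(sel) < 3L) next
    rs <- numeric(0)
    for (s in seq_len(nsub)) {
      own <- P[s, sel]
      others <- (tot[sel] - own) / (nsub - 1)
      if (sd(own) == 0 || sd(others) == 0) next
      rs <- c(rs, cor(own, others))
    }
    if (length(rs)) out[i] <- mean(rs)
  }
  out
}

#' Overall leave-one-out ISC of the first component
#'
#' Pearson correlation between each subject's component projection and the
#' mean projection of all other subjects, averaged over subjects, on the full
#' analysis span.
#'
#' @inheritParams iscTimecourse
#' @return single numeric ISC value.
#' @export
iscSummary <- function(stack, model) {
  stack <- asSubjectStack(stack)
  P <- corrcaProject(stack, model)
  nsub <- nrow(P)
  tot <- colSums(P)
  rs <- vapply(seq_len(nsub), function(s) {
    own <- P[s, ]
    others <- (tot - own) / (nsub - 1)
    if (sd(own) == 0 || sd(others) == 0) return(NA_real_)
    cor(own, others)
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Build a gaze subject stack from an interpolated frame matrix
#'
#' Stacks each subject's per-frame (x, y) positions as a two-channel signal
#' for gaze ISC. The frame matrix must be complete (aggregate interpolated
#' recordings, or interpolate remaining frame gaps), since CorrCA cannot
#' handle missing data.
#'
#' @param fgm a [FrameGazeMatrix-class] without missing cells.
#' @return list of 2 x frames matrices, one per subject.
#' @export
gazeStack <- function(fgm) {
  X <- SummarizedExperiment::assay(fgm, "x")
  Y <- SummarizedExperiment::assay(fgm, "y")
  if (anyNA(X) || anyNA(Y))
    stop("frame matrix has missing cells; interpolate recordings first")
  lapply(seq_len(ncol(X)), function(j) rbind(x = X[, j], y = Y[, j]))
}
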