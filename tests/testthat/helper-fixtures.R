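# Shared fixtures: scene builders and an independent DBSCAN oracle.

# Brute-force density-connectivity oracle. Independent of the package's
# implementation: core points by neighborhood count, reachability closure
# among core points by Warshall iteration, border points assigned to the
# cluster (among those with a core neighbor) whose smallest core index is
# smallest, ids canonicalized by smallest member index.
oracleDBSCAN <- function(pts, eps, minPts) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(pts))
  nb <- d <= eps
  core <- rowSums(nb) >= minPts
  lab <- integer(n)
  if (any(core)) {
    R <- nb
    R[!core, ] <- FALSE
    R[, !core] <- FALSE
    diag(R) <- core
    for (k in which(core)) R <- R | outer(R[, k], R[k, ], "&")
    comp <- integer(n)
    cid <- 0L
    for (i in which(core)) {
      if (comp[i] == 0L) {
        cid <- cid + 1L
        comp[which(R[i, ])] <- cid
      }
    }
    lab[core] <- comp[core]
    for (j in which(!core)) {
      cand <- comp[core & nb[j, ]]
      if (length(cand)) lab[j] <- min(cand)
    }
  }
  # canonical ids by smallest member index (renumber via positive positions
  # only; zero indices would silently shrink the subscripted vector)
  ids <- setdiff(unique(lab), 0L)
  if (length(ids)) {
    firsts <- vapply(ids, function(k) min(which(lab == k)), integer(1))
    remap <- integer(max(ids))
    remap[ids[order(firsts)]] <- seq_along(ids)
    pos <- lab != 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

# scene with two foci 400 px apart on a 1680x1050 screen; moving foci give
# attentive gaze a correlated time course for ISC comparisons
twoFociScene <- function(duration = 60, fps = 25, moving = TRUE) {
  if (moving) {
    f1 <- orbitingFocus(c(640, 525), radius = 120, period = 23)
    f2 <- orbitingFocus(c(1040, 525), radius = 120, period = 31, phase = 1.7)
  } else {
    f1 <- focusTrack(c(640, 525))
    f2 <- focusTrack(c(1040, 525))
  }
  sceneScript(duration, fps, c(1680, 1050), list(f1, f2))
}

# observer panel: nA attentive alternating over the scene's foci, nW wanderers
mixedObservers <- function(nA, nW, nFoci = 2, noiseSd = 15, blinkRate = 12) {
  c(lapply(seq_len(nA), function(i)
      observerProfile("attentive", focus = ((i - 1L) %% nFoci) + 1L,
                      fixationNoiseSd = noiseSd, blinkRate = blinkRate)),
    lapply(seq_len(nW), function(i)
      observerProfile("wandering", blinkRate = blinkRate)))
}

# quick AttentionSeries wrapper around a precomputed smoothed-GCM matrix,
# for tests of the long-table builder that need no clustering run
seriesFromSmoothed <- function(sm, grid = seq_len(nrow(sm)) - 1) {
  memb <- matrix(1L, 2, ncol(sm), dimnames = list(NULL, colnames(sm)))
  new("AttentionSeries", membership = memb,
      gcm = rep(1, ncol(sm)), clusterCount = c(1L, 1L),
      grid = as.numeric(grid), smoothedGCM = sm,
      smoothedClusterCount = rep(1, nrow(sm)))
}
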