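# Per-frame DBSCAN with adaptive parameters, GCM series, smoothing.

test_that("minimum cluster size is max(4, ceiling(5%))", {
  expect_identical(selectMinPts(40), 4L)
  expect_identical(selectMinPts(100), 5L)
  expect_identical(selectMinPts(105), 6L)   # ceiling(5.25)
  expect_identical(selectMinPts(0), 4L)
  expect_error(selectMinPts(-1), ">= 0")
})

test_that("epsilon is the first k-distance beyond the bulk threshold", {
  # hand-checkable line instance: 2nd-NN distances are {2,1,1,1,2,97}; both
  # threshold estimators leave only 97 above the cutoff
  pts <- cbind(c(0, 1, 2, 3, 4, 100), 0)
  kd <- c(2, 1, 1, 1, 2, 97)
  e <- selectEpsilon(pts, k = 2)
  expect_identical(sort(attr(e, "kdist")), sort(kd))
  expect_equal(attr(e, "threshold"), median(kd) + 2.5 * mad(kd))
  expect_equal(as.numeric(e), 97)
  ec <- selectEpsilon(pts, k = 2, method = "classic")
  expect_equal(attr(ec, "threshold"), mean(kd) + sd(kd))
  expect_equal(as.numeric(ec), 97)

  # zero variance in the k-distances: fall back to the maximum
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(as.numeric(selectEpsilon(sq, k = 1)), 1)

  # coincident points: smallest positive representable distance
  co <- matrix(5, 6, 2)
  expect_identical(as.numeric(selectEpsilon(co, k = 2)),
                   .Machine$double.xmin)
  expect_error(selectEpsilon(sq, k = 4), "more points than k")
})

test_that("epsilon separates two tight clouds in nearly all draws", {
  below <- 0L
  for (s in 1:100) {
    set.seed(s)
    pts <- rbind(cbind(rnorm(50, 400, 15), rnorm(50, 500, 15)),
                 cbind(rnorm(50, 800, 15), rnorm(50, 500, 15)))
    if (as.numeric(selectEpsilon(pts, k = 5)) < 400) below <- below + 1L
  }
  expect_gte(below, 95L)
})

test_that("dbscan handles the degenerate fixtures", {
  expect_identical(dbscanLabels(matrix(0, 10, 2),
                                eps = .Machine$double.xmin, minPts = 4),
                   rep(1L, 10))
  expect_identical(dbscanLabels(cbind(c(0, 1, 2), 0), eps = 5, minPts = 4),
                   rep(0L, 3))
  expect_identical(dbscanLabels(matrix(numeric(0), 0, 2), 1, 1), integer(0))
})

test_that("dbscan matches the brute-force density-connectivity oracle", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    pts <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    eps <- runif(1, 0.3, 4)
    minPts <- sample(1:6, 1)
    expect_identical(dbscanLabels(pts, eps, minPts),
                     oracleDBSCAN(pts, eps, minPts))
  }
})

test_that("dbscan labels are invariant to translation and rotation", {
  set.seed(5)
  pts <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  lab <- dbscanLabels(pts, eps = 1.5, minPts = 4)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% R, 2, c(-31.4, 12.7))
  expect_identical(dbscanLabels(moved, eps = 1.5, minPts = 4), lab)
})

test_that("clusters are built around genuine cores within reach", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    pts <- cbind(runif(n, 0, 8), runif(n, 0, 8))
    eps <- runif(1, 0.5, 3); minPts <- sample(2:6, 1)
    lab <- dbscanLabels(pts, eps, minPts)
    d <- as.matrix(dist(pts))
    core <- rowSums(d <= eps) >= minPts
    # how many clusters can reach each point through one of their cores
    nReach <- vapply(seq_len(n), function(j)
      length(unique(lab[core & d[j, ] <= eps & lab > 0L])), integer(1))
    for (k in setdiff(unique(lab), 0L)) {
      members <- which(lab == k)
      coreK <- members[core[members]]
      # every cluster owns at least one core, every member sits within
      # epsilon of one of its cluster's cores, and each core's neighborhood
      # meets the density requirement
      expect_gte(length(coreK), 1L)
      expect_true(all(apply(d[members, coreK, drop = FALSE], 1,
                            min) <= eps))
      expect_gte(sum(d[, coreK[1]] <= eps), minPts)
      # border points reachable from a single cluster guarantee the
      # minimum size; shared borders may be claimed by an earlier cluster
      if (all(nReach[members] == 1L))
        expect_gte(length(members), minPts)
    }
  }
})

test_that("growing epsilon never creates more noise points", {
  set.seed(23)
  for (i in 1:20) {
    pts <- cbind(runif(30, 0, 10), runif(30, 0, 10))
    minPts <- sample(2:5, 1)
    epss <- sort(runif(4, 0.2, 5))
    noise <- vapply(epss, function(e)
      sum(dbscanLabels(pts, e, minPts) == 0L), integer(1))
    expect_true(all(diff(noise) <= 0))
  }
})

test_that("frame clustering handles missing subjects and small frames", {
  allMissing <- clusterFrame(rep(NA_real_, 10), rep(NA_real_, 10))
  expect_identical(allMissing$n_clusters, 0L)
  expect_true(all(is.na(allMissing$labels)))

  # n_valid <= k: everyone valid is noise
  few <- clusterFrame(c(1, 2, 3, NA), c(1, 2, 3, NA))
  expect_identical(few$labels, c(0L, 0L, 0L, NA))
  expect_identical(few$n_clusters, 0L)
  expect_true(is.na(few$epsilon))

  # one tight fixation cloud of 100 subjects: a single cluster holding
  # (almost) everyone; a homogeneous k-distance curve falls back to its
  # maximum, so only rare extreme scatter tails can drop out
  set.seed(31)
  x <- rnorm(100, 840, 3); y <- rnorm(100, 525, 3)
  one <- clusterFrame(x, y)
  expect_identical(one$n_clusters, 1L)
  expect_gte(sum(one$labels == 1L), 90L)
  expect_identical(one$min_pts, 5L)
})

test_that("cluster count and membership are subject-permutation invariant", {
  set.seed(41)
  x <- c(rnorm(30, 300, 10), rnorm(30, 900, 10), runif(10, 0, 1680))
  y <- c(rnorm(30, 300, 10), rnorm(30, 700, 10), runif(10, 0, 1050))
  a <- clusterFrame(x, y)
  perm <- sample(70)
  b <- clusterFrame(x[perm], y[perm])
  expect_identical(b$n_clusters, a$n_clusters)
  expect_identical(b$labels >= 1L, (a$labels >= 1L)[perm])
})

test_that("attention series counts membership and excludes missing frames", {
  lab <- matrix(NA_integer_, 100, 2)
  lab[, 1] <- 1L                          # always in a cluster
  lab[1:75, 2] <- 1L; lab[76:100, 2] <- 0L
  cl <- new("GazeClustering", labels = lab,
            params = data.frame(frame = 0:99, n_valid = 2L, min_pts = 4L,
                                epsilon = 1, n_clusters = 1L),
            fps = 25, duration = 4)
  s <- computeAttentionSeries(cl)
  expect_identical(gcm(s), c(1, 0.75))

  # missing frames drop out of numerator and denominator
  lab2 <- lab
  lab2[1:50, 2] <- NA_integer_
  cl2 <- new("GazeClustering", labels = lab2, params = cl@params,
             fps = 25, duration = 4)
  expect_equal(gcm(cl2 |> computeAttentionSeries())[2], 25 / 50)

  # a subject with no valid frame has undefined GCM, not zero
  lab3 <- lab; lab3[, 2] <- NA_integer_
  cl3 <- new("GazeClustering", labels = lab3, params = cl@params,
             fps = 25, duration = 4)
  expect_true(is.na(gcm(computeAttentionSeries(cl3))[2]))
})

test_that("moving-window smoothing matches hand counts at a step edge", {
  expect_equal(smoothSeries(rep(3.5, 250), 25, 10), rep(3.5, 10))
  # step series at t = 10 s, 25 fps: window [7.5, 12.5) holds 63 zeros and
  # 62 ones
  v <- c(rep(0, 250), rep(1, 1250))
  s <- smoothSeries(v, 25, 60)
  expect_length(s, 60)
  expect_equal(s[11], 62 / 125)
  expect_true(all(is.na(smoothSeries(rep(NA_real_, 100), 25, 4))))
})

test_that("noiseless multi-focus scenes are recovered perfectly end to end", {
  sc <- sceneScript(3, 25, c(1680, 1050),
                    list(focusTrack(c(200, 200)), focusTrack(c(800, 200)),
                         focusTrack(c(1400, 800))))
  obs <- mixedObservers(18, 0, nFoci = 3, noiseSd = 0, blinkRate = 0)
  sim <- simulateGazeSession(sc, obs, 250, seed = 2)
  fgm <- aggregateToFrames(sim$recordings, 25, 3, c(1680, 1050))
  cl <- clusterFrames(fgm)
  expect_true(all(frameParams(cl)$n_clusters == 3L))
  s <- computeAttentionSeries(cl)
  expect_true(all(gcm(s) == 1))
})
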