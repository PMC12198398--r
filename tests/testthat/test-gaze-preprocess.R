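# Blink detection, masking, outlier exclusion, interpolation, aggregation.

test_that("blink cores are padded by 60 ms and merged", {
  p <- rep(1000, 500)                     # 1 s at 500 Hz, 2 ms per sample
  expect_identical(nrow(detectBlinks(p, 500)), 0L)

  p[101:151] <- 0                          # t = 200..300 ms
  b <- detectBlinks(p, 500)
  expect_equal(b$onset, 140)               # [200, 302) padded by 60
  expect_equal(b$offset, 362)

  # two cores whose pads touch merge into one interval
  p2 <- rep(1000, 500); p2[101:110] <- 0; p2[140:150] <- 0
  b2 <- detectBlinks(p2, 500)
  expect_identical(nrow(b2), 1L)
  expect_equal(b2$onset, 200 - 60)
  expect_equal(b2$offset, 300 + 60)

  expect_warning(ball <- detectBlinks(rep(0, 100), 500), "entirely missing")
  expect_true(isTRUE(attr(ball, "allMissing")))
  expect_equal(ball$offset - ball$onset, 200)
})

test_that("velocity refinement extends blink edges over abrupt pupil changes", {
  p <- rep(1000, 400) + rnorm(400, 0, 2)
  p[196:200] <- c(900, 700, 450, 250, 80)   # steep descent into the blink
  p[201:230] <- 0
  set.seed(42)
  b <- detectBlinks(p, 500, velocityK = 5)
  expect_identical(nrow(b), 1L)
  expect_lte(b$onset, (195 - 1) * 2 - 60 + 2)  # descent absorbed before pad
})

test_that("blink detection covers planted blinks from the simulator", {
  sc <- sceneScript(60, 25, c(1680, 1050), list(focusTrack(c(840, 525))))
  ob <- observerProfile("attentive", 1, blinkRate = 15)
  sim <- simulateGazeSession(sc, list(ob), 500, seed = 21)
  r <- sim$recordings[[1]]
  b <- detectBlinks(r@pupil, r@rate, t = r@t)
  planted <- sim$truth@blinkLog[[1]]
  core <- r@pupil == 0
  covered <- rep(FALSE, length(r@t))
  for (i in seq_len(nrow(b)))
    covered <- covered | (r@t >= b$onset[i] & r@t < b$offset[i])
  expect_gte(mean(covered[core]), 0.99)
  expect_gte(nrow(b), 1L)
  expect_lte(nrow(b), nrow(planted) + 2L)
})

test_that("masking follows half-open screen bounds and is idempotent", {
  rec <- new("GazeRecording", subject = "s", rate = 500,
             t = c(0, 2, 4, 6), x = c(1680, 0, 840, 100),
             y = c(500, 0, 525, 1050), pupil = rep(1000, 4),
             valid = rep(TRUE, 4))
  noBlinks <- data.frame(onset = numeric(0), offset = numeric(0))
  m <- maskSamples(rec, noBlinks, c(1680, 1050))
  expect_identical(m@valid, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(maskSamples(m, noBlinks, c(1680, 1050))@valid, m@valid)

  # blink interval masking is half-open too
  m2 <- maskSamples(rec, data.frame(onset = 2, offset = 4), c(1680, 1050))
  expect_identical(m2@valid, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("masked missing fraction matches planted off-screen fraction", {
  state <- function(t) {
    off <- (floor(t * 10) %% 10) == 0      # every 10th 100 ms slice off-screen
    list(state = ifelse(off, "off_screen", "attentive"),
         focus = ifelse(off, NA_integer_, 1L))
  }
  ob <- observerProfile(state, blinkRate = 0, fixationNoiseSd = 5)
  sc <- sceneScript(20, 25, c(1680, 1050), list(focusTrack(c(840, 525))))
  sim <- simulateGazeSession(sc, list(ob), 500, seed = 3)
  r <- maskSamples(sim$recordings[[1]],
                   data.frame(onset = numeric(0), offset = numeric(0)),
                   c(1680, 1050))
  expect_equal(mean(!r@valid), 0.10, tolerance = 0.01)
})

test_that("outlier exclusion z-scores subjects one-sided with sd n-1", {
  # identical subjects: zero variance, nobody excluded
  r0 <- excludeOutlierSubjects(rep(10, 5), rep(0.05, 5))
  expect_false(any(r0$excluded))
  expect_true(all(r0$z_blink == 0))

  # 20 subjects at 5% missing plus one at 60%: hand-computed z = 4.36 > 2
  mf <- c(rep(0.05, 20), 0.60)
  r1 <- excludeOutlierSubjects(rep(10, 21), mf)
  zHand <- (0.60 - mean(mf)) / sd(mf)
  expect_equal(r1$z_missing[21], zHand)
  expect_gt(zHand, 2)
  expect_identical(which(r1$excluded), 21L)

  # high on one criterion alone is enough
  bc <- c(rep(10, 20), 40)
  r2 <- excludeOutlierSubjects(bc, rep(0.05, 21))
  expect_true(r2$excluded[21])
  expect_identical(sum(r2$excluded), 1L)
  # low outliers are never excluded (one-sided rule)
  r3 <- excludeOutlierSubjects(c(rep(10, 20), 0), rep(0.05, 21))
  expect_false(any(r3$excluded))
  expect_error(excludeOutlierSubjects(c(1, 2), c(0, 0)), "three subjects")
})

test_that("gap interpolation is linear, exact on ramps, identity when complete", {
  rec <- new("GazeRecording", subject = "s", rate = 20,
             t = seq(0, 100, by = 50), x = c(100, NA, 200),
             y = c(0, NA, 50), pupil = rep(1000, 3),
             valid = c(TRUE, FALSE, TRUE))
  out <- interpolateGaps(rec)
  expect_equal(out@x[2], 150)
  expect_equal(out@y[2], 25)
  expect_true(all(out@valid))

  full <- new("GazeRecording", subject = "s", rate = 20,
              t = c(0, 50, 100), x = 1:3, y = 3:1,
              pupil = rep(1, 3), valid = rep(TRUE, 3))
  expect_identical(interpolateGaps(full), full)

  # random mask on an affine signal reconstructs exactly
  set.seed(8)
  n <- 500
  t <- seq(0, 999, length.out = n)
  ramp <- new("GazeRecording", subject = "s", rate = 500, t = t,
              x = 2 * t + 10, y = 1000 - t, pupil = rep(1, n),
              valid = replace(rep(TRUE, n), sample(2:(n - 1), 150), FALSE))
  fixed <- interpolateGaps(ramp)
  expect_equal(fixed@x, 2 * t + 10, tolerance = 1e-12)
  expect_equal(fixed@y, 1000 - t, tolerance = 1e-12)

  bad <- new("GazeRecording", subject = "s", rate = 1, t = c(0, 1000),
             x = c(1, 2), y = c(1, 2), pupil = c(1, 1),
             valid = c(TRUE, FALSE))
  expect_error(interpolateGaps(bad), "two valid samples")
})

test_that("frame aggregation averages valid samples into half-open windows", {
  expect_identical(round(946.56 * 25), 23664)   # the full-video frame count

  # constant gaze fills every cell with the constant
  rec <- new("GazeRecording", subject = "a", rate = 500,
             t = seq(0, 1998, by = 2), x = rep(300, 1000),
             y = rep(400, 1000), pupil = rep(1, 1000),
             valid = rep(TRUE, 1000))
  fgm <- aggregateToFrames(list(rec), fps = 25, duration = 2,
                           screen = c(1680, 1050))
  expect_identical(nrow(fgm), 50L)
  expect_true(all(SummarizedExperiment::assay(fgm, "x") == 300))

  # a 40 ms window at 500 Hz holds 20 samples; mean of {100, 110} when only
  # two are valid
  rec2 <- rec
  rec2@x[1:20] <- c(100, 110, rep(999, 18))
  rec2@valid[3:20] <- FALSE
  fgm2 <- aggregateToFrames(list(rec2), 25, 2, c(1680, 1050))
  expect_equal(unname(SummarizedExperiment::assay(fgm2, "x")[1, 1]), 105)

  # a frame with no valid samples is missing
  rec3 <- rec; rec3@valid[1:20] <- FALSE
  fgm3 <- aggregateToFrames(list(rec3), 25, 2, c(1680, 1050))
  expect_true(is.na(SummarizedExperiment::assay(fgm3, "x")[1, 1]))

  # short recording: trailing frames missing, with a warning
  short <- new("GazeRecording", subject = "b", rate = 500,
               t = seq(0, 998, by = 2), x = rep(1, 500), y = rep(1, 500),
               pupil = rep(1, 500), valid = rep(TRUE, 500))
  expect_warning(fgm4 <- aggregateToFrames(list(short), 25, 2,
                                           c(1680, 1050)), "shorter")
  expect_true(all(is.na(SummarizedExperiment::assay(fgm4, "x")[26:50, 1])))
})

test_that("aggregation is permutation-equivariant in subjects", {
  sc <- twoFociScene(4)
  sim <- simulateGazeSession(sc, mixedObservers(4, 2), 250, seed = 6)
  fgm <- aggregateToFrames(sim$recordings, 25, 4, c(1680, 1050))
  perm <- c(3, 1, 6, 2, 5, 4)
  fgmP <- aggregateToFrames(sim$recordings[perm], 25, 4, c(1680, 1050))
  expect_identical(SummarizedExperiment::assay(fgmP, "x"),
                   SummarizedExperiment::assay(fgm, "x")[, perm])
})

test_that("masking can only grow the missing fraction", {
  sc <- twoFociScene(4)
  sim <- simulateGazeSession(sc, mixedObservers(3, 3), 250, seed = 16)
  for (r in sim$recordings) {
    b <- detectBlinks(r@pupil, r@rate, t = r@t)
    m <- maskSamples(r, b, c(1680, 1050))
    expect_gte(mean(!m@valid), mean(!r@valid))
  }
})

test_that("noiseless simulator output aggregates exactly to focus positions", {
  sc <- sceneScript(3, 25, c(1680, 1050),
                    list(focusTrack(c(300, 400)), focusTrack(c(900, 700))))
  obs <- mixedObservers(4, 0, noiseSd = 0, blinkRate = 0)
  sim <- simulateGazeSession(sc, obs, 500, seed = 1)
  fgm <- aggregateToFrames(sim$recordings, 25, 3, c(1680, 1050))
  X <- SummarizedExperiment::assay(fgm, "x")
  expect_true(all(X[, c(1, 3)] == 300))
  expect_true(all(X[, c(2, 4)] == 900))
})
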