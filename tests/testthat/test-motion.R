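test_that("grid segments match a brute-force enumeration of the lattice rule", {
  H <- 32; W <- 32; l <- 7
  grid <- buildGrid(c(H, W), l)
  # brute force: every pixel satisfying the lattice condition, segment by
  # segment (strict inequalities; corner pixels belong to no segment)
  expectPix <- list()
  for (n in 0:((H - 1) %/% l)) for (m in 0:((W - 1) %/% l)) {
    xs <- (l * m + 1):(l * (m + 1) - 1)
    if (max(xs) <= W - 1 && l * n <= H - 1)
      expectPix[[paste0("h", m, "_", n)]] <-
        cbind(x = xs, y = rep(l * n, l - 1))
    ys <- (l * n + 1):(l * (n + 1) - 1)
    if (max(ys) <= H - 1 && l * m <= W - 1)
      expectPix[[paste0("v", m, "_", n)]] <-
        cbind(x = rep(l * m, l - 1), y = ys)
  }
  got <- lapply(grid@segments, function(s) unname(s$pixels))
  expect_equal(length(got), length(expectPix))
  key <- function(p) paste(p[, 1], p[, 2], collapse = ";")
  expect_setequal(vapply(got, key, character(1)),
                  vapply(expectPix, function(p) key(unname(p)),
                         character(1)))
  # every segment has l - 1 interior pixels, all within bounds
  for (s in grid@segments) {
    expect_equal(nrow(s$pixels), l - 1L)
    expect_true(all(s$pixels >= 0 & s$pixels <= 31))
  }
  expect_error(buildGrid(c(32, 32), 8), "odd")
  expect_error(buildGrid(c(32, 32), 35), "min\\(H, W\\)")
})

test_that("segment motion statistic equals the hand-computed difference sum", {
  H <- 32; T <- 16
  arr <- array(0.2, dim = c(T, H, H, 1))
  # one blinking pixel of amplitude 0.5 on a known horizontal segment:
  # pixel (x=3, y=7) lies in the l=7 segment at m=0, n=1
  blink <- rep(c(0.2, 0.7), length.out = T)
  arr[, 8, 4, 1] <- blink
  v <- VideoSequence(arr, frameRate = 10)
  grid <- buildGrid(c(H, H), 7)
  hits <- detectMovingSegments(v, grid, mth = 0)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$center, c(x = 3, y = 7))
  expect_equal(hits[[1]]$motionSum, sum(abs(diff(blink))), tolerance = 1e-12)
  # static video: nothing moves
  expect_length(detectMovingSegments(
    VideoSequence(array(0.3, dim = c(4, H, H, 1)), frameRate = 10),
    grid, mth = 0), 0L)
  # the statistic is invariant to reversing time
  rev <- VideoSequence(arr[T:1, , , , drop = FALSE], frameRate = 10)
  hitsRev <- detectMovingSegments(rev, grid, mth = 0)
  expect_equal(hitsRev[[1]]$motionSum, hits[[1]]$motionSum)
})

test_that("center of mass of a symmetric profile is zero and rms matches a two-pass oracle", {
  # static symmetric blob centered on the probe center
  v <- blobVideo(T = 8, a = 0, size = 33, sigma = 3)
  ctr <- c(16L, 16L)
  for (th in c(0, 45, 90, 135)) {
    cm <- cellmag:::.cmTrack(v, ctr, th, 9L)
    expect_lt(max(abs(cm)), 1e-9)
  }
  # rms scores against an independent two-pass computation
  vm <- blobVideo(T = 24, a = 1.5, freq = 2, size = 33, sigma = 2.5,
                  directionDeg = 90)
  md <- assignDirection(vm, list(center = ctr, motionSum = 1), l = 9)
  for (i in seq_along(c(0, 45, 90, 135))) {
    th <- c(0, 45, 90, 135)[i]
    cm <- cellmag:::.cmTrack(vm, ctr, th, 9L)
    mu <- sum(cm) / length(cm)
    rms <- sqrt(sum((cm - mu)^2) / length(cm))
    expect_equal(unname(md@scores[i]), rms, tolerance = 1e-12)
  }
  # a static probe yields no director
  grid <- buildGrid(c(33, 33), 9)
  expect_length(findDirectors(v, grid, mth = 1e-6), 0L)
})

test_that("injected translation direction is recovered in at least 95% of triggered segments", {
  hits <- 0; total <- 0
  for (dir in c(0, 45, 90, 135)) {
    fx <- blobFieldVideo(dir, seed = 40 + dir)
    sums <- vapply(detectMovingSegments(fx$video, fx$grid, 0),
                   function(s) s$motionSum, numeric(1))
    dirs <- findDirectors(fx$video, fx$grid, 0.6 * max(sums))
    expect_gt(length(dirs), 3)
    hits <- hits + sum(vapply(dirs, function(d) d@thetaDeg,
                              numeric(1)) == dir)
    total <- total + length(dirs)
  }
  expect_gte(hits / total, 0.95)
})

test_that("at the ring's rightmost edge the radial probe carries the wave and the tangential one does not", {
  spec <- fixtureSpec("ring", size = c(63, 63), frames = 48, frameRate = 24,
                      motionFreq = 2, amplitudePx = 2, noiseSigma = 0.002,
                      seed = 45, radius = 16)
  fx <- makeRing(spec)
  # ring center (31, 31), rightmost edge at x = 47: the radial direction
  # there is horizontal (90 deg); the tangential (0 deg) probe runs along
  # the arc and sees no center-of-mass wave at all. The oblique probes
  # also cross the breathing arc (their crossing point slides along the
  # probe), so the discriminating contrast is radial vs tangential.
  md <- assignDirection(fx$video, list(center = c(47L, 31L),
                                       motionSum = 1), l = 9)
  expect_gt(md@scores["rms90"], 100 * md@scores["rms0"])
  expect_true(md@thetaDeg != 0)
  # the radial kymograph shows a clean oscillation at the drive frequency
  ky <- phaseAnnotate(fx$video, center = c(47L, 31L), thetaDeg = 90,
                      l = 9, nFit = 3)
  cm <- ky@cmTrack - mean(ky@cmTrack)
  spec1 <- powerSpectrum((0:24) * 24 / 48,
                         btOracleSpectrum(cm)$power, frameRate = 24)
  expect_equal(dominantFreq(spec1), 2, tolerance = 1e-9)
})

test_that("probe lines leaving the frame are skipped with a warning", {
  v <- blobVideo(T = 8, a = 0, size = 33)
  expect_warning(
    res <- assignDirection(v, list(center = c(1L, 16L), motionSum = 1),
                           l = 9),
    "leaves the frame")
  expect_null(res)
})

test_that("phase labels flip at the extrema of a sinusoidal center of mass", {
  # blob oscillating along y with period 20 frames: cm(t) ~ sin(2 pi t / 20)
  v <- blobVideo(T = 60, fps = 20, a = 2, freq = 1, size = 33, sigma = 3,
                 directionDeg = 0)
  ky <- phaseAnnotate(v, center = c(16L, 16L), thetaDeg = 0, l = 15,
                      nFit = 4)
  expect_length(ky@cmTrack, 60)
  expect_equal(dim(ky@image), c(15L, 60L))
  # derivative of sin(2 pi t / 20) flips at t = 5, 15, 25, ... (0-based)
  flips <- which(diff(ky@phaseSign) != 0 & ky@phaseSign[-1] != 0)
  expected <- seq(5, 55, by = 10)
  for (f in expected)
    expect_true(min(abs(flips - 1 - f)) <= 1,
                label = paste("flip near frame", f))
  # a monotonically drifting center of mass keeps a single phase
  img <- blobImage(33, 16, 16, 3)
  fr <- array(0, dim = c(20, 33, 33, 1))
  for (t in 1:20) fr[t, , , 1] <- fourierShift(img, 0, 0.15 * (t - 1))
  drv <- VideoSequence(fr, frameRate = 10)
  ky2 <- phaseAnnotate(drv, center = c(16L, 16L), thetaDeg = 0,
                       l = 15, nFit = 4)
  expect_true(all(ky2@phaseSign == ky2@phaseSign[1]))
  expect_error(phaseAnnotate(v, center = c(16L, 16L), thetaDeg = 0, l = 9,
                             nFit = 2), "nFit")
  expect_error(phaseAnnotate(blobVideo(T = 8, size = 33),
                             center = c(16L, 16L), thetaDeg = 0, l = 9,
                             nFit = 5), "too short")
})

test_that("director rendering draws arrows only when directors exist", {
  v <- blobVideo(T = 8, a = 0.5, freq = 2, fps = 10, size = 33)
  same <- renderDirectors(v, list())
  expect_identical(frames(same), frames(v))
  md <- assignDirection(v, list(center = c(16L, 16L), motionSum = 1), l = 9)
  ann <- renderDirectors(v, list(md))
  expect_gt(sum(frames(ann) != frames(v)), 0)
  # annotation is identical on every frame
  d1 <- frames(ann)[1, , , 1] != frames(v)[1, , , 1]
  d2 <- frames(ann)[8, , , 1] != frames(v)[8, , , 1]
  expect_identical(which(d1), which(d2))
})

test_that("the automatic motion threshold separates moving from static regions", {
  fx <- blobFieldVideo(90, seed = 47)
  # the lower band of the blob field is feature-free: a static control
  mth <- autoMotionThreshold(fx$video, rectROI(18, 40, 40, 62), l = 9)
  expect_gt(mth, 0)
  sums <- vapply(detectMovingSegments(fx$video, fx$grid, 0),
                 function(s) s$motionSum, numeric(1))
  expect_lt(mth, max(sums))
  dirs <- findDirectors(fx$video, fx$grid, mth)
  expect_gt(length(dirs), 0)
})
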