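test_that("fixtures are byte-deterministic given spec + seed", {
  for (kind in c("ring", "oscillating_texture", "drift", "static")) {
    spec <- fixtureSpec(kind, size = c(32, 32), frames = 6, frameRate = 12,
                        motionFreq = 1, amplitudePx = 0.4,
                        noiseSigma = 0.01, seed = 11, radius = 8)
    a <- makeFixture(spec); b <- makeFixture(spec)
    expect_identical(frames(a$video), frames(b$video))
    expect_identical(a$truth, b$truth)
    spec2 <- fixtureSpec(kind, size = c(32, 32), frames = 6, frameRate = 12,
                         motionFreq = 1, amplitudePx = 0.4,
                         noiseSigma = 0.01, seed = 12, radius = 8)
    expect_false(identical(frames(a$video),
                           frames(makeFixture(spec2)$video)))
  }
})

test_that("Fourier shift by an integer equals an array roll", {
  set.seed(4)
  m <- cellmag:::.bandLimitedTexture(24, 24)
  expect_lt(max(abs(fourierShift(m, 1, 0) - m[, c(24, 1:23)])), 1e-9)
  expect_lt(max(abs(fourierShift(m, 0, -2) - m[c(3:24, 1:2), ])), 1e-9)
  expect_lt(max(abs(fourierShift(m, 0, 0) - m)), 1e-12)
})

test_that("oscillating texture is sub-pixel and carries exact ground truth", {
  spec <- fixtureSpec("oscillating_texture", size = c(32, 32), frames = 240,
                      frameRate = 24, motionFreq = 1, amplitudePx = 0.36,
                      noiseSigma = 0, seed = 5)
  fx <- makeOscillatingTexture(spec)
  d <- fx$truth$displacement_px
  expect_lt(max(abs(d)), 1)                       # imperceptibility: < 1 px
  expect_gt(max(abs(d)), 0.3)
  # sine rms: a / sqrt(2) within 1 %
  expect_equal(sqrt(mean(d^2)), 0.36 / sqrt(2), tolerance = 0.01)
  # frames actually modulate
  expect_gt(max(abs(frames(fx$video)[2, , , 1] - frames(fx$video)[1, , , 1])),
            0)
  # displacement period equals frameRate / f frames
  expect_equal(d[1 + 24], d[1], tolerance = 1e-9)
})

test_that("ring radius follows the harmonic ground truth and stays in frame", {
  spec <- fixtureSpec("ring", size = c(64, 64), frames = 24, frameRate = 12,
                      motionFreq = 1, amplitudePx = 2, noiseSigma = 0,
                      seed = 6, radius = 16)
  fx <- makeRing(spec)
  r <- fx$truth$radius_px
  expect_equal(r, 16 + 2 * sin(2 * pi * 1 * (0:23) / 12), tolerance = 1e-12)
  expect_equal(r[1 + 12], r[1], tolerance = 1e-9)   # period = fps / f frames
  # amplitude 0 -> all frames identical before noise
  spec0 <- fixtureSpec("ring", size = c(64, 64), frames = 5, frameRate = 12,
                       amplitudePx = 0, noiseSigma = 0, seed = 6,
                       radius = 16)
  fr0 <- frames(makeRing(spec0)$video)
  expect_identical(fr0[1, , , 1], fr0[5, , , 1])
  # ring leaving the frame is rejected
  expect_error(makeRing(fixtureSpec("ring", size = c(32, 32), frames = 4,
                                    radius = 14, amplitudePx = 3,
                                    seed = 1)),
               "leaves the frame")
})

test_that("static and drift fixtures behave as labelled", {
  s0 <- makeStatic(fixtureSpec("static", size = c(16, 16), frames = 5,
                               noiseSigma = 0, seed = 7))
  expect_identical(frames(s0$video)[1, , , 1], frames(s0$video)[5, , , 1])
  dr <- makeDrift(fixtureSpec("drift", size = c(16, 16), frames = 10,
                              amplitudePx = 0.5, directionDeg = 90,
                              noiseSigma = 0, seed = 8))
  expect_equal(dr$truth$dx_px[10], 0.5 * 9, tolerance = 1e-12)
  expect_equal(dr$truth$dy_px[10], 0, tolerance = 1e-12)
})

test_that("super-Nyquist drive frequencies are rejected unless aliasing is requested", {
  expect_error(fixtureSpec("oscillating_texture", frameRate = 24,
                           motionFreq = 20),
               "Nyquist")
  spec <- fixtureSpec("oscillating_texture", size = c(32, 32), frames = 48,
                      frameRate = 24, motionFreq = 20, amplitudePx = 0.5,
                      noiseSigma = 0, seed = 9, allowAlias = TRUE)
  expect_warning(makeOscillatingTexture(spec), "alias")
})
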