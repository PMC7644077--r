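test_that("degree of motion is near zero for a noiseless static video", {
  fx <- makeStatic(fixtureSpec("static", size = c(64, 64), frames = 6,
                               noiseSigma = 0, seed = 61))
  dom <- degreeOfMotion(fx$video)
  expect_lt(degreeOfMotionValue(dom), 1e-3 * 64 * 64 * 5)
})

test_that("uniform translation yields the analytic flow budget", {
  # texture translating 1 px/frame over the whole frame: total flow
  # magnitude should approach A * (T - 1) * 1.0 with A = H * W
  fx <- makeDrift(fixtureSpec("drift", size = c(64, 64), frames = 11,
                              frameRate = 10, amplitudePx = 1,
                              directionDeg = 90, noiseSigma = 0,
                              seed = 62))
  dom <- degreeOfMotionValue(degreeOfMotion(fx$video))
  expected <- 64 * 64 * 10
  expect_lt(abs(dom - expected) / expected, 0.25)
})

test_that("degree of motion is additive in duration and offset-invariant", {
  mk <- function(T) makeOscillatingTexture(
    fixtureSpec("oscillating_texture", size = c(48, 48), frames = T,
                frameRate = 12, motionFreq = 1, amplitudePx = 0.5,
                noiseSigma = 0, seed = 63))$video
  d1 <- degreeOfMotionValue(degreeOfMotion(mk(24)))
  d2 <- degreeOfMotionValue(degreeOfMotion(mk(48)))
  expect_lt(abs(d2 - 2 * d1) / (2 * d1), 0.2)
  v <- mk(12)
  shifted <- VideoSequence(pmin(frames(v) + 0.1, 1), frameRate = 12)
  expect_equal(degreeOfMotionValue(degreeOfMotion(shifted)),
               degreeOfMotionValue(degreeOfMotion(v)), tolerance = 1e-6)
})

test_that("noise-floor sweep separates real motion from amplified noise", {
  osc <- makeOscillatingTexture(fixtureSpec("oscillating_texture",
                                            size = c(64, 64), frames = 48,
                                            amplitudePx = 0.5,
                                            noiseSigma = 0.01, seed = 64))
  ctrl <- makeStatic(fixtureSpec("static", size = c(64, 64), frames = 48,
                                 noiseSigma = 0.01, seed = 65))
  params <- magnificationParams(1, 1, halfBand = 0.3)
  cur <- noiseFloorCurve(osc$video, ctrl$video, c(5, 10, 20), params)
  tb <- cur@table
  expect_equal(tb$alpha, c(5, 10, 20))
  expect_true(all(tb$verdict == "real"))
  expect_true(all(tb$sample_motion > tb$control_motion))
})

test_that("a video compared against itself never counts as real motion", {
  ctrl <- makeStatic(fixtureSpec("static", size = c(48, 48), frames = 24,
                                 noiseSigma = 0.01, seed = 66))$video
  params <- magnificationParams(1, 1, halfBand = 0.3)
  cur <- noiseFloorCurve(ctrl, ctrl, 5, params)
  expect_equal(nrow(cur@table), 1L)
  expect_equal(cur@table$verdict, "noise-level")
  # mismatched frame rates are rejected
  other <- makeStatic(fixtureSpec("static", size = c(48, 48), frames = 24,
                                  frameRate = 12, noiseSigma = 0.01,
                                  seed = 66))$video
  expect_error(noiseFloorCurve(ctrl, other, 5, params), "frame rates")
})

test_that("amplified-noise growth is sub-linear relative to coherent motion", {
  # sample/control ratio at fixed alpha increases with motion amplitude
  ctrl <- makeStatic(fixtureSpec("static", size = c(48, 48), frames = 36,
                                 noiseSigma = 0.01, seed = 67))$video
  params <- magnificationParams(1, 1, halfBand = 0.3)
  ratio <- vapply(c(0.2, 0.6), function(a) {
    s <- makeOscillatingTexture(fixtureSpec("oscillating_texture",
                                            size = c(48, 48), frames = 36,
                                            amplitudePx = a,
                                            noiseSigma = 0.01,
                                            seed = 68))$video
    tb <- noiseFloorCurve(s, ctrl, 10, params)@table
    tb$sample_motion / tb$control_motion
  }, numeric(1))
  expect_gt(ratio[2], ratio[1])
})
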