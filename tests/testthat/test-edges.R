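test_that("temporal mean averages the requested window per channel", {
  arr <- array(0, dim = c(4, 16, 16, 2))
  arr[1, , , ] <- 0; arr[2, , , ] <- 1; arr[3, , , ] <- 0.25
  arr[4, , , ] <- 0.75
  v <- VideoSequence(arr, frameRate = 10)
  expect_equal(temporalMean(v)[, , 1], matrix(0.5, 16, 16))
  expect_equal(temporalMean(v, c(0, 2))[, , 2], matrix(0.5, 16, 16))
  # single-frame window is that frame
  expect_equal(temporalMean(v, c(2, 3))[, , 1], matrix(0.25, 16, 16))
  expect_error(temporalMean(v, c(2, 2)), "window")
  expect_error(temporalMean(v, c(0, 9)), "window")
})

test_that("a uniform image yields no edge pixels, zero threshold nearly all", {
  v <- VideoSequence(array(0.5, dim = c(2, 24, 24, 1)), frameRate = 10)
  expect_equal(edgeCount(detectEdges(v, gth = 0.01)), 0L)
  fx <- makeStatic(fixtureSpec("static", size = c(24, 24), frames = 4,
                               noiseSigma = 0.02, seed = 3))
  em0 <- detectEdges(fx$video, gth = 0)
  expect_gt(edgeCount(em0), 0.95 * 24 * 24)
})

test_that("edge mask of a ring is an annulus within 2 px of the true radius", {
  spec <- fixtureSpec("ring", size = c(64, 64), frames = 8, frameRate = 12,
                      motionFreq = 1, amplitudePx = 0.5, noiseSigma = 0.002,
                      seed = 4, radius = 16)
  fx <- makeRing(spec)
  # moderate threshold relative to the ring's peak gradient (~0.43)
  em <- detectEdges(fx$video, gth = 0.3, method = "sobel")
  expect_gt(edgeCount(em), 50)
  co <- edgeCoords(em)
  dist <- sqrt((co$x - 31.5)^2 + (co$y - 31.5)^2)
  expect_true(all(abs(dist - 16) <= 2 + 0.5))   # 0.5: fixture amplitude
})

test_that("gradient-threshold masks shrink monotonically with gth", {
  fx <- makeOscillatingTexture(fixtureSpec("oscillating_texture",
                                           size = c(48, 48), frames = 6,
                                           amplitudePx = 0.2,
                                           noiseSigma = 0.01, seed = 5))
  for (method in c("sobel", "prewitt", "roberts")) {
    prev <- NULL
    for (gth in c(0.02, 0.05, 0.1, 0.2)) {
      m <- detectEdges(fx$video, gth, method = method)@mask
      if (!is.null(prev)) expect_true(all(prev | !m))  # m subset of prev
      prev <- m
    }
  }
})

test_that("multi-channel edge condition must hold in every channel", {
  H <- 48
  sp1 <- fixtureSpec("ring", size = c(H, H), frames = 3, frameRate = 10,
                     amplitudePx = 0, noiseSigma = 0, seed = 1, radius = 12)
  ring <- frames(makeRing(sp1)$video)
  arr <- array(0, dim = c(3, H, H, 2))
  arr[, , , 1] <- ring[, , , 1]
  arr[, , , 2] <- 0.5                      # featureless second channel
  v2 <- VideoSequence(arr, frameRate = 10)
  expect_equal(edgeCount(detectEdges(v2, gth = 0.05)), 0L)
  # intersection is a subset of each per-channel mask
  arr[, , , 2] <- ring[, c(2:H, H), , 1]   # shifted ring
  v3 <- VideoSequence(arr, frameRate = 10)
  both <- detectEdges(v3, gth = 0.05)@mask
  ch1 <- detectEdges(selectChannels(v3, 1), gth = 0.05)@mask
  ch2 <- detectEdges(selectChannels(v3, 2), gth = 0.05)@mask
  expect_true(all(ch1 | !both))
  expect_true(all(ch2 | !both))
})

test_that("binary-map operators return their own edge maps", {
  spec <- fixtureSpec("ring", size = c(64, 64), frames = 4, frameRate = 10,
                      amplitudePx = 0, noiseSigma = 0.002, seed = 6,
                      radius = 16)
  v <- makeRing(spec)$video
  for (method in c("canny", "log", "zerocross")) {
    em <- detectEdges(v, gth = 0.05, method = method)
    co <- edgeCoords(em)
    expect_gt(nrow(co), 20)
    dist <- sqrt((co$x - 31.5)^2 + (co$y - 31.5)^2)
    # detected structure concentrates near the ring
    expect_lt(median(abs(dist - 16)), 3)
  }
  expect_error(detectEdges(v, gth = 0.05, method = "laplace"),
               "should be one of")
})
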