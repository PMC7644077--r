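# Shared fixture builders and measurement helpers. Everything is generated
# in code under fixed seeds; no stored data.

# Gaussian blob image centered at (cx, cy), 0-based coords
blobImage <- function(size, cx, cy, sigma = 4, amp = 0.8, bg = 0.1) {
  d2 <- outer(((0:(size - 1)) - cy)^2, rep(1, size)) +
    outer(rep(1, size), ((0:(size - 1)) - cx)^2)
  pmin(bg + amp * exp(-d2 / (2 * sigma^2)), 1)
}

# single blob translating as a*sin(2 pi f t) along directionDeg
blobVideo <- function(T = 96, fps = 24, a = 0.2, freq = 1, size = 64,
                      sigma = 4, directionDeg = 90, noise = 0, seed = 1) {
  img <- blobImage(size, size %/% 2, size %/% 2, sigma)
  th <- directionDeg * pi / 180
  fr <- array(0, dim = c(T, size, size, 1))
  set.seed(seed)
  for (t in seq_len(T)) {
    d <- a * sin(2 * pi * freq * (t - 1) / fps)
    fr[t, , , 1] <- fourierShift(img, d * sin(th), d * cos(th))
  }
  if (noise > 0)
    fr <- fr + array(rnorm(length(fr), sd = noise), dim = dim(fr))
  VideoSequence(pmin(pmax(fr, 0), 1), frameRate = fps)
}

# field of small blobs placed on motion-grid segment centers, pairwise
# >= 14 px apart, translating along directionDeg; returns video + grid
blobFieldVideo <- function(directionDeg, size = 63, l = 9, T = 48,
                           fps = 24, a = 2, freq = 2, noise = 0.003,
                           seed = 1) {
  hc <- expand.grid(x = l * (0:((size - 1) %/% l)) + l %/% 2,
                    y = l * (1:((size - 1) %/% l)))
  vc <- expand.grid(x = l * (1:((size - 1) %/% l)),
                    y = l * (0:((size - 1) %/% l)) + l %/% 2)
  cand <- rbind(hc, vc)
  cand <- cand[cand$x >= 4 & cand$x <= size - 5 &
                 cand$y >= 4 & cand$y <= size - 5, ]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(keep) ||
        min(sqrt((cand$x[keep] - cand$x[i])^2 +
                   (cand$y[keep] - cand$y[i])^2)) >= 14)
      keep <- c(keep, i)
  }
  cents <- cand[keep, ][seq_len(min(8, length(keep))), ]
  img <- matrix(0.05, size, size)
  for (i in seq_len(nrow(cents)))
    img <- img + 0.9 * exp(-(outer(((0:(size - 1)) - cents$y[i])^2,
                                   rep(1, size)) +
                               outer(rep(1, size),
                                     ((0:(size - 1)) - cents$x[i])^2)) /
                             (2 * 1.5^2))
  img <- pmin(img, 1)
  th <- directionDeg * pi / 180
  fr <- array(0, dim = c(T, size, size, 1))
  set.seed(seed)
  for (t in seq_len(T)) {
    d <- a * sin(2 * pi * freq * (t - 1) / fps)
    fr[t, , , 1] <- fourierShift(img, d * sin(th), d * cos(th)) +
      rnorm(size^2, sd = noise)
  }
  list(video = VideoSequence(pmin(pmax(fr, 0), 1), frameRate = fps),
       grid = buildGrid(c(size, size), l), centers = cents)
}

# background-subtracted center of mass along one row, windowed around the
# frame center: the kymograph-line displacement measurement
cmWindowTrack <- function(video, row = NULL, win = 12) {
  d <- frameDim(video)
  if (is.null(row)) row <- d[1] %/% 2 + 1
  mid <- d[2] %/% 2 + 1
  h <- (-win):win
  vapply(seq_len(nFrames(video)), function(t) {
    prof <- frames(video)[t, row, (mid - win):(mid + win), 1]
    prof <- prof - min(prof)
    sum(h * prof) / sum(prof)
  }, numeric(1))
}

# amplitude of a sinusoidal track from its rms
sineAmplitude <- function(tr) {
  tr <- tr - mean(tr)
  sqrt(2) * sqrt(mean(tr^2))
}

# Independent Blackman-Tukey oracle: biased autocorrelation by explicit
# double loop, then the one-sided cosine symmetrization by explicit sums.
btOracleSpectrum <- function(x, L = length(x)) {
  N <- length(x)
  xm <- x - mean(x)
  r <- numeric(L)
  for (tau in 0:(L - 1)) {
    s <- 0
    for (t in 1:(N - tau)) s <- s + xm[t] * xm[t + tau]
    r[tau + 1] <- s / N
  }
  S <- numeric(L %/% 2 + 1)
  for (k in 0:(L %/% 2)) {
    acc <- r[1]
    for (tau in 1:(L - 1))
      acc <- acc + 2 * r[tau + 1] * cos(2 * pi * k * tau / L)
    S[k + 1] <- acc
  }
  list(r = r, power = pmax(S, 0), raw = S)
}
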