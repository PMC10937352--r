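rate <- 2000
tt <- function(nSec) seq_len(nSec * rate) / rate

test_that("detrending annihilates linear trends and keeps passband tones", {
  n <- 4 * rate
  ramp <- 2.5 + 0.8 * seq_len(n)
  tone100 <- sin(2 * pi * 100 * tt(4))
  rec <- RawRecording(rbind(ramp, tone100), rate)
  out <- voltages(detrendAntialias(rec))
  expect_lt(max(abs(out[1, ])), 1e-7)          # a line maps to zero
  mid <- (rate):(3 * rate)
  gain <- sqrt(mean(out[2, mid]^2) * 2)
  expect_lt(abs(gain - 1), 0.01)               # 100 Hz passes at gain 1
})

test_that("anti-alias stopband attenuation matches the analytic response", {
  n <- 4 * rate
  tone600 <- sin(2 * pi * 600 * tt(4))
  rec <- RawRecording(matrix(tone600, 1), rate)
  out <- voltages(detrendAntialias(rec))
  mid <- (rate):(3 * rate)
  gain <- sqrt(mean(out[1, mid]^2) * 2)
  # analytic digital Butterworth low-pass (order 4, applied twice)
  W <- tan(pi * 600 / rate) / tan(pi * 500 / rate)
  expected <- (1 / sqrt(1 + W^8))^2
  expect_lt(abs(gain - expected) / expected, 0.05)
})

test_that("rates below twice the anti-alias cutoff are rejected", {
  rec <- RawRecording(matrix(rnorm(500), 1), 500)
  expect_error(detrendAntialias(rec), "1000")
})

test_that("band-pass gains match the closed-form Butterworth magnitude", {
  n <- 20 * rate
  mid <- (5 * rate):(15 * rate)
  probe <- function(f, band) {
    rec <- RawRecording(matrix(sin(2 * pi * f * tt(20)), 1), rate)
    out <- extractBand(rec, band)
    # measure at 200 Hz on the central region
    m <- (5 * 200):(15 * 200)
    sqrt(mean(out[1, m]^2) * 2)
  }
  # passband centers
  expect_lt(abs(probe(10, "1-30Hz") - 1), 0.02)
  expect_lt(abs(probe(50, "30-70Hz") - 1), 0.02)
  # 50 Hz through the 1-30 Hz band: stopband, compare to analytic |H|^2
  g <- probe(50, "1-30Hz")
  expected <- butterBandGain(50, c(1, 30), rate)
  expect_lt(abs(g - expected) / expected, 0.01)
  expect_error(extractBand(RawRecording(matrix(0, 1, rate), rate),
                           "70-150Hz"), "unsupported")
})

test_that("high-gamma envelope recovers tone amplitude and AM waveform", {
  A <- 2.3
  x <- A * sin(2 * pi * 100 * tt(20))
  rec <- RawRecording(matrix(x, 1), rate)
  env <- extractHighGamma(rec)
  m <- (5 * 200):(15 * 200)
  expect_lt(max(abs(env[1, m] - A)) / A, 0.03)

  am <- A * sin(2 * pi * 100 * tt(20)) * (1 + 0.5 * sin(2 * pi * 2 * tt(20)))
  env2 <- extractHighGamma(RawRecording(matrix(am, 1), rate))
  target <- A * (1 + 0.5 * sin(2 * pi * 2 * (seq_len(20 * 200) / 200)))
  err <- sqrt(mean((env2[1, m] - target[m])^2)) / sqrt(mean(target[m]^2))
  expect_lt(err, 0.05)

  z <- extractHighGamma(RawRecording(matrix(0, 1, 20 * rate), rate))
  expect_equal(max(abs(z)), 0)
})

test_that("all band paths are zero-phase aligned (impulse peaks agree)", {
  n <- 8 * rate
  x <- numeric(n)
  x[4 * rate] <- 1
  rec <- RawRecording(matrix(x, 1), rate)
  peaks <- c(which.max(abs(extractBand(rec, "1-30Hz")[1, ])),
             which.max(abs(extractBand(rec, "30-70Hz")[1, ])),
             which.max(extractHighGamma(rec)[1, ]))
  expect_lte(diff(range(peaks)), 1L)
})

test_that("designed filters are stable", {
  for (band in list(c(1, 30), c(30, 70), c(70, 150))) {
    flt <- seegspeech:::butterBand(band, rate)
    expect_lt(max(Mod(polyroot(rev(flt$a)))), 1)
  }
})

test_that("band paths suppress out-of-band energy", {
  set.seed(1)
  x <- rnorm(30 * rate)
  rec <- RawRecording(matrix(x, 1), rate)
  b <- extractBand(rec, "30-70Hz")[1, ]
  sp <- Mod(fft(b))^2
  sp <- sp[seq_len(length(sp) %/% 2)]          # one-sided spectrum
  f <- (seq_along(sp) - 1) / (2 * length(sp)) * 200
  inBand <- f >= 30 & f <= 70
  stop1 <- f >= 1 & f <= 20
  stop2 <- f >= 80 & f <= 100
  expect_lt(mean(sp[stop1 | stop2]) / mean(sp[inBand]), 0.01)
})

test_that("running z-score standardizes, guards flats, tracks gain steps", {
  set.seed(2)
  n <- 200 * 60
  x <- rnorm(n, mean = 5, sd = 3)
  z <- runningZscore(x, 200, 30)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(var(z) - 1), 0.1)

  # constant input: epsilon-floored sd, output indistinguishable from 0
  expect_lt(max(abs(runningZscore(rep(4.2, n), 200, 30))), 1e-6)

  # amplitude doubles halfway: both halves come back near unit variance
  # (samples whose window straddles the step are excluded)
  n2 <- 200 * 120
  g <- c(rep(1, n2 / 2), rep(2, n2 / 2)) * rnorm(n2)
  zg <- runningZscore(g, 200, 30)
  margin <- 200 * 16
  expect_lt(abs(var(zg[seq_len(n2 / 2 - margin)]) - 1), 0.1)
  expect_lt(abs(var(zg[(n2 / 2 + margin):n2]) - 1), 0.1)

  expect_error(runningZscore(rnorm(100), 200, 30), "shorter")
})

test_that("preprocessSession composes deterministically with right shapes", {
  set.seed(3)
  rec <- RawRecording(matrix(rnorm(2 * 60 * rate), 2), rate,
                      c("chA", "chB"), "sess1")
  ft <- preprocessSession(rec)
  expect_s4_class(ft, "FeatureTensor")
  expect_equal(dim(featureValues(ft)), c(2L, 3L, 12000L))
  expect_equal(featureBands(ft), bandNames())
  expect_equal(samplingRate(ft), 200)

  ft2 <- preprocessSession(rec)
  expect_identical(featureValues(ft), featureValues(ft2))

  z <- preprocessSession(RawRecording(matrix(0, 1, 60 * rate), rate))
  expect_equal(max(abs(featureValues(z))), 0)
  expect_equal(dim(featureValues(z))[3], 12000L)
})

test_that("downsampling consistency holds for low-frequency content", {
  # a band-limited signal below 100 Hz: band-pass at 2 kHz then decimate
  # agrees with decimating first and band-passing at 200 Hz
  set.seed(4)
  n <- 30 * rate
  x <- signal::filtfilt(signal::butter(4, 40 / (rate / 2), "low"), rnorm(n))
  rec <- RawRecording(matrix(x, 1), rate)
  hi <- extractBand(rec, "1-30Hz")[1, ]
  xd <- x[seq(1, n, by = 10)]
  lo <- signal::filtfilt(signal::butter(3, c(1, 30) / 100, "pass"), xd)
  m <- 1000:5000
  expect_lt(sqrt(mean((hi[m] - lo[m])^2)) / sd(lo[m]), 0.1)
})
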