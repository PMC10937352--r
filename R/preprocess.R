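## Signal path: linear detrend, 500 Hz anti-alias, three band features
## (1-30 Hz, 30-70 Hz, 70-150 Hz Hilbert envelope) at 200 Hz, and the
## 30 s running z-score.
##
## All filters are Butterworth designs applied forward-backward
## (zero-phase), so the three band paths share one time axis with no
## relative group delay; the effective magnitude response of each
## design is |H|^2 and the effective order doubles.

FEATURE_RATE <- 200

## Design a 6-pole Butterworth bandpass (prototype order 3) and assert
## stability: every pole strictly inside the unit circle.
butterBand <- function(edges, rate, order = 3L) {
  flt <- signal::butter(order, edges / (rate / 2), type = "pass")
  assertStable(flt)
  flt
}

butterLow <- function(cutoff, rate, order = 4L) {
  assertThat(cutoff < rate / 2,
             "low-pass cutoff %g Hz is at or above Nyquist (%g Hz)",
             cutoff, rate / 2)
  flt <- signal::butter(order, cutoff / (rate / 2), type = "low")
  assertStable(flt)
  flt
}

assertStable <- function(flt) {
  poles <- polyroot(rev(flt$a))
  assertThat(all(Mod(poles) < 1),
             "designed filter is unstable (pole modulus %.6f)",
             max(Mod(poles)))
  invisible(flt)
}

## Zero-phase application to each row of a channels x time matrix.
filtRows <- function(x, flt) {
  t(apply(x, 1L, function(ch) signal::filtfilt(flt, ch)))
}

## Keep every (rate/FEATURE_RATE)-th sample, starting at the first, so
## all band paths land on one common 200 Hz time axis.
decimateRows <- function(x, factor) {
  idx <- seq(1L, ncol(x), by = factor)
  x[, idx, drop = FALSE]
}

decimFactor <- function(rate) {
  fac <- rate / FEATURE_RATE
  assertThat(abs(fac - round(fac)) < 1e-9,
             "rate %g is not an integer multiple of %d Hz", rate,
             FEATURE_RATE)
  as.integer(round(fac))
}

#' Linear detrend and 500 Hz anti-alias filtering
#'
#' Removes each channel's least-squares linear trend over the full
#' session and applies a zero-phase Butterworth low-pass at 500 Hz
#' (order 4 forward-backward, i.e. 8th-order effective magnitude).
#'
#' @param rec a [RawRecording-class] sampled at >= 1000 Hz.
#' @return a RawRecording of identical shape.
#' @export
detrendAntialias <- function(rec) {
  assertThat(is(rec, "RawRecording"), "rec must be a RawRecording")
  rate <- samplingRate(rec)
  assertThat(rate >= 1000, "rate %g < 1000 samples/s", rate)
  assertThat(rate > 2 * 500,
             "anti-alias cutoff 500 Hz is not below Nyquist at rate %g",
             rate)
  x <- voltages(rec)
  n <- ncol(x)
  # closed-form least-squares line removal, all channels at once
  tt <- seq_len(n) - (n + 1) / 2            # centered time, mean 0
  stt <- sum(tt * tt)
  slope <- (x %*% tt) / stt                 # per-channel slope
  x <- x - rowMeans(x) - slope %*% t(tt)
  flt <- butterLow(500, rate, order = 4L)
  x <- filtRows(x, flt)
  RawRecording(x, rate, channelIds(rec), sessionId(rec))
}

#' High-gamma (70-150 Hz) Hilbert envelope at 200 Hz
#'
#' Band-passes 70-150 Hz (6-pole Butterworth, zero phase), takes the
#' analytic-signal magnitude, applies a safety low-pass at 100 Hz to the
#' envelope so decimation cannot alias it, and keeps every tenth sample.
#'
#' @param rec a detrended/anti-aliased [RawRecording-class].
#' @return channels x time matrix of envelope amplitude at 200 Hz.
#' @export
extractHighGamma <- function(rec) {
  assertThat(is(rec, "RawRecording"), "rec must be a RawRecording")
  rate <- samplingRate(rec)
  fac <- decimFactor(rate)
  bp <- filtRows(voltages(rec), butterBand(c(70, 150), rate))
  env <- t(apply(bp, 1L, hilbertEnvelope))
  env <- filtRows(env, butterLow(100, rate, order = 4L))
  decimateRows(env, fac)
}

#' Low/mid band-pass component at 200 Hz
#'
#' Extracts the 1-30 Hz or 30-70 Hz component with a 6-pole zero-phase
#' Butterworth band-pass, then decimates to 200 Hz on the same time axis
#' as the high-gamma envelope.
#'
#' @param rec a detrended/anti-aliased [RawRecording-class].
#' @param band `"1-30Hz"` or `"30-70Hz"`.
#' @return channels x time matrix at 200 Hz.
#' @export
extractBand <- function(rec, band) {
  assertThat(is(rec, "RawRecording"), "rec must be a RawRecording")
  assertThat(band %in% c("1-30Hz", "30-70Hz"),
             "unsupported band '%s' (use 1-30Hz or 30-70Hz)", band)
  rate <- samplingRate(rec)
  fac <- decimFactor(rate)
  bp <- filtRows(voltages(rec), butterBand(bandEdges(band), rate))
  decimateRows(bp, fac)
}

#' Running z-score with a 30 s window
#'
#' Standardizes every channel x band series by its running mean and
#' standard deviation in a centered window (shrunk symmetrically at the
#' session edges). A floored standard deviation,
#' `max(sd, 1e-8 * global sd, 1e-12)`, guards flat segments against
#' division by zero, so constant input maps to all zeros.
#'
#' @param x numeric vector, matrix (series in rows), or 3-d array
#'   (channels x bands x time; time last).
#' @param rate series sampling rate in samples/s.
#' @param windowSeconds z-score window length (default 30).
#' @return object of the same shape, standardized.
#' @export
runningZscore <- function(x, rate = FEATURE_RATE, windowSeconds = 30) {
  half <- as.integer(round(windowSeconds * rate / 2))
  zs <- function(v) {
    n <- length(v)
    assertThat(n >= 2L * half + 1L,
               "series length %d is shorter than the %g s window", n,
               windowSeconds)
    v0 <- v - mean(v)                     # conditioning for the cumsums
    st <- runningStats(v0, half)
    g <- stats::sd(v0)
    floorSd <- pmax(st$sd, 1e-8 * ifelse(is.finite(g), g, 0), 1e-12)
    z <- (v0 - st$mean) / floorSd
    # windows that are flat to numerical precision have a zero numerator
    # by contract; snap them to exactly zero instead of noise/epsilon
    flat <- st$sd < pmax(1e-8 * g, 1e-6 * mean(abs(v)), 1e-300)
    z[flat] <- 0
    z
  }
  if (is.null(dim(x))) return(zs(x))
  if (length(dim(x)) == 2L) return(t(apply(x, 1L, zs)))
  out <- x
  for (i in seq_len(dim(x)[1])) for (j in seq_len(dim(x)[2])) {
    out[i, j, ] <- zs(x[i, j, ])
  }
  out
}

#' Full session preprocessing: raw recording to feature tensor
#'
#' Composes the signal path: linear detrend and 500 Hz anti-alias,
#' the 1-30 Hz and 30-70 Hz band-pass components and the 70-150 Hz
#' Hilbert envelope, decimation to a common 200 Hz axis, and the 30 s
#' running z-score. Deterministic given its input.
#'
#' @param rec a [RawRecording-class] at an integer multiple of 200 Hz
#'   (2000 Hz in the study design).
#' @param zscoreWindowSeconds running z-score window (default 30).
#' @return a [FeatureTensor-class], channels x 3 bands x time.
#' @export
#' @examples
#' rec <- RawRecording(matrix(rnorm(2 * 2000 * 31), nrow = 2), 2000)
#' ft <- preprocessSession(rec)
#' dim(featureValues(ft))
preprocessSession <- function(rec, zscoreWindowSeconds = 30) {
  rec <- detrendAntialias(rec)
  hg <- extractHighGamma(rec)
  b1 <- extractBand(rec, "1-30Hz")
  b2 <- extractBand(rec, "30-70Hz")
  stopifnot(ncol(hg) == ncol(b1), ncol(b1) == ncol(b2))
  vals <- array(0, dim = c(nrow(hg), 3L, ncol(hg)))
  vals[, 1L, ] <- b1
  vals[, 2L, ] <- b2
  vals[, 3L, ] <- hg
  vals <- runningZscore(vals, FEATURE_RATE, zscoreWindowSeconds)
  new("FeatureTensor", values = vals, rate = FEATURE_RATE,
      bands = bandNames(), channelIds = channelIds(rec),
      sessionId = sessionId(rec),
      metadata = list(
        sourceRate = samplingRate(rec),
        zscoreWindowSeconds = zscoreWindowSeconds,
        filters = list(
          antialias = "Butterworth low-pass 500 Hz, order 4, zero-phase",
          bands = "Butterworth band-pass, 6-pole, zero-phase",
          envelopeGuard = "Butterworth low-pass 100 Hz, order 4, zero-phase"
        )
      ))
}

#' Analytic Butterworth band-pass magnitude response
#'
#' Closed-form magnitude of the bilinear-transformed (digital)
#' Butterworth band-pass used by [extractBand()], evaluated at frequency
#' `f`: with v = tan(pi f / rate), the lowpass-prototype argument is
#' W = (v^2 - v1 v2) / (v (v2 - v1)) and |H| = 1/sqrt(1 + W^(2n)).
#' Forward-backward filtering squares this. Exposed as an independent
#' oracle for validating the filter implementation.
#'
#' @param f frequency in Hz (vectorized).
#' @param edges band edges in Hz, length 2.
#' @param rate sampling rate in Hz.
#' @param order prototype order n (default 3, a 6-pole band-pass).
#' @param zeroPhase if TRUE (default) return the forward-backward
#'   magnitude |H|^2.
#' @return magnitude gain at `f`.
#' @export
butterBandGain <- function(f, edges, rate, order = 3L, zeroPhase = TRUE) {
  v <- tan(pi * f / rate)
  v1 <- tan(pi * edges[1] / rate)
  v2 <- tan(pi * edges[2] / rate)
  W <- (v^2 - v1 * v2) / (v * (v2 - v1))
  g <- 1 / sqrt(1 + W^(2 * order))
  if (zeroPhase) g^2 else g
}
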