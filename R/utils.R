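## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so seeded internals never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a per-repeat seed from a base seed; stays inside 32-bit range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

#' Analytic signal via the FFT
#'
#' Constructs the analytic signal x + i * H(x) (H the Hilbert transform)
#' by zeroing negative frequencies and doubling positive ones.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analyticSignal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Envelope (instantaneous amplitude) of a band-limited series.
hilbertEnvelope <- function(x) Mod(analyticSignal(x))

## Centered running mean/sd with symmetric shrink at the edges:
## at sample i the half-width is min(half, i - 1, n - i), so windows
## near the boundary stay centered rather than lopsided.
runningStats <- function(x, halfWidth) {
  n <- length(x)
  i <- seq_len(n)
  h <- pmin(halfWidth, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x * x))
  lo <- i - h
  hi <- i + h
  cnt <- hi - lo + 1L
  m <- (cs[hi + 1L] - cs[lo]) / cnt
  v <- (cs2[hi + 1L] - cs2[lo]) / cnt - m * m
  v[v < 0] <- 0
  list(mean = m, sd = sqrt(v))
}

## stopifnot with a formatted message.
assertThat <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
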