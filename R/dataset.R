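## Dataset assembly: syllable-locked feature segments, sliding 200 ms
## windows, and session-wise train/test splits.

PAD_SECONDS <- 0.1      # context kept on each side of a syllable
WINDOW_SECONDS <- 0.2   # decoder input span

#' Subset a feature tensor by channels and/or bands
#'
#' Selects (and orders) channels and bands of a
#' [FeatureTensor-class]; used to restrict decoding to a brain
#' region's electrodes or to single feature bands, and to permute the
#' channel order fed to the decoder.
#'
#' @param ft a [FeatureTensor-class].
#' @param channels character channel ids (in the desired order), or
#'   NULL for all.
#' @param bands character band names, or NULL for all.
#' @return a [FeatureTensor-class].
#' @export
subsetFeatureTensor <- function(ft, channels = NULL, bands = NULL) {
  assertThat(is(ft, "FeatureTensor"), "ft must be a FeatureTensor")
  if (is.null(channels)) channels <- channelIds(ft)
  if (is.null(bands)) bands <- featureBands(ft)
  ci <- match(channels, channelIds(ft))
  assertThat(!anyNA(ci), "channel(s) not in tensor: %s",
             paste(channels[is.na(ci)], collapse = ", "))
  bi <- match(bands, featureBands(ft))
  assertThat(!anyNA(bi), "band(s) not in tensor: %s",
             paste(bands[is.na(bi)], collapse = ", "))
  new("FeatureTensor",
      values = ft@values[ci, bi, , drop = FALSE], rate = ft@rate,
      bands = bands, channelIds = channels, sessionId = ft@sessionId,
      metadata = ft@metadata)
}

#' Cut syllable-locked feature segments
#'
#' Extracts, for every event of the tensor's session, the feature slab
#' between onset and offset plus 100 ms of surrounding context on each
#' side. Context that would fall outside the session is filled by
#' edge-value replication (zeros would be extreme values after
#' z-scoring). Events outside the recording are rejected by name.
#'
#' @param ft a [FeatureTensor-class].
#' @param events event data.frame (see [readEvents()]); only rows whose
#'   `session_id` matches the tensor are used.
#' @return list of segments, in event order; each has elements `data`
#'   (channels x bands x padded-time array), `coreLength`, `pad`
#'   (samples per side), `label` ([labelSyllable()] result),
#'   `sessionId`, and `eventRow`.
#' @export
segmentEvents <- function(ft, events) {
  assertThat(is(ft, "FeatureTensor"), "ft must be a FeatureTensor")
  rate <- samplingRate(ft)
  pad <- as.integer(round(PAD_SECONDS * rate))
  nT <- dim(featureValues(ft))[3]
  ev <- events[events$session_id == sessionId(ft), , drop = FALSE]
  vals <- featureValues(ft)
  lapply(seq_len(nrow(ev)), function(i) {
    i0 <- as.integer(round(ev$onset_s[i] * rate)) + 1L
    i1 <- as.integer(round(ev$offset_s[i] * rate))
    assertThat(i0 >= 1L && i1 <= nT && i1 >= i0,
               "event %d ('%s' at %.3f s, session %s) exceeds recording bounds",
               i, ev$pinyin[i], ev$onset_s[i], sessionId(ft))
    idx <- pmin(pmax((i0 - pad):(i1 + pad), 1L), nT)  # edge replication
    list(data = vals[, , idx, drop = FALSE],
         coreLength = i1 - i0 + 1L, pad = pad,
         label = labelSyllable(ev$pinyin[i], ev$tone[i]),
         sessionId = sessionId(ft), eventRow = rownames(ev)[i])
  })
}

## Flatten a segment's channels x bands x time array to features x time.
flattenSegment <- function(segment) {
  d <- dim(segment$data)
  matrix(segment$data, nrow = d[1] * d[2], ncol = d[3])
}

#' Sliding 200 ms windows over one segment
#'
#' Emits one 40-sample (200 ms at 200 Hz) window per core sample of the
#' segment: window k spans padded samples \[k, k+40), so with the 100 ms
#' pads the window count equals the core length exactly (the last of
#' the L+1 stride-1 windows is dropped — an off-by-one forced by the
#' even window length). Every window's target is the segment's one-hot
#' label under `task`; window k's center sample is core sample k.
#'
#' @param segment one element of [segmentEvents()] output.
#' @param task `"place"`, `"manner"` or `"tone"`.
#' @param stride emit every `stride`-th window (1 = the full
#'   equal-length set; larger strides subsample windows for training).
#' @return `NULL` if the segment has no label under `task` (zero-initial
#'   syllable on a consonant task); else a list with `x` (features x
#'   nWindows x 40 array), `y` (K x nWindows one-hot matrix),
#'   `coreIndex` (1-based core sample of each window), `classIndex`,
#'   `sessionId`.
#' @export
makeWindows <- function(segment, task, stride = 1L) {
  k <- taskClassIndex(segment$label, task)
  if (is.na(k)) return(NULL)
  lv <- taskLevels(task)
  feat <- flattenSegment(segment)
  w <- as.integer(round(WINDOW_SECONDS * samplingRateOfSegment(segment)))
  L <- segment$coreLength
  assertThat(ncol(feat) == L + 2L * segment$pad,
             "segment padding inconsistent")
  starts <- seq.int(0L, L - 1L, by = stride)
  cols <- as.vector(outer(seq_len(w), starts, `+`))
  x <- array(feat[, cols], dim = c(nrow(feat), w, length(starts)))
  x <- aperm(x, c(1L, 3L, 2L))                 # features x nWin x 40
  y <- matrix(0, nrow = length(lv), ncol = length(starts))
  y[k, ] <- 1
  list(x = x, y = y, coreIndex = starts + 1L, classIndex = k,
       sessionId = segment$sessionId)
}

## The feature rate is fixed at 200 Hz; keep it in one place in case a
## segment ever carries its own rate.
samplingRateOfSegment <- function(segment) FEATURE_RATE

#' Session-wise train/test split
#'
#' Assigns whole sessions to the training or test side, so no temporal
#' neighborhood (nor any syllable) is shared between them. Deterministic
#' given `seed`.
#'
#' @param sessionIds character vector of session ids (duplicates
#'   allowed; the unique set is split).
#' @param trainFraction fraction of sessions assigned to training
#'   (default 0.8); at least one session lands on each side.
#' @param seed integer seed.
#' @return list with character vectors `train` and `test`.
#' @export
splitSessions <- function(sessionIds, trainFraction = 0.8, seed = 1) {
  ids <- unique(sessionIds)
  assertThat(length(ids) >= 2L,
             "session-wise splitting needs at least 2 sessions (got %d)",
             length(ids))
  assertThat(trainFraction > 0 && trainFraction < 1,
             "trainFraction must be in (0, 1)")
  nTrain <- min(max(round(trainFraction * length(ids)), 1L),
                length(ids) - 1L)
  withSeed(seed, {
    train <- sample(ids, nTrain)
    list(train = sort(train), test = sort(setdiff(ids, train)))
  })
}

## Concatenate pre-windowed items (list(x = D x n x 40, k, session))
## into one set: X cube features x N x 40 and one-hot Y (K x N).
bindItems <- function(items, K) {
  assertThat(length(items) > 0, "no labeled segments to bind")
  ns <- vapply(items, function(it) dim(it$x)[2], integer(1))
  D <- dim(items[[1]]$x)[1]
  w <- dim(items[[1]]$x)[3]
  X <- array(0, dim = c(D, sum(ns), w))
  Y <- matrix(0, K, sum(ns))
  at <- 0L
  for (it in items) {
    idx <- at + seq_len(dim(it$x)[2])
    X[, idx, ] <- it$x
    Y[it$k, idx] <- 1
    at <- at + length(idx)
  }
  list(x = X, y = Y, segment = rep(seq_along(items), ns),
       session = rep(vapply(items, `[[`, "", "session"), ns))
}
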