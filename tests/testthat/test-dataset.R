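# A small feature tensor with recognizable values for slicing checks.
mkTensor <- function(nCh = 2, nT = 2000, sid = "s1") {
  vals <- array(seq_len(nCh * 3 * nT) / 1000, dim = c(nCh, 3, nT))
  new("FeatureTensor", values = vals, rate = 200, bands = bandNames(),
      channelIds = paste0("ch", seq_len(nCh)), sessionId = sid,
      metadata = list())
}

mkEvents <- function(onsets, durations, pinyin, tone, sid = "s1") {
  data.frame(session_id = sid, onset_s = onsets,
             offset_s = onsets + durations, pinyin = pinyin, tone = tone,
             stringsAsFactors = FALSE)
}

test_that("segments carry 100 ms pads around the event core", {
  ft <- mkTensor()
  ev <- mkEvents(c(1.0, 3.0, 5.0), c(0.4, 0.3, 0.2),
                 c("ba", "ma", "zha"), c(1, 2, 3))
  segs <- segmentEvents(ft, ev)
  expect_length(segs, 3L)
  expect_equal(segs[[1]]$coreLength, 80L)          # 0.4 s at 200 Hz
  expect_equal(dim(segs[[1]]$data)[3], 80L + 40L)  # 20 pad samples each side
  expect_equal(segs[[1]]$pad, 20L)
  # order preserved, labels attached
  expect_equal(vapply(segs, function(s) s$label$pinyin, ""),
               c("ba", "ma", "zha"))
  # segment content matches the tensor slab
  i0 <- round(1.0 * 200) + 1
  expect_equal(segs[[1]]$data[, , 21], ft@values[, , i0])
})

test_that("events at the session edge use edge replication", {
  ft <- mkTensor()
  ev <- mkEvents(0, 0.3, "da", 1)
  seg <- segmentEvents(ft, ev)[[1]]
  # left pad columns replicate the first sample
  expect_equal(seg$data[, , 1], ft@values[, , 1])
  expect_equal(seg$data[, , 20], ft@values[, , 1])
  expect_equal(seg$data[, , 21], ft@values[, , 1])
})

test_that("events beyond the recording are rejected by name", {
  ft <- mkTensor(nT = 400)                          # 2 s of features
  ev <- mkEvents(1.8, 0.5, "ba", 1)
  expect_error(segmentEvents(ft, ev), "ba")
})

test_that("window count equals core length (equal-length contract)", {
  ft <- mkTensor(nT = 4000)
  for (L in c(37L, 40L, 80L, 200L)) {
    ev <- mkEvents(2.0, L / 200, "sha", 2)
    seg <- segmentEvents(ft, ev)[[1]]
    expect_equal(seg$coreLength, L)
    w <- makeWindows(seg, "place")
    expect_equal(dim(w$x), c(6L, L, 40L))           # 2 ch x 3 bands
    expect_equal(length(w$coreIndex), L)
  }
})

test_that("windows slide sample by sample from padded index zero", {
  ft <- mkTensor()
  seg <- segmentEvents(ft, mkEvents(1.0, 0.4, "ma", 3))[[1]]
  w <- makeWindows(seg, "tone")
  feat <- seegspeech:::flattenSegment(seg)
  expect_equal(w$x[, 1, ], feat[, 1:40])            # first window
  expect_equal(w$x[, 2, ], feat[, 2:41])            # stride 1
  # one-hot target: tone 3 -> unit vector at index 3 of 4
  expect_equal(w$y[, 1], c(0, 0, 1, 0))
  expect_true(all(colSums(w$y) == 1))
  # all examples of one syllable share one target
  expect_equal(unique(t(w$y)), matrix(c(0, 0, 1, 0), 1))
})

test_that("zero-initial syllables are skipped for consonant tasks only", {
  ft <- mkTensor()
  seg <- segmentEvents(ft, mkEvents(1.0, 0.4, "an", 4))[[1]]
  expect_null(makeWindows(seg, "place"))
  expect_null(makeWindows(seg, "manner"))
  expect_equal(makeWindows(seg, "tone")$classIndex, 4L)
})

test_that("session splits partition deterministically", {
  ids <- paste0("s", 1:5)
  sp <- splitSessions(ids, 0.8, seed = 9)
  expect_length(sp$train, 4L)
  expect_length(sp$test, 1L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, splitSessions(ids, 0.8, seed = 9))
  expect_false(identical(sp, splitSessions(ids, 0.8, seed = 10)))
  expect_error(splitSessions("s1", 0.8, 1), "2 sessions")
})

test_that("subsetFeatureTensor selects and orders channels and bands", {
  ft <- mkTensor(nCh = 3)
  sub <- subsetFeatureTensor(ft, channels = c("ch3", "ch1"),
                             bands = "70-150Hz")
  expect_equal(channelIds(sub), c("ch3", "ch1"))
  expect_equal(featureBands(sub), "70-150Hz")
  expect_equal(featureValues(sub)[1, 1, ], ft@values[3, 3, ])
  expect_error(subsetFeatureTensor(ft, channels = "nope"), "nope")
})
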