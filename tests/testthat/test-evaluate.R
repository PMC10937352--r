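fabricateResult <- function(correct, total, task = "tone") {
  seegspeech:::EvalResultNew(task, "thalamus", "70-150Hz",
                             correct / total, correct, total, NA_real_, 1L)
}

test_that("chanceTest is an exact binomial test against 1/K", {
  expect_gt(chanceTest(fabricateResult(25, 100)), 0.9)   # exactly at chance
  expect_lt(chanceTest(fabricateResult(60, 100)), 1e-10)
  # agreement with stats::binom.test on pooled counts
  r <- seegspeech:::EvalResultNew("place", "STG", "70-150Hz",
                                  c(0.3, 0.4), c(3, 4), c(10, 10),
                                  NA_real_, 1L)
  expect_equal(chanceTest(r), binom.test(7, 20, p = 1 / 7)$p.value)
  r0 <- seegspeech:::EvalResultNew("tone", "STG", "70-150Hz",
                                   numeric(0), integer(0), integer(0),
                                   NA_real_, 1L)
  expect_error(chanceTest(r0), "no test syllables")
})

test_that("chanceTest rejects at the nominal rate under the null", {
  set.seed(77)
  pvals <- vapply(seq_len(200), function(i) {
    chanceTest(fabricateResult(rbinom(1, 60, 0.25), 60))
  }, numeric(1))
  rejections <- sum(pvals < 0.05)
  expect_gte(rejections, qbinom(0.025, 200, 0.05))
  expect_lte(rejections, qbinom(0.975, 200, 0.05))
})

test_that("EvalResult invariants are enforced", {
  r <- fabricateResult(30, 60)
  expect_equal(chance(r), 0.25)
  expect_equal(accuracy(r), mean(perRepeat(r)))
  expect_error(new("EvalResult", task = "tone", regions = "STG",
                   bands = "70-150Hz", accuracy = 0.9, chance = 0.25,
                   nRepeats = 1L, perRepeatAccuracies = 0.5,
                   perRepeatCorrect = 5L, perRepeatTotal = 10L,
                   timepointAccuracy = NA_real_, seed = 1L),
               "mean per-repeat")
})

test_that("region evaluation is seeded, deterministic and validated", {
  sim <- nullStudy("tone", seed = 61, nSessions = 3, lengthS = 12)
  cfg <- nullDecoderConfig(maxEpochs = 3L)
  r1 <- evaluateRegion(sim$features, sim$events, sim$emap, "tone",
                       "thalamus", bands = "70-150Hz", nRepeats = 2,
                       seed = 5, config = cfg)
  r2 <- evaluateRegion(sim$features, sim$events, sim$emap, "tone",
                       "thalamus", bands = "70-150Hz", nRepeats = 2,
                       seed = 5, config = cfg)
  expect_identical(perRepeat(r1), perRepeat(r2))
  expect_equal(r1@nRepeats, 2L)
  expect_true(all(perRepeat(r1) >= 0 & perRepeat(r1) <= 1))
  expect_equal(chance(r1), chanceLevel("tone"))

  emapEmpty <- ElectrodeMap("only1", "STG")
  expect_error(evaluateRegion(sim$features, sim$events, emapEmpty, "tone",
                              "thalamus", nRepeats = 1, config = cfg),
               "no channels")
})

test_that("pair evaluation enforces cortical/subcortical roles", {
  sim <- nullStudy("tone", seed = 62, nSessions = 3, lengthS = 12)
  cfg <- nullDecoderConfig(maxEpochs = 2L)
  expect_error(evaluatePair(sim$features, sim$events, sim$emap, "tone",
                            "thalamus", "STG", nRepeats = 1, config = cfg),
               "not a cortical region")
  expect_error(evaluatePair(sim$features, sim$events, sim$emap, "tone",
                            "STG", "MTG", nRepeats = 1, config = cfg),
               "not a subcortical region")
  # a well-formed pair runs and reports a finite ratio and shared splits
  res <- evaluatePair(sim$features, sim$events, sim$emap, "tone",
                      "STG", "thalamus", bands = "70-150Hz",
                      nRepeats = 2, seed = 3, config = cfg,
                      channelPolicy = "random")
  expect_s4_class(res$pair, "EvalResult")
  expect_equal(res$pair@regions, c("STG", "thalamus"))
  expect_equal(res$pair@perRepeatTotal, res$corticalAlone@perRepeatTotal)
  expect_true(is.finite(res$improvementRatio) || is.na(res$improvementRatio))
})

test_that("duplicating an informative channel never hurts beyond noise", {
  cfg <- simConfig(nSessions = 4, sessionLengthSeconds = 18,
                   channelsPerRegion = 1, syllableRate = 40,
                   effects = list(effectSpec("tone", "thalamus",
                                             "70-150Hz", 3)),
                   corpus = taskBalancedCorpus("tone"), seed = 71)
  sim <- simulateRecordings(cfg)
  fts <- preprocessSessions(sim$recordings, zscoreWindowSeconds = 8)
  # clone the thalamus channel into a second, identical channel
  fts2 <- lapply(fts, function(ft) {
    i <- match("Th1", channelIds(ft))
    vals <- ft@values[c(seq_len(dim(ft@values)[1]), i), , , drop = FALSE]
    new("FeatureTensor", values = vals, rate = ft@rate, bands = ft@bands,
        channelIds = c(channelIds(ft), "Th2"), sessionId = ft@sessionId,
        metadata = ft@metadata)
  })
  emap2 <- ElectrodeMap(c(channelIds(sim$emap), "Th2"),
                        c(electrodeTable(sim$emap)$region, "thalamus"))
  dcfg <- nullDecoderConfig(hiddenUnits = 8L, maxEpochs = 10L,
                            patience = 3L)
  n <- 20
  r1 <- evaluateRegion(fts, sim$events, sim$emap, "tone", "thalamus",
                       bands = "70-150Hz", nRepeats = n, seed = 9,
                       config = dcfg)
  r2 <- evaluateRegion(fts2, sim$events, emap2, "tone", "thalamus",
                       bands = "70-150Hz", nRepeats = n, seed = 9,
                       config = dcfg)
  noiseBand <- sd(perRepeat(r1) - perRepeat(r2)) / sqrt(n)
  expect_gt(accuracy(r2) - accuracy(r1), -3 * max(noiseBand, 0.02))
})
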