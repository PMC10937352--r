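test_that("simulation is deterministic and structurally valid", {
  cfg <- simConfig(nSessions = 2, sessionLengthSeconds = 10,
                   channelsPerRegion = 1, syllableRate = 30,
                   effects = list(), seed = 33)
  s1 <- simulateRecordings(cfg)
  s2 <- simulateRecordings(cfg)
  expect_identical(voltages(s1$recordings[[1]]), voltages(s2$recordings[[1]]))
  expect_identical(s1$events, s2$events)

  expect_length(s1$recordings, 2L)
  expect_equal(dim(voltages(s1$recordings[[1]])), c(8L, 20000L))
  expect_equal(nrow(electrodeTable(s1$emap)), 8L)
  expect_silent(validateEvents(s1$events))
  # events fall inside their sessions and tones cover 1..4
  expect_true(all(s1$events$offset_s <= 10))
  expect_true(all(s1$events$tone %in% 1:4))

  cfg2 <- simConfig(nSessions = 2, sessionLengthSeconds = 10,
                    channelsPerRegion = 1, effects = list(), seed = 34)
  expect_false(identical(voltages(simulateRecordings(cfg2)$recordings[[1]]),
                         voltages(s1$recordings[[1]])))
})

test_that("background spectrum follows the configured 1/f exponent", {
  cfg <- simConfig(nSessions = 2, sessionLengthSeconds = 20,
                   channelsPerRegion = 1, syllableRate = 30,
                   effects = list(effectSpec("tone", "thalamus",
                                             "70-150Hz", 2)),
                   seed = 44)
  sim <- simulateRecordings(cfg)
  rep1 <- verifySpectrum(sim$recordings[[1]], sim)
  expect_gt(rep1$spectralSlope, -1.2)
  expect_lt(rep1$spectralSlope, -0.8)
})

test_that("event-locked envelope contrast matches the configured effect", {
  cfg <- simConfig(nSessions = 2, sessionLengthSeconds = 30,
                   channelsPerRegion = 1, syllableRate = 40,
                   effects = list(effectSpec("tone", "thalamus",
                                             "70-150Hz", 2)),
                   seed = 45)
  sim <- simulateRecordings(cfg)
  ms <- vapply(sim$recordings,
               function(r) verifySpectrum(r, sim)$contrasts$measured,
               numeric(1))
  m <- mean(ms)
  expect_gt(m, 1.6)
  expect_lt(m, 2.4)
})

test_that("zero effect size leaves the envelope contrast at zero", {
  cfg <- simConfig(nSessions = 2, sessionLengthSeconds = 20,
                   channelsPerRegion = 1, syllableRate = 40,
                   effects = list(effectSpec("tone", "thalamus",
                                             "70-150Hz", 0)),
                   seed = 46)
  sim <- simulateRecordings(cfg)
  m <- verifySpectrum(sim$recordings[[1]], sim)$contrasts$measured
  expect_lt(abs(m), 0.35)
})

test_that("task-balanced corpora equalize class frequencies", {
  for (task in c("place", "manner", "tone")) {
    corp <- taskBalancedCorpus(task)
    idx <- vapply(seq_len(nrow(corp)), function(i)
      seegspeech:::taskClassIndex(labelSyllable(corp$pinyin[i],
                                                corp$tone[i]), task),
      integer(1))
    expect_equal(length(unique(table(idx))), 1L)  # all classes equal
    expect_length(unique(idx), length(seegspeech:::taskLevels(task)))
  }
})

test_that("simulation output files are readable by the pipeline readers", {
  cfg <- simConfig(nSessions = 2, sessionLengthSeconds = 6,
                   channelsPerRegion = 1, syllableRate = 30,
                   effects = list(), seed = 50)
  sim <- simulateRecordings(cfg)
  dir <- tempfile()
  writeSimulation(sim, dir)
  expect_setequal(list.files(dir),
                  c("session01.edf", "session02.edf", "events.tsv",
                    "electrodes.tsv"))
  rec <- readEDF(file.path(dir, "session01.edf"))
  expect_equal(channelIds(rec), channelIds(sim$recordings[[1]]))
  qstep <- apply(abs(voltages(sim$recordings[[1]])), 1, max) * 2 / 65535
  expect_true(all(abs(voltages(rec) - voltages(sim$recordings[[1]])) <=
                  qstep))
  ev <- readEvents(file.path(dir, "events.tsv"))
  expect_equal(nrow(ev), nrow(sim$events))
  em <- readElectrodes(file.path(dir, "electrodes.tsv"))
  expect_equal(electrodeTable(em), electrodeTable(sim$emap))
  unlink(dir, recursive = TRUE)
})

test_that("end-to-end accuracy recovers effect size monotonically", {
  # core generator contract: over shared split seeds, decoding accuracy
  # is nondecreasing in the injected effect size
  accs <- vapply(c(0, 1, 3), function(es) {
    cfg <- simConfig(nSessions = 4, sessionLengthSeconds = 18,
                     channelsPerRegion = 1, syllableRate = 40,
                     effects = list(effectSpec("tone", "thalamus",
                                               "70-150Hz", es)),
                     corpus = taskBalancedCorpus("tone"), seed = 90)
    sim <- simulateRecordings(cfg)
    fts <- preprocessSessions(sim$recordings, zscoreWindowSeconds = 8)
    accuracy(evaluateRegion(fts, sim$events, sim$emap, "tone",
                            "thalamus", bands = "70-150Hz",
                            nRepeats = 20, seed = 15,
                            config = nullDecoderConfig(hiddenUnits = 8L,
                                                       maxEpochs = 10L,
                                                       patience = 3L)))
  }, numeric(1))
  expect_gte(accs[2], accs[1])
  expect_gte(accs[3], accs[2])
  expect_gt(accs[3], chanceLevel("tone"))
})

test_that("invalid simulation configs are rejected", {
  expect_error(simConfig(nSessions = 1), "2 sessions")
  expect_error(simConfig(channelsPerRegion = c(STG = 2, foo = 1)),
               "unknown region")
  expect_error(effectSpec("tone", "STG2"), "unknown region")
  expect_error(effectSpec("tone", "STG", effectSize = -1), ">= 0")
  expect_error(simConfig(channelsPerRegion = c(STG = 0),
                         effects = list(effectSpec("tone", "STG"))),
               "no channels")
})
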