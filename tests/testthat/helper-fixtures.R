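# Shared fixture builders: everything is generated in code at test time.

# Fabricated labeled segment: one channel, one band, Gaussian noise with
# a class-dependent mean shift (in units of the noise sd), centered so
# the overall feature scale resembles z-scored data.
toySegment <- function(k, sid, coreLength = 50, shift = 3, K = 4,
                       D = 1L) {
  arr <- array(stats::rnorm(D * (coreLength + 40)),
               dim = c(D, 1L, coreLength + 40))
  arr <- arr + shift * (k - 1) - shift * (K - 1) / 2
  list(data = arr, coreLength = as.integer(coreLength), pad = 20L,
       label = labelSyllable("a", k), sessionId = sid)
}

# A small set of separable segments over several sessions (tone task).
toySegmentSet <- function(nSessions = 4, perSession = 12, coreLength = 50,
                          shift = 3, seed = 3) {
  set.seed(seed)
  segs <- list()
  truth <- integer(0)
  for (s in seq_len(nSessions)) {
    for (i in seq_len(perSession)) {
      k <- sample(4L, 1L)
      truth <- c(truth, k)
      segs <- c(segs, list(toySegment(k, sprintf("s%d", s), coreLength,
                                      shift)))
    }
  }
  list(segments = segs, truth = truth)
}

# Decoder config small enough for test-time training.
toyDecoderConfig <- function(...) {
  args <- utils::modifyList(
    list(hiddenUnits = 8L, layers = 3L, maxEpochs = 40L, patience = 8L,
         trainStride = 3L, batchSize = 64L, seed = 7L),
    list(...))
  do.call(decoderConfig, args)
}

# Tiny no-effect study for null checks (per-task balanced corpus).
nullStudy <- function(task, seed, nSessions = 4, lengthS = 18,
                      channelsPerRegion = 1) {
  cfg <- simConfig(nSessions = nSessions, sessionLengthSeconds = lengthS,
                   channelsPerRegion = channelsPerRegion,
                   syllableRate = 40,
                   effects = list(effectSpec(task, "STG", "70-150Hz", 0)),
                   corpus = taskBalancedCorpus(task), seed = seed)
  sim <- simulateRecordings(cfg)
  sim$features <- preprocessSessions(sim$recordings,
                                     zscoreWindowSeconds = 8)
  sim
}

# Signal study under the default scenario (effect size 3 in the
# 70-150 Hz band: place -> STG, manner -> STG + thalamus,
# tone -> thalamus), with the corpus balanced for the task under test.
# STG carries three contacts (place then occupies two of them under the
# round-robin effect assignment); other regions carry two.
signalStudy <- function(task, seed, effectSize = 3, nSessions = 6,
                        lengthS = 36) {
  cpr <- stats::setNames(rep(2L, 8), brainRegions())
  cpr[["STG"]] <- 3L
  cfg <- simConfig(nSessions = nSessions, sessionLengthSeconds = lengthS,
                   channelsPerRegion = cpr, syllableRate = 30,
                   effects = defaultScenario(effectSize),
                   corpus = taskBalancedCorpus(task), seed = seed)
  sim <- simulateRecordings(cfg)
  sim$features <- preprocessSessions(sim$recordings,
                                     zscoreWindowSeconds = 10)
  sim
}

# Evaluation-scale decoder config (shared by the ordering checks).
evalDecoderConfig <- function(...) {
  args <- utils::modifyList(
    list(hiddenUnits = 8L, layers = 3L, maxEpochs = 22L, patience = 3L,
         trainStride = 8L, batchSize = 256L),
    list(...))
  do.call(decoderConfig, args)
}

# Fast config for null-calibration runs: no-signal fits stop early.
nullDecoderConfig <- function(...) {
  args <- utils::modifyList(
    list(hiddenUnits = 6L, layers = 3L, maxEpochs = 6L, patience = 2L,
         trainStride = 8L, batchSize = 256L),
    list(...))
  do.call(decoderConfig, args)
}

# Acceptance band (two-sided) for a pooled null accuracy: the count
# interval covering `conf` of Binomial(n, chance), as proportions.
nullBand <- function(n, chance, conf = 0.95) {
  a <- (1 - conf) / 2
  c(qbinom(a, n, chance), qbinom(1 - a, n, chance)) / n
}
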