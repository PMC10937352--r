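## Synthetic sEEG generator: 1/f background noise, session structure,
## Mandarin syllable events, and region/band-specific class information
## carried by event-locked gain on the in-band signal component.
##
## Class information rides on band AMPLITUDE (envelope), matching the
## pipeline's power/envelope features: during an event of class index k
## (0-based within the effect's task), the targeted band's component on
## the targeted region's channels is scaled by
##   1 + k * effectSize * sd(envelope) / mean(envelope),
## under a Tukey window, so the Hilbert envelope is elevated by exactly
## k * effectSize baseline standard deviations at the window plateau.

#' Specify one region/band class effect
#'
#' @param task `"place"`, `"manner"` or `"tone"` — which label the
#'   effect encodes.
#' @param region targeted brain region (see [brainRegions()]).
#' @param band targeted feature band (see [bandNames()]).
#' @param effectSize standardized envelope separation between adjacent
#'   classes, in units of the baseline envelope sd (>= 0).
#' @param latencySeconds offset of the modulation from syllable onset.
#' @return a validated effect specification list.
#' @export
effectSpec <- function(task, region, band = "70-150Hz", effectSize = 3,
                       latencySeconds = 0) {
  taskLevels(task)
  assertThat(region %in% brainRegions(), "unknown region '%s'", region)
  bandEdges(band)
  assertThat(effectSize >= 0, "effectSize must be >= 0")
  list(task = task, region = region, band = band,
       effectSize = effectSize, latencySeconds = latencySeconds)
}

#' Default simulation scenario
#'
#' Three high-gamma effects mirroring the qualitative regional findings
#' of the study design: articulatory place coded in the superior
#' temporal gyrus, manner in STG and thalamus, tone in the thalamus.
#'
#' @param effectSize standardized per-class separation (default 3).
#' @return list of [effectSpec()] entries.
#' @export
defaultScenario <- function(effectSize = 3) {
  list(
    effectSpec("place", "STG", "70-150Hz", effectSize),
    effectSpec("manner", "STG", "70-150Hz", effectSize),
    effectSpec("manner", "thalamus", "70-150Hz", effectSize),
    effectSpec("tone", "thalamus", "70-150Hz", effectSize)
  )
}

#' Simulation configuration
#'
#' Defines the synthetic recording conditions: session structure,
#' per-region channel counts, syllable event statistics, the 1/f
#' background, and the list of class effects.
#'
#' @param nSessions number of recording sessions (>= 2 so session-wise
#'   splits exist).
#' @param sessionLengthSeconds whole-second session duration.
#' @param channelsPerRegion named integer vector (names from
#'   [brainRegions()]); unnamed scalar = that many channels in every
#'   region.
#' @param syllableRate syllable events per minute.
#' @param syllableDurationSeconds (min, max) uniform syllable duration.
#' @param backgroundExponent 1/f^a spectral exponent of the background.
#' @param backgroundAmplitude background standard deviation in
#'   microvolts.
#' @param effects list of [effectSpec()] entries (default
#'   [defaultScenario()]).
#' @param corpus optional data.frame with columns `pinyin`, `tone`; by
#'   default the uniform 21-initial x 4-tone inventory (initial + "a").
#' @param rate sampling rate, samples/s.
#' @param seed integer seed fixing every random draw.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(nSessions = 6, sessionLengthSeconds = 60,
                      channelsPerRegion = 2, syllableRate = 40,
                      syllableDurationSeconds = c(0.25, 0.4),
                      backgroundExponent = 1, backgroundAmplitude = 20,
                      effects = defaultScenario(), corpus = NULL,
                      rate = 2000, seed = 1) {
  if (is.null(names(channelsPerRegion))) {
    assertThat(length(channelsPerRegion) == 1L,
               "channelsPerRegion must be named or a single count")
    channelsPerRegion <- stats::setNames(
      rep(as.integer(channelsPerRegion), length(brainRegions())),
      brainRegions())
  }
  assertThat(all(names(channelsPerRegion) %in% brainRegions()),
             "unknown region(s) in channelsPerRegion: %s",
             paste(setdiff(names(channelsPerRegion), brainRegions()),
                   collapse = ", "))
  assertThat(nSessions >= 2, "need at least 2 sessions")
  assertThat(all(syllableDurationSeconds > 0) &&
             diff(syllableDurationSeconds) >= 0,
             "syllable durations must be positive (min, max)")
  assertThat(sessionLengthSeconds == round(sessionLengthSeconds),
             "sessionLengthSeconds must be whole seconds")
  for (ef in effects) {
    assertThat(ef$region %in% names(channelsPerRegion) &&
               channelsPerRegion[[ef$region]] > 0,
               "effect targets region '%s' with no channels", ef$region)
  }
  if (is.null(corpus)) {
    corpus <- expand.grid(initial = consonantInventory()$pinyin,
                          tone = toneCategories(),
                          stringsAsFactors = FALSE)
    corpus <- data.frame(pinyin = paste0(corpus$initial, "a"),
                         tone = corpus$tone, stringsAsFactors = FALSE)
  }
  structure(list(
    nSessions = as.integer(nSessions),
    sessionLengthSeconds = sessionLengthSeconds,
    channelsPerRegion = channelsPerRegion,
    syllableRate = syllableRate,
    syllableDurationSeconds = syllableDurationSeconds,
    backgroundExponent = backgroundExponent,
    backgroundAmplitude = backgroundAmplitude,
    effects = effects, corpus = corpus,
    rate = rate, seed = as.integer(seed)
  ), class = "SimConfig")
}

#' Corpus with balanced classes for one task
#'
#' The uniform 21-initial corpus has unequal marginal class frequencies
#' (e.g. five initials are voiceless fricatives but only one is a
#' lateral), so a no-signal decoder that learns class priors can sit
#' away from 1/K on it. This helper builds a corpus whose rows repeat
#' each initial inversely to its class size, making every category of
#' `task` exactly equiprobable — the design under which the exact
#' chance level 1/K (and a binomial null around it) holds.
#'
#' @param task `"place"`, `"manner"` or `"tone"`.
#' @return data.frame with columns `pinyin`, `tone`, usable as the
#'   `corpus` argument of [simConfig()].
#' @export
taskBalancedCorpus <- function(task) {
  inv <- consonantInventory()
  if (task == "tone") {
    reps <- rep(1L, nrow(inv))          # tone is uniform by construction
  } else {
    cls <- as.character(inv[[task]])
    counts <- table(cls)
    mult <- Reduce(lcm2, as.integer(counts))
    reps <- as.integer(mult / counts[cls])
  }
  corpus <- expand.grid(i = rep(seq_len(nrow(inv)), reps),
                        tone = toneCategories())
  data.frame(pinyin = paste0(inv$pinyin[corpus$i], "a"),
             tone = corpus$tone, stringsAsFactors = FALSE)
}

lcm2 <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a / g(a, b) * b
}

## 1/f^a Gaussian noise via FFT amplitude shaping, scaled to sd = amp.
onefNoise <- function(n, rate, exponent, amp) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1e-12, seq_len(n - 1)) * rate / n
  f[-1] <- pmin(f[-1], rate - f[-1])   # two-sided frequency axis
  shape <- f^(-exponent / 2)
  shape[1] <- 0                        # no DC power
  y <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  amp * y / stats::sd(y)
}

## Tukey (tapered cosine) window: flat plateau with cosine ramps.
tukeyWindow <- function(n, alpha = 0.4) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  ramp <- alpha / 2
  lo <- t < ramp
  hi <- t > 1 - ramp
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / ramp - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + ramp) / ramp)))
  w
}

#' Generate a synthetic sEEG study
#'
#' Produces per-session [RawRecording-class] objects with 1/f
#' background noise, a syllable event table drawn from the configured
#' corpus (balanced by cycling a shuffled corpus), an
#' [ElectrodeMap-class], and the configured class effects injected as
#' event-locked band-limited gain. Deterministic given `config$seed`.
#'
#' @param config a [simConfig()].
#' @return list with elements `recordings` (list of RawRecording),
#'   `events` (data.frame), `emap` ([ElectrodeMap-class]), and `config`.
#' @export
#' @examples
#' sim <- simulateRecordings(simConfig(nSessions = 2,
#'   sessionLengthSeconds = 8, channelsPerRegion = 1,
#'   effects = list(), seed = 7))
#' sim$recordings[[1]]
simulateRecordings <- function(config) {
  assertThat(inherits(config, "SimConfig"), "config must come from simConfig()")
  withSeed(config$seed, {
    rate <- config$rate
    lenS <- config$sessionLengthSeconds
    n <- as.integer(round(lenS * rate))
    cpr <- config$channelsPerRegion
    regions <- rep(names(cpr), cpr)
    abbrev <- c(ITG = "ITG", MTG = "MTG", STG = "STG", thalamus = "Th",
                `insular gyrus` = "IG", amygdala = "Amy",
                `parahippocampal gyrus` = "PhG", hippocampus = "Hipp")
    chIds <- unlist(lapply(names(cpr), function(r) {
      if (cpr[[r]] == 0) return(character(0))
      paste0(abbrev[[r]], seq_len(cpr[[r]]))
    }))
    emap <- ElectrodeMap(chIds, regions)

    nEvPerSession <- max(1L, floor(config$syllableRate / 60 * lenS))
    nEvTotal <- nEvPerSession * config$nSessions
    # labels drawn iid uniform over the corpus: keeps sessions
    # statistically exchangeable, so a no-signal decoder cannot be
    # pushed off chance by train/test composition dependence
    corpus <- config$corpus
    pool <- corpus[sample.int(nrow(corpus), nEvTotal, replace = TRUE), ,
                   drop = FALSE]

    recordings <- vector("list", config$nSessions)
    eventRows <- list()
    for (s in seq_len(config$nSessions)) {
      sid <- sprintf("session%02d", s)
      x <- t(vapply(seq_along(chIds), function(i)
        onefNoise(n, rate, config$backgroundExponent,
                  config$backgroundAmplitude),
        numeric(n)))

      # non-overlapping events on a jittered grid
      slot <- lenS / nEvPerSession
      dur <- stats::runif(nEvPerSession, config$syllableDurationSeconds[1],
                          config$syllableDurationSeconds[2])
      margin <- pmax(slot - dur - 0.1, 0)
      onset <- (seq_len(nEvPerSession) - 1) * slot + 0.05 +
        stats::runif(nEvPerSession) * margin
      offset <- pmin(onset + dur, lenS - 1 / rate)
      lab <- pool[(s - 1L) * nEvPerSession + seq_len(nEvPerSession), ]
      ev <- data.frame(session_id = sid, onset_s = onset,
                       offset_s = offset, pinyin = lab$pinyin,
                       tone = as.integer(lab$tone),
                       stringsAsFactors = FALSE)
      labels <- lapply(seq_len(nrow(ev)),
                       function(i) labelSyllable(ev$pinyin[i], ev$tone[i]))

      # effects sharing a region take disjoint channel subsets
      # (round-robin), emulating spatially segregated coding
      # populations under different contacts of one electrode shaft
      regionEffects <- vapply(config$effects, `[[`, "", "region")
      for (iEf in seq_along(config$effects)) {
        ef <- config$effects[[iEf]]
        if (ef$effectSize == 0) next
        chans <- which(regions == ef$region)
        peers <- which(regionEffects == ef$region)
        if (length(peers) > 1L && length(chans) >= length(peers)) {
          slot <- match(iEf, peers)
          chans <- chans[seq(slot, length(chans), by = length(peers))]
        }
        flt <- butterBand(bandEdges(ef$band), rate)
        for (ch in chans) {
          bp <- signal::filtfilt(flt, x[ch, ])
          env <- hilbertEnvelope(bp)
          m0 <- mean(env)
          s0 <- stats::sd(env)
          gainPerClass <- ef$effectSize * s0 / m0
          for (i in seq_len(nrow(ev))) {
            k <- taskClassIndex(labels[[i]], ef$task) - 1L
            if (is.na(k) || k == 0L) next
            i0 <- max(1L, as.integer(round((ev$onset_s[i] +
                                            ef$latencySeconds) * rate)) + 1L)
            i1 <- min(n, as.integer(round((ev$offset_s[i] +
                                           ef$latencySeconds) * rate)))
            if (i1 <= i0) next
            w <- tukeyWindow(i1 - i0 + 1L)
            x[ch, i0:i1] <- x[ch, i0:i1] + k * gainPerClass * w * bp[i0:i1]
          }
        }
      }
      recordings[[s]] <- RawRecording(x, rate, chIds, sid)
      eventRows[[s]] <- ev
    }
    events <- do.call(rbind, eventRows)
    rownames(events) <- NULL
    validateEvents(events)
    list(recordings = recordings, events = events, emap = emap,
         config = config)
  })
}

#' Write a simulated study to disk
#'
#' Emits one EDF file per session plus `events.tsv` and
#' `electrodes.tsv` — exactly the formats the rest of the pipeline
#' reads.
#'
#' @param sim result of [simulateRecordings()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in sim$recordings) {
    writeEDF(rec, file.path(dir, paste0(sessionId(rec), ".edf")))
  }
  writeEvents(sim$events, file.path(dir, "events.tsv"))
  writeElectrodes(sim$emap, file.path(dir, "electrodes.tsv"))
  invisible(dir)
}

#' Diagnostic checks of a simulated recording
#'
#' Verifies two generator contracts on a recording: (1) the background
#' spectrum follows the configured 1/f exponent — fitted as the log-log
#' slope of the channel-averaged periodogram over 2-150 Hz; (2) each
#' configured effect produces the intended standardized event-locked
#' envelope contrast — measured as the regression slope of per-event
#' envelope elevation (central 60% of the event, in baseline sd units)
#' on the event's 0-based class index.
#'
#' @param rec one [RawRecording-class] from the simulation.
#' @param sim the full [simulateRecordings()] result (for events,
#'   electrode map and config).
#' @return list with `spectralSlope` (expected about minus the
#'   configured exponent) and `contrasts` (data.frame: task, region,
#'   band, effectSize, measured slope).
#' @export
verifySpectrum <- function(rec, sim) {
  config <- sim$config
  emap <- electrodeTable(sim$emap)
  x <- voltages(rec)
  rate <- samplingRate(rec)
  n <- ncol(x)

  effectRegions <- unique(vapply(config$effects, `[[`, "", "region"))
  quiet <- which(!emap$region %in% effectRegions)
  if (length(quiet) == 0) quiet <- seq_len(nrow(x))
  f <- seq_len(n %/% 2) * rate / n
  keep <- f >= 2 & f <= 150
  pmean <- rowMeans(vapply(quiet, function(ch) {
    (Mod(stats::fft(x[ch, ]))^2 / n)[seq_len(n %/% 2) + 1L]
  }, numeric(n %/% 2)))
  fit <- stats::lm(log10(pmean[keep]) ~ log10(f[keep]))
  slope <- unname(stats::coef(fit)[2])

  ev <- sim$events[sim$events$session_id == sessionId(rec), ]
  labels <- lapply(seq_len(nrow(ev)),
                   function(i) labelSyllable(ev$pinyin[i], ev$tone[i]))
  rows <- lapply(config$effects, function(ef) {
    chans <- which(emap$region == ef$region)
    flt <- butterBand(bandEdges(ef$band), rate)
    slopes <- vapply(chans, function(ch) {
      env <- hilbertEnvelope(signal::filtfilt(flt, x[ch, ]))
      inEvent <- rep(FALSE, n)
      for (i in seq_len(nrow(ev))) {
        i0 <- max(1L, as.integer(round((ev$onset_s[i] - 0.1) * rate)))
        i1 <- min(n, as.integer(round((ev$offset_s[i] + 0.1) * rate)))
        inEvent[i0:i1] <- TRUE
      }
      m0 <- mean(env[!inEvent])
      s0 <- stats::sd(env[!inEvent])
      kk <- cc <- numeric(0)
      for (i in seq_len(nrow(ev))) {
        k <- taskClassIndex(labels[[i]], ef$task) - 1L
        if (is.na(k)) next
        i0 <- as.integer(round((ev$onset_s[i] + ef$latencySeconds) * rate)) + 1L
        i1 <- as.integer(round((ev$offset_s[i] + ef$latencySeconds) * rate))
        len <- i1 - i0 + 1L
        core <- i0 + as.integer(round(0.2 * len)):as.integer(round(0.8 * len))
        core <- core[core >= 1 & core <= n]
        kk <- c(kk, k)
        cc <- c(cc, (mean(env[core]) - m0) / s0)
      }
      if (length(unique(kk)) < 2) return(NA_real_)
      unname(stats::coef(stats::lm(cc ~ kk))[2])
    }, numeric(1))
    data.frame(task = ef$task, region = ef$region, band = ef$band,
               effectSize = ef$effectSize,
               measured = mean(slopes, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  list(spectralSlope = slope, contrasts = do.call(rbind, rows))
}
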