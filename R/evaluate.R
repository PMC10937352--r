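## Single-region and cortical+subcortical pair evaluation: repeated
## session-wise splits, per-repeat decoder training, syllable-level
## accuracy against exact chance levels, band comparison and the
## improvement ratio of pairing a subcortical channel with a cortical
## one.
##
## Window tensors are built once per evaluation (buildTaskData) and
## reused across split repeats; per repeat only the channel order is
## permuted (a row permutation of the cached tensors) and a fresh
## decoder is trained.

#' Preprocess every session of a study
#'
#' Convenience wrapper applying [preprocessSession()] to each recording
#' and keying the result by session id.
#'
#' @param recordings list of [RawRecording-class] objects.
#' @param zscoreWindowSeconds running z-score window.
#' @return named list of [FeatureTensor-class] objects.
#' @export
preprocessSessions <- function(recordings, zscoreWindowSeconds = 30) {
  fts <- lapply(recordings, preprocessSession,
                zscoreWindowSeconds = zscoreWindowSeconds)
  stats::setNames(fts, vapply(fts, sessionId, ""))
}

## Pre-windowed dataset for one task over a fixed channel/band subset:
## per labeled segment, the strided training windows and the full
## stride-1 test windows, plus class index and session.
buildTaskData <- function(features, events, task, channels, bands,
                          trainStride) {
  items <- list()
  for (sid in names(features)) {
    segs <- segmentEvents(subsetFeatureTensor(features[[sid]], channels,
                                              bands), events)
    for (seg in segs) {
      k <- taskClassIndex(seg$label, task)
      if (is.na(k)) next
      wTrain <- makeWindows(seg, task, stride = trainStride)
      wTest <- if (trainStride == 1L) wTrain
               else makeWindows(seg, task, stride = 1L)
      items[[length(items) + 1L]] <-
        list(xTrain = wTrain$x, xTest = wTest$x, k = k, session = sid)
    }
  }
  assertThat(length(items) > 0, "no labeled segments for task '%s'", task)
  list(items = items, nCh = length(channels), nBands = length(bands),
       K = length(taskLevels(task)),
       sessions = unique(names(features)))
}

## Feature-row permutation corresponding to a channel permutation
## (rows are channel-major within each band).
channelRowPerm <- function(perm, nBands) {
  nCh <- length(perm)
  as.vector(outer(perm, (seq_len(nBands) - 1L) * nCh, `+`))
}

## Majority-vote test of a trained decoder on cached test items.
scoreItems <- function(model, items, rows) {
  cfg <- model@config
  K <- length(model@classLevels)
  ns <- vapply(items, function(it) dim(it$xTest)[2], integer(1))
  D <- length(rows)
  X <- array(0, dim = c(D, sum(ns), dim(items[[1]]$xTest)[3]))
  at <- 0L
  for (it in items) {
    X[, at + seq_len(dim(it$xTest)[2]), ] <- it$xTest[rows, , , drop = FALSE]
    at <- at + dim(it$xTest)[2]
  }
  tstar <- readoutStep(structure(cfg, class = "DecoderConfig"))
  scores <- matrix(0, K, sum(ns))
  for (s in seq(1L, sum(ns), by = 2048L)) {
    idx <- s:min(sum(ns), s + 2047L)
    scores[, idx] <- cpp_blstm_predict(model@params, D, cfg$hiddenUnits,
                                       cfg$layers, K,
                                       X[, idx, , drop = FALSE], tstar)
  }
  bounds <- c(0L, cumsum(ns))
  correct <- 0L
  tp <- numeric(length(items))
  for (i in seq_along(items)) {
    sc <- scores[, (bounds[i] + 1L):bounds[i + 1L], drop = FALSE]
    correct <- correct + as.integer(unname(classifySyllable(sc)) ==
                                    items[[i]]$k)
    tp[i] <- mean(apply(sc, 2L, which.max) == items[[i]]$k)
  }
  list(correct = correct, total = length(items),
       timepointAccuracy = mean(tp))
}

## One split repeat on a cached task dataset.
runRepeat <- function(td, task, repSeed, config, trainFraction) {
  split <- splitSessions(td$sessions, trainFraction, seed = repSeed)
  perm <- withSeed(deriveSeed(repSeed, 13L), sample.int(td$nCh))
  rows <- channelRowPerm(perm, td$nBands)
  cfg <- config
  cfg$seed <- deriveSeed(repSeed, 29L)
  trainItems <- lapply(Filter(function(it) it$session %in% split$train,
                              td$items),
                       function(it) list(x = it$xTrain[rows, , ,
                                                       drop = FALSE],
                                         k = it$k, session = it$session))
  testItems <- Filter(function(it) it$session %in% split$test, td$items)
  assertThat(length(testItems) > 0, "no labeled test syllables")
  model <- trainDecoderFromWindows(trainItems, task, cfg)
  c(scoreItems(model, testItems, rows), list(model = model, split = split))
}

#' Decoding accuracy of a single brain region
#'
#' For each of `nRepeats` seeded repeats: draw a fresh session-wise
#' train/test split, shuffle the region's channel order, train a
#' decoder on the region's channels restricted to `bands`, and measure
#' syllable-level test accuracy (majority vote over per-timepoint
#' predictions). Deterministic given `seed`.
#'
#' @param features named list of [FeatureTensor-class] per session
#'   (see [preprocessSessions()]).
#' @param events syllable event data.frame.
#' @param emap an [ElectrodeMap-class].
#' @param task `"place"`, `"manner"` or `"tone"`.
#' @param region brain region to decode from.
#' @param bands feature bands to use (default all three).
#' @param nRepeats split repeats (default 50).
#' @param seed base seed.
#' @param config a [decoderConfig()].
#' @param trainFraction fraction of sessions used for training.
#' @return an [EvalResult-class].
#' @export
evaluateRegion <- function(features, events, emap, task, region,
                           bands = bandNames(), nRepeats = 50L, seed = 1L,
                           config = decoderConfig(), trainFraction = 0.8) {
  channels <- channelsForRegion(emap, region)
  assertThat(length(channels) > 0, "region '%s' has no channels", region)
  assertThat(nRepeats >= 1, "nRepeats must be >= 1")
  td <- buildTaskData(features, events, task, channels, bands,
                      config$trainStride)
  acc <- cor <- tot <- tp <- numeric(nRepeats)
  for (r in seq_len(nRepeats)) {
    res <- runRepeat(td, task, deriveSeed(seed, r), config, trainFraction)
    acc[r] <- res$correct / res$total
    cor[r] <- res$correct
    tot[r] <- res$total
    tp[r] <- res$timepointAccuracy
  }
  EvalResultNew(task, region, bands, acc, cor, tot, mean(tp), seed)
}

#' Per-band decoding comparison for one region
#'
#' Runs [evaluateRegion()] once per feature band with *common* splits
#' and channel orders across bands in every repeat (paired design), so
#' band differences are not confounded by split luck.
#'
#' @inheritParams evaluateRegion
#' @return named list of [EvalResult-class], one per band.
#' @export
bandComparison <- function(features, events, emap, task, region,
                           nRepeats = 50L, seed = 1L,
                           config = decoderConfig(), trainFraction = 0.8) {
  channels <- channelsForRegion(emap, region)
  assertThat(length(channels) > 0, "region '%s' has no channels", region)
  bands <- bandNames()
  tds <- lapply(bands, function(b)
    buildTaskData(features, events, task, channels, b,
                  config$trainStride))
  names(tds) <- bands
  acc <- cor <- tot <- tp <-
    matrix(0, nRepeats, length(bands), dimnames = list(NULL, bands))
  for (r in seq_len(nRepeats)) {
    rs <- deriveSeed(seed, r)
    for (b in bands) {
      res <- runRepeat(tds[[b]], task, rs, config, trainFraction)
      acc[r, b] <- res$correct / res$total
      cor[r, b] <- res$correct
      tot[r, b] <- res$total
      tp[r, b] <- res$timepointAccuracy
    }
  }
  stats::setNames(lapply(bands, function(b) {
    EvalResultNew(task, region, b, acc[, b], cor[, b], tot[, b],
                  mean(tp[, b]), seed)
  }), bands)
}

## Fit a decoder on cached items (optionally with a reduced epoch
## budget) and return it with its test tallies.
fitOn <- function(td, task, split, rows, cfg, maxEpochs = NULL) {
  if (!is.null(maxEpochs)) cfg$maxEpochs <- as.integer(maxEpochs)
  trainItems <- lapply(Filter(function(it) it$session %in% split$train,
                              td$items),
                       function(it) list(x = it$xTrain[rows, , ,
                                                       drop = FALSE],
                                         k = it$k, session = it$session))
  trainDecoderFromWindows(trainItems, task, cfg)
}

testOn <- function(model, td, split, rows) {
  testItems <- Filter(function(it) it$session %in% split$test, td$items)
  scoreItems(model, testItems, rows)
}

#' Cortical + subcortical channel-pair decoding
#'
#' Evaluates one channel from a cortical region combined with one from
#' a subcortical region, against the cortical channel alone, under
#' identical splits per repeat (paired design). The improvement ratio
#' is the relative gain `(pair - corticalAlone) / corticalAlone`.
#' Channel selection within each region follows `channelPolicy`:
#' `"best-val"` (default) trains one decoder per candidate channel on
#' the training sessions and keeps the channel with the lowest
#' best-checkpoint validation loss — no test data is touched;
#' `"random"` picks a seeded random channel; `"all-pairs-mean"`
#' averages the paired accuracies over every (cortical, subcortical)
#' channel combination.
#'
#' @inheritParams evaluateRegion
#' @param corticalRegion region whose class is cortical.
#' @param subcorticalRegion region whose class is subcortical.
#' @param channelPolicy channel selection rule (see Details).
#' @param selectionMaxEpochs optional reduced epoch budget for the
#'   `"best-val"` candidate ranking (the selected channel's alone model
#'   and the pair model are always trained at the full budget).
#' @return list with elements `pair` ([EvalResult-class] for the
#'   pair), `corticalAlone` (EvalResult), `improvementRatio` (mean over
#'   repeats), and `perRepeatRatio`.
#' @export
evaluatePair <- function(features, events, emap, task, corticalRegion,
                         subcorticalRegion, bands = bandNames(),
                         nRepeats = 50L, seed = 1L,
                         config = decoderConfig(), trainFraction = 0.8,
                         channelPolicy = c("best-val", "random",
                                           "all-pairs-mean"),
                         selectionMaxEpochs = NULL) {
  channelPolicy <- match.arg(channelPolicy)
  assertThat(regionClass(corticalRegion) == "cortical",
             "'%s' is not a cortical region", corticalRegion)
  assertThat(regionClass(subcorticalRegion) == "subcortical",
             "'%s' is not a subcortical region", subcorticalRegion)
  chC <- channelsForRegion(emap, corticalRegion)
  chS <- channelsForRegion(emap, subcorticalRegion)
  assertThat(length(chC) > 0 && length(chS) > 0,
             "both regions need at least one channel")

  stride <- config$trainStride
  tdC <- lapply(chC, function(ch)
    buildTaskData(features, events, task, ch, bands, stride))
  tdS <- lapply(chS, function(ch)
    buildTaskData(features, events, task, ch, bands, stride))
  tdPair <- lapply(seq_along(chC), function(i)
    lapply(seq_along(chS), function(j)
      buildTaskData(features, events, task, c(chC[i], chS[j]), bands,
                    stride)))
  sessions <- tdC[[1]]$sessions
  oneRow <- channelRowPerm(1L, length(bands))

  accP <- accC <- corP <- corC <- totP <- totC <- numeric(nRepeats)
  tpP <- tpC <- numeric(nRepeats)
  for (r in seq_len(nRepeats)) {
    rs <- deriveSeed(seed, r)
    split <- splitSessions(sessions, trainFraction, seed = rs)
    cfgAt <- function(salt) {
      cfg <- config
      cfg$seed <- deriveSeed(rs, salt)
      cfg
    }
    pairRows <- function(salt) {
      perm <- withSeed(deriveSeed(rs, salt), sample.int(2L))
      channelRowPerm(perm, length(bands))
    }
    runPair <- function(i, j, salt) {
      td <- tdPair[[i]][[j]]
      rows <- pairRows(salt + 1L)
      testOn(fitOn(td, task, split, rows, cfgAt(salt)), td, split, rows)
    }
    runAlone <- function(i, salt) {
      td <- tdC[[i]]
      testOn(fitOn(td, task, split, oneRow, cfgAt(salt)), td, split,
             oneRow)
    }
    if (channelPolicy == "all-pairs-mean") {
      resP <- list()
      for (i in seq_along(chC)) for (j in seq_along(chS)) {
        resP <- c(resP, list(runPair(i, j, 200L + 10L * i + j)))
      }
      resC <- lapply(seq_along(chC), function(i) runAlone(i, 300L + i))
      accP[r] <- mean(vapply(resP, function(x) x$correct / x$total, 0))
      accC[r] <- mean(vapply(resC, function(x) x$correct / x$total, 0))
      corP[r] <- round(accP[r] * resP[[1]]$total)
      corC[r] <- round(accC[r] * resC[[1]]$total)
      totP[r] <- resP[[1]]$total
      totC[r] <- resC[[1]]$total
      tpP[r] <- mean(vapply(resP, `[[`, 0, "timepointAccuracy"))
      tpC[r] <- mean(vapply(resC, `[[`, 0, "timepointAccuracy"))
    } else {
      pick <- function(tds, saltBase) {
        if (length(tds) == 1L) return(1L)
        valLoss <- vapply(seq_along(tds), function(i) {
          m <- fitOn(tds[[i]], task, split, oneRow,
                     cfgAt(saltBase + i), selectionMaxEpochs)
          min(m@trainingLog$valLoss)
        }, numeric(1))
        which.min(valLoss)
      }
      if (channelPolicy == "best-val") {
        i <- pick(tdC, 100L)
        j <- pick(tdS, 120L)
      } else {
        i <- withSeed(deriveSeed(rs, 41L), sample.int(length(chC), 1L))
        j <- withSeed(deriveSeed(rs, 43L), sample.int(length(chS), 1L))
      }
      resC1 <- runAlone(i, 45L)
      resP1 <- runPair(i, j, 47L)
      accP[r] <- resP1$correct / resP1$total
      accC[r] <- resC1$correct / resC1$total
      corP[r] <- resP1$correct
      corC[r] <- resC1$correct
      totP[r] <- resP1$total
      totC[r] <- resC1$total
      tpP[r] <- resP1$timepointAccuracy
      tpC[r] <- resC1$timepointAccuracy
    }
  }
  ratios <- ifelse(accC > 0, (accP - accC) / accC, NA_real_)
  list(
    pair = EvalResultNew(task, c(corticalRegion, subcorticalRegion), bands,
                         accP, corP, totP, mean(tpP), seed),
    corticalAlone = EvalResultNew(task, corticalRegion, bands, accC, corC,
                                  totC, mean(tpC), seed),
    improvementRatio = mean(ratios, na.rm = TRUE),
    perRepeatRatio = ratios
  )
}

#' Exact binomial test of an evaluation against chance
#'
#' Pools correct and total syllable counts over repeats and tests the
#' pooled proportion against the task's exact chance level (two-sided
#' exact binomial test).
#'
#' @param result an [EvalResult-class].
#' @return the p-value.
#' @export
chanceTest <- function(result) {
  assertThat(is(result, "EvalResult"), "result must be an EvalResult")
  n <- sum(result@perRepeatTotal)
  assertThat(n > 0, "no test syllables: cannot test against chance")
  stats::binom.test(sum(result@perRepeatCorrect), n,
                    p = result@chance)$p.value
}
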