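## The sequence decoder: a stacked 3-layer bidirectional LSTM (100
## hidden units per cell by default) mapping each 200 ms feature window
## to the articulatory category scores of the window's center sample,
## trained with Adam on mean-squared error against one-hot targets,
## with variational dropout and session-wise early stopping.

#' Decoder configuration
#'
#' Defaults are the study design's stated values: 3 bidirectional LSTM
#' layers of 100 hidden units, 50% dropout, Adam with learning rate
#' 0.001, beta1 0.9, beta2 0.999, epsilon 1e-8, mean-squared-error
#' objective, early stopping when validation loss stops decreasing.
#' Patience, epoch cap, batch size, window-target alignment and the
#' training-window stride are implementation knobs the design leaves
#' open; they are exposed here.
#'
#' @param hiddenUnits LSTM hidden units per cell.
#' @param layers stacked bLSTM layers.
#' @param dropout dropout fraction on every layer's output
#'   (variational: one mask per unit and example, shared across time).
#' @param learningRate,beta1,beta2,epsilon Adam hyperparameters.
#' @param patience epochs without validation improvement before
#'   stopping.
#' @param minDelta minimum decrease counted as an improvement.
#' @param maxEpochs hard epoch cap.
#' @param batchSize minibatch size.
#' @param trainStride window stride used for the training set (1 =
#'   every core sample; prediction always slides sample by sample).
#' @param targetAlignment which window sample the target describes:
#'   `"center"` (default; symmetric for a bidirectional model) or
#'   `"right"`.
#' @param validationFraction fraction of training sessions held out
#'   for early stopping.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return config list of class `"DecoderConfig"`.
#' @export
decoderConfig <- function(hiddenUnits = 100L, layers = 3L, dropout = 0.5,
                          learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                          epsilon = 1e-8, patience = 5L, minDelta = 0,
                          maxEpochs = 100L, batchSize = 256L,
                          trainStride = 1L,
                          targetAlignment = c("center", "right"),
                          validationFraction = 0.1, seed = 1L) {
  targetAlignment <- match.arg(targetAlignment)
  assertThat(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  assertThat(hiddenUnits >= 1 && layers >= 1, "need >= 1 units and layers")
  structure(list(
    hiddenUnits = as.integer(hiddenUnits), layers = as.integer(layers),
    bidirectional = TRUE, dropout = dropout,
    learningRate = learningRate, beta1 = beta1, beta2 = beta2,
    epsilon = epsilon, objective = "mse", patience = as.integer(patience),
    minDelta = minDelta, maxEpochs = as.integer(maxEpochs),
    batchSize = as.integer(batchSize), trainStride = as.integer(trainStride),
    targetAlignment = targetAlignment,
    validationFraction = validationFraction, seed = as.integer(seed)
  ), class = "DecoderConfig")
}

## 0-based readout timestep within the 40-sample window.
readoutStep <- function(config, windowLen = 40L) {
  switch(config$targetAlignment,
         center = as.integer(windowLen / 2),      # padded center sample
         right = windowLen - 1L)
}

## Parameter initialization: uniform(-r, r) with r = 1/sqrt(H), forget
## gate biases at +1 (standard LSTM practice), readout biases at the
## one-hot mean so the initial output sits near the target centroid.
initParams <- function(D, H, L, K) {
  n <- cpp_blstm_n_params(D, H, L, K)
  r <- 1 / sqrt(H)
  p <- stats::runif(n, -r, r)
  off <- 0L
  for (l in seq_len(L)) {
    din <- if (l == 1L) D else 2L * H
    for (d in 1:2) {
      boff <- off + 4L * H * din + 4L * H * H
      p[boff + H + seq_len(H)] <- 1       # forget-gate bias block
      off <- off + 4L * H * din + 4L * H * H + 4L * H
    }
  }
  p[(n - K + 1L):n] <- 1 / K
  p
}

## Fresh variational dropout masks (inverted scaling), one 2H x B
## matrix per layer.
dropoutMasks <- function(H, B, L, p) {
  if (p <= 0) return(array(1, dim = c(2L * H, B, L)))
  array(stats::rbinom(2L * H * B * L, 1L, 1 - p) / (1 - p),
        dim = c(2L * H, B, L))
}

## Mean loss of a window set under the current parameters, no dropout.
batchLoss <- function(params, D, H, L, K, X, Y, tstar, batchSize = 1024L) {
  n <- dim(X)[2]
  tot <- 0
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(n, s + batchSize - 1L)
    r <- cpp_blstm_loss_grad(params, D, H, L, K,
                             X[, idx, , drop = FALSE],
                             Y[, idx, drop = FALSE], tstar,
                             array(0, dim = c(1, 1, 1)), FALSE, FALSE)
    tot <- tot + r$loss * length(idx)
  }
  tot / n
}

#' Train the bLSTM sequence decoder
#'
#' Builds sliding-window examples from labeled segments, holds out a
#' session-wise validation split, and optimizes the network with Adam
#' until validation loss stops decreasing (`patience` epochs, best
#' checkpoint restored). All randomness (initialization, shuffling,
#' dropout) derives from `config$seed`, so training is reproducible.
#' Segments without a label under `task` (zero-initial syllables on
#' consonant tasks) are skipped and counted.
#'
#' @param segments list of labeled segments from [segmentEvents()]
#'   (all from the training sessions; channel/band selection done
#'   upstream via [subsetFeatureTensor()]).
#' @param task `"place"`, `"manner"` or `"tone"`.
#' @param config a [decoderConfig()].
#' @return a [TrainedDecoder-class].
#' @export
trainDecoder <- function(segments, task, config = decoderConfig()) {
  assertThat(inherits(config, "DecoderConfig"),
             "config must come from decoderConfig()")
  dims <- vapply(segments, function(s) dim(s$data)[1] * dim(s$data)[2],
                 integer(1))
  assertThat(length(unique(dims)) == 1L,
             "segments disagree on channel/band count: %s",
             paste(unique(dims), collapse = ", "))
  labeled <- !vapply(segments,
                     function(s) is.na(taskClassIndex(s$label, task)),
                     logical(1))
  nSkipped <- sum(!labeled)
  if (nSkipped > 0)
    message(sprintf("trainDecoder: skipped %d unlabeled segment(s) for task '%s'",
                    nSkipped, task))
  segments <- segments[labeled]
  assertThat(length(segments) > 0, "no labeled segments for task '%s'",
             task)
  items <- lapply(segments, function(s) {
    w <- makeWindows(s, task, stride = config$trainStride)
    list(x = w$x, k = w$classIndex, session = s$sessionId)
  })
  trainDecoderFromWindows(items, task, config)
}

## Core training loop on pre-windowed items: list of
## list(x = features x nWin x 40, k = class index, session = id).
trainDecoderFromWindows <- function(items, task, config) {
  lv <- taskLevels(task)
  K <- length(lv)
  H <- config$hiddenUnits
  L <- config$layers
  withSeed(config$seed, {
    sess <- unique(vapply(items, `[[`, "", "session"))
    if (length(sess) >= 2L) {
      nVal <- min(max(round(config$validationFraction * length(sess)), 1L),
                  length(sess) - 1L)
      valSess <- sample(sess, nVal)
      isVal <- vapply(items, function(s) s$session %in% valSess,
                      logical(1))
    } else {
      # single training session: fall back to a random segment holdout
      isVal <- seq_along(items) %in%
        sample(seq_along(items),
               max(1L, round(config$validationFraction * length(items))))
    }
    trainSet <- bindItems(items[!isVal], K)
    valSet <- bindItems(items[isVal], K)
    D <- dim(trainSet$x)[1]
    tstar <- readoutStep(config)
    params <- initParams(D, H, L, K)
    m <- v <- numeric(length(params))
    stepN <- 0L
    nTrain <- dim(trainSet$x)[2]

    bestVal <- Inf
    bestParams <- params
    wait <- 0L
    log <- data.frame(epoch = integer(), trainLoss = numeric(),
                      valLoss = numeric())
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample.int(nTrain)
      epochLoss <- 0
      for (s in seq(1L, nTrain, by = config$batchSize)) {
        idx <- ord[s:min(nTrain, s + config$batchSize - 1L)]
        masks <- dropoutMasks(H, length(idx), L, config$dropout)
        r <- cpp_blstm_loss_grad(params, D, H, L, K,
                                 trainSet$x[, idx, , drop = FALSE],
                                 trainSet$y[, idx, drop = FALSE],
                                 tstar, masks, config$dropout > 0, TRUE)
        epochLoss <- epochLoss + r$loss * length(idx)
        stepN <- stepN + 1L
        g <- as.numeric(r$grad)
        m <- config$beta1 * m + (1 - config$beta1) * g
        v <- config$beta2 * v + (1 - config$beta2) * g^2
        mhat <- m / (1 - config$beta1^stepN)
        vhat <- v / (1 - config$beta2^stepN)
        params <- params - config$learningRate * mhat /
          (sqrt(vhat) + config$epsilon)
      }
      valLoss <- batchLoss(params, D, H, L, K, valSet$x, valSet$y, tstar)
      log <- rbind(log, data.frame(epoch = epoch,
                                   trainLoss = epochLoss / nTrain,
                                   valLoss = valLoss))
      if (valLoss < bestVal - config$minDelta) {
        bestVal <- valLoss
        bestParams <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    new("TrainedDecoder", params = bestParams, config = unclass(config),
        inputDim = as.integer(D), task = task, classLevels = lv,
        trainingLog = log)
  })
}

#' Score every timepoint of a syllable segment
#'
#' Slides the decoder over the padded segment sample by sample: one
#' 200 ms window per core sample, scored at the window center, so the
#' output has exactly one category-score vector per core sample
#' (equal-length contract). Inference is deterministic: dropout is
#' disabled.
#'
#' @param model a [TrainedDecoder-class].
#' @param segment one element of [segmentEvents()] output, with the
#'   same channel/band selection the model was trained on.
#' @return K x coreLength matrix of scores (rows named by category).
#' @export
predictSequence <- function(model, segment) {
  assertThat(is(model, "TrainedDecoder"), "model must be a TrainedDecoder")
  D <- dim(segment$data)[1] * dim(segment$data)[2]
  assertThat(D == model@inputDim,
             "segment feature dim %d does not match model input dim %d",
             D, model@inputDim)
  cfg <- model@config
  feat <- flattenSegment(segment)
  L <- segment$coreLength
  w <- as.integer(round(WINDOW_SECONDS * FEATURE_RATE))
  starts <- seq.int(0L, L - 1L)
  cols <- as.vector(outer(seq_len(w), starts, `+`))
  X <- aperm(array(feat[, cols], dim = c(D, w, L)), c(1L, 3L, 2L))
  K <- length(model@classLevels)
  tstar <- readoutStep(structure(cfg, class = "DecoderConfig"))
  out <- matrix(0, K, L, dimnames = list(model@classLevels, NULL))
  for (s in seq(1L, L, by = 1024L)) {
    idx <- s:min(L, s + 1023L)
    out[, idx] <- cpp_blstm_predict(model@params, D, cfg$hiddenUnits,
                                    cfg$layers, K,
                                    X[, idx, , drop = FALSE], tstar)
  }
  out
}

#' Reduce per-timepoint scores to one syllable-level category
#'
#' Majority vote over the per-timepoint argmax categories; ties are
#' broken by the summed score of the tied categories.
#'
#' @param scores K x timepoints score matrix (e.g. from
#'   [predictSequence()]).
#' @return integer class index in 1..K (named if `scores` has
#'   rownames).
#' @export
classifySyllable <- function(scores) {
  assertThat(is.matrix(scores) && ncol(scores) >= 1L,
             "scores must be a K x timepoints matrix with >= 1 column")
  votes <- apply(scores, 2L, which.max)
  tab <- tabulate(votes, nbins = nrow(scores))
  top <- which(tab == max(tab))
  win <- if (length(top) == 1L) top else {
    sums <- rowSums(scores)[top]
    top[which.max(sums)]
  }
  if (!is.null(rownames(scores))) names(win) <- rownames(scores)[win]
  win
}
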