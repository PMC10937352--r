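## Central S4 containers: raw recordings, feature tensors, electrode
## maps, trained decoders and evaluation results.

#' The eight sampled brain regions
#'
#' Region vocabulary used throughout: three temporal-lobe gyri recorded
#' cortically and five deep structures. The parahippocampal gyrus is
#' archicortex but is grouped with the subcortical class here because,
#' like the other deep structures, it is inaccessible to surface grids;
#' region class labels are data, not anatomy.
#'
#' @return character vector of region names (`brainRegions()`), or the
#'   `"cortical"`/`"subcortical"` class of each region
#'   (`regionClass(region)`).
#' @export
#' @examples
#' brainRegions()
#' regionClass("STG")
brainRegions <- function() {
  c("ITG", "MTG", "STG", "thalamus", "insular gyrus", "amygdala",
    "parahippocampal gyrus", "hippocampus")
}

#' @rdname brainRegions
#' @param region character vector of region names.
#' @export
regionClass <- function(region) {
  assertThat(all(region %in% brainRegions()),
             "unknown region(s): %s",
             paste(setdiff(region, brainRegions()), collapse = ", "))
  ifelse(region %in% c("ITG", "MTG", "STG"), "cortical", "subcortical")
}

#' Band vocabulary of the feature tensor
#'
#' The three frequency bands whose power/amplitude at 200 Hz forms the
#' decoder input: 1-30 Hz, 30-70 Hz, and the 70-150 Hz high-gamma
#' envelope.
#'
#' @return character vector of band names in canonical order.
#' @export
bandNames <- function() c("1-30Hz", "30-70Hz", "70-150Hz")

## Band edges in Hz, keyed by band name.
bandEdges <- function(band) {
  switch(band,
    "1-30Hz" = c(1, 30),
    "30-70Hz" = c(30, 70),
    "70-150Hz" = c(70, 150),
    stop(sprintf("unsupported band '%s'", band), call. = FALSE)
  )
}

# ---------------------------------------------------------------------
# RawRecording

#' RawRecording: multichannel voltage time series
#'
#' One recording session: a channels x time matrix of voltages (microvolts)
#' at a common sampling rate (2000 Hz in the study design), with channel
#' labels and a session identifier.
#'
#' @slot samples numeric matrix, channels in rows, time in columns.
#' @slot rate sampling rate in samples/s.
#' @slot channelIds character vector, one label per row of `samples`.
#' @slot sessionId single session label.
#' @export
setClass("RawRecording",
  representation(samples = "matrix", rate = "numeric",
                 channelIds = "character", sessionId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@rate) != 1L || !is.finite(object@rate) ||
        object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    if (nrow(object@samples) != length(object@channelIds))
      msg <- c(msg, "one channelId per sample row required")
    if (anyDuplicated(object@channelIds))
      msg <- c(msg, "channelIds must be unique")
    if (length(object@sessionId) != 1L)
      msg <- c(msg, "sessionId must be a single string")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a RawRecording
#'
#' @param samples channels x time numeric matrix (microvolts).
#' @param rate sampling rate in samples/s.
#' @param channelIds channel labels (default `ch1..chN`).
#' @param sessionId session label.
#' @return a [RawRecording-class] object.
#' @export
RawRecording <- function(samples, rate, channelIds = NULL,
                         sessionId = "session1") {
  samples <- as.matrix(samples)
  if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(nrow(samples)))
  new("RawRecording", samples = samples, rate = as.numeric(rate),
      channelIds = as.character(channelIds),
      sessionId = as.character(sessionId))
}

# ---------------------------------------------------------------------
# FeatureTensor

#' FeatureTensor: 3-band features at 200 Hz
#'
#' Channels x bands x time array of z-scored band power/amplitude
#' features, the decoder's input representation.
#'
#' @slot values numeric array, channels x 3 bands x time.
#' @slot rate feature rate in samples/s (200).
#' @slot bands band names in array order.
#' @slot channelIds channel labels, one per array row.
#' @slot sessionId session label.
#' @slot metadata list of processing provenance (filter specs, z-score
#'   window, source rate).
#' @export
setClass("FeatureTensor",
  representation(values = "array", rate = "numeric", bands = "character",
                 channelIds = "character", sessionId = "character",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) != 3L)
      msg <- c(msg, "values must be a 3-d array (channels x bands x time)")
    else {
      if (d[1] != length(object@channelIds))
        msg <- c(msg, "one channelId per channel row required")
      if (d[2] != length(object@bands))
        msg <- c(msg, "one band name per band slice required")
    }
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------
# ElectrodeMap

#' ElectrodeMap: channel-to-region assignment
#'
#' Maps each recording channel to one of the eight sampled brain regions
#' and its cortical/subcortical class. The class is constrained to the
#' study's designation (temporal gyri cortical, deep structures
#' subcortical).
#'
#' @slot table data.frame with columns `channel_id`, `region`, `class`.
#' @export
setClass("ElectrodeMap",
  representation(table = "data.frame"),
  validity = function(object) {
    tb <- object@table
    msg <- character()
    need <- c("channel_id", "region", "class")
    if (!all(need %in% names(tb)))
      return(paste("electrode table needs columns:",
                   paste(need, collapse = ", ")))
    if (anyDuplicated(tb$channel_id))
      msg <- c(msg, "duplicate channel_id entries")
    bad <- setdiff(unique(tb$region), brainRegions())
    if (length(bad))
      msg <- c(msg, paste("unknown region(s):", paste(bad, collapse = ", ")))
    if (length(bad) == 0 && !all(tb$class == regionClass(tb$region)))
      msg <- c(msg, "cortical/subcortical class inconsistent with region")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an ElectrodeMap
#'
#' @param channelIds character channel labels.
#' @param regions region name per channel (see [brainRegions()]).
#' @return an [ElectrodeMap-class] object; the cortical/subcortical
#'   class is derived from the region.
#' @export
ElectrodeMap <- function(channelIds, regions) {
  tb <- data.frame(channel_id = as.character(channelIds),
                   region = as.character(regions),
                   class = regionClass(as.character(regions)),
                   stringsAsFactors = FALSE)
  new("ElectrodeMap", table = tb)
}

# ---------------------------------------------------------------------
# TrainedDecoder

#' TrainedDecoder: a fitted bLSTM sequence decoder
#'
#' Opaque flat parameter vector plus the architecture/config needed to
#' run it, the task it was trained for, and the per-epoch training log.
#'
#' @slot params numeric parameter vector (layout fixed by the config).
#' @slot config decoder configuration list (see [decoderConfig()]).
#' @slot inputDim integer, features per timestep (channels x bands).
#' @slot task `"place"`, `"manner"` or `"tone"`.
#' @slot classLevels category names in output order.
#' @slot trainingLog data.frame with columns epoch, trainLoss, valLoss.
#' @export
setClass("TrainedDecoder",
  representation(params = "numeric", config = "list", inputDim = "integer",
                 task = "character", classLevels = "character",
                 trainingLog = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!object@task %in% c("place", "manner", "tone"))
      msg <- c(msg, "task must be place, manner or tone")
    lg <- object@trainingLog
    if (nrow(lg) > 0 && !is.na(bestEpoch <- which.min(lg$valLoss))) {
      # early-stopping contract: the restored checkpoint is the best one
      if (!isTRUE(all.equal(min(lg$valLoss), lg$valLoss[bestEpoch])))
        msg <- c(msg, "training log inconsistent")
    }
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------
# EvalResult

#' EvalResult: decoding accuracy for a region or region pair
#'
#' Aggregate of repeated session-wise train/test splits: per-repeat
#' syllable-level accuracies, their mean, the task's exact chance level,
#' and the correct/total counts needed for binomial testing.
#'
#' @slot task decoded task.
#' @slot regions one region, or (cortical, subcortical) pair.
#' @slot bands feature bands used.
#' @slot accuracy mean of `perRepeatAccuracies`.
#' @slot chance exact chance level 1/K.
#' @slot nRepeats number of split repeats.
#' @slot perRepeatAccuracies numeric vector, one accuracy per repeat.
#' @slot perRepeatCorrect integer correct-syllable counts per repeat.
#' @slot perRepeatTotal integer test-syllable counts per repeat.
#' @slot timepointAccuracy mean per-timepoint accuracy (secondary unit).
#' @slot seed base seed of the evaluation.
#' @export
setClass("EvalResult",
  representation(task = "character", regions = "character",
                 bands = "character", accuracy = "numeric",
                 chance = "numeric", nRepeats = "integer",
                 perRepeatAccuracies = "numeric",
                 perRepeatCorrect = "integer", perRepeatTotal = "integer",
                 timepointAccuracy = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@perRepeatAccuracies < 0 | object@perRepeatAccuracies > 1))
      msg <- c(msg, "accuracies must lie in [0, 1]")
    if (length(object@perRepeatAccuracies) &&
        !isTRUE(all.equal(object@accuracy,
                          mean(object@perRepeatAccuracies))))
      msg <- c(msg, "accuracy must equal the mean per-repeat accuracy")
    if (!isTRUE(all.equal(object@chance, chanceLevel(object@task))))
      msg <- c(msg, "chance must equal the task's exact chance level")
    if (length(msg)) msg else TRUE
  }
)

EvalResultNew <- function(task, regions, bands, perRepeat, correct, total,
                          timepointAcc, seed) {
  new("EvalResult", task = task, regions = regions, bands = bands,
      accuracy = mean(perRepeat), chance = chanceLevel(task),
      nRepeats = length(perRepeat), perRepeatAccuracies = perRepeat,
      perRepeatCorrect = as.integer(correct),
      perRepeatTotal = as.integer(total),
      timepointAccuracy = timepointAcc, seed = as.integer(seed))
}
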