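## Generics, accessors and show methods for the S4 containers.

#' Accessors for sEEG containers
#'
#' Slot access for [RawRecording-class] and [FeatureTensor-class]
#' objects: channel labels, session label, sampling rate, and the
#' underlying numeric data.
#'
#' @param x a RawRecording or FeatureTensor.
#' @return `channelIds`: character; `sessionId`: character;
#'   `samplingRate`: numeric (samples/s); `voltages`: channels x time
#'   matrix; `featureValues`: channels x bands x time array;
#'   `featureBands`: character band names.
#' @name accessors
#' @aliases channelIds sessionId samplingRate voltages featureValues
#'   featureBands
NULL

#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureBands", function(x) standardGeneric("featureBands"))

#' @rdname accessors
setMethod("channelIds", "RawRecording", function(x) x@channelIds)
#' @rdname accessors
setMethod("channelIds", "FeatureTensor", function(x) x@channelIds)
#' @rdname accessors
setMethod("channelIds", "ElectrodeMap", function(x) x@table$channel_id)
#' @rdname accessors
setMethod("sessionId", "RawRecording", function(x) x@sessionId)
#' @rdname accessors
setMethod("sessionId", "FeatureTensor", function(x) x@sessionId)
#' @rdname accessors
setMethod("samplingRate", "RawRecording", function(x) x@rate)
#' @rdname accessors
setMethod("samplingRate", "FeatureTensor", function(x) x@rate)
#' @rdname accessors
setMethod("voltages", "RawRecording", function(x) x@samples)
#' @rdname accessors
setMethod("featureValues", "FeatureTensor", function(x) x@values)
#' @rdname accessors
setMethod("featureBands", "FeatureTensor", function(x) x@bands)

#' Electrode map queries
#'
#' `electrodeTable` returns the underlying data.frame;
#' `channelsForRegion` lists the channel ids assigned to the given
#' region(s).
#'
#' @param x an [ElectrodeMap-class].
#' @param regions character vector of region names.
#' @return data.frame, or character vector of channel ids.
#' @export
setGeneric("electrodeTable", function(x) standardGeneric("electrodeTable"))
#' @rdname electrodeTable
setMethod("electrodeTable", "ElectrodeMap", function(x) x@table)

#' @rdname electrodeTable
#' @export
setGeneric("channelsForRegion",
           function(x, regions) standardGeneric("channelsForRegion"))
#' @rdname electrodeTable
setMethod("channelsForRegion", "ElectrodeMap", function(x, regions) {
  assertThat(all(regions %in% brainRegions()),
             "unknown region(s): %s",
             paste(setdiff(regions, brainRegions()), collapse = ", "))
  x@table$channel_id[x@table$region %in% regions]
})

#' Evaluation result accessors
#'
#' @param x an [EvalResult-class].
#' @return `accuracy`: mean syllable-level accuracy; `perRepeat`: vector
#'   of per-repeat accuracies; `chance`: the task's exact chance level.
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accuracy
setMethod("accuracy", "EvalResult", function(x) x@accuracy)
#' @rdname accuracy
#' @export
setGeneric("perRepeat", function(x) standardGeneric("perRepeat"))
#' @rdname accuracy
setMethod("perRepeat", "EvalResult", function(x) x@perRepeatAccuracies)
#' @rdname accuracy
#' @export
setGeneric("chance", function(x) standardGeneric("chance"))
#' @rdname accuracy
setMethod("chance", "EvalResult", function(x) x@chance)

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("<RawRecording> session '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@sessionId, nrow(object@samples), ncol(object@samples),
              object@rate, ncol(object@samples) / object@rate))
})

setMethod("show", "FeatureTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("<FeatureTensor> session '%s': %d channels x %d bands x %d samples @ %g Hz\n",
              object@sessionId, d[1], d[2], d[3], object@rate))
  cat("  bands:", paste(object@bands, collapse = ", "), "\n")
})

setMethod("show", "ElectrodeMap", function(object) {
  tb <- object@table
  cat(sprintf("<ElectrodeMap> %d channels over %d regions\n",
              nrow(tb), length(unique(tb$region))))
  print(table(region = tb$region, class = tb$class))
})

setMethod("show", "TrainedDecoder", function(object) {
  cfg <- object@config
  cat(sprintf("<TrainedDecoder> task '%s': %d-layer bLSTM, %d hidden units, input dim %d, %d classes\n",
              object@task, cfg$layers, cfg$hiddenUnits, object@inputDim,
              length(object@classLevels)))
  if (nrow(object@trainingLog))
    cat(sprintf("  trained %d epochs; best validation loss %.5f (epoch %d)\n",
                nrow(object@trainingLog), min(object@trainingLog$valLoss),
                which.min(object@trainingLog$valLoss)))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("<EvalResult> task '%s', region(s) %s, bands %s\n",
              object@task, paste(object@regions, collapse = " + "),
              paste(object@bands, collapse = ",")))
  cat(sprintf("  accuracy %.3f (chance %.3f) over %d repeats; per-repeat sd %.3f\n",
              object@accuracy, object@chance, object@nRepeats,
              stats::sd(object@perRepeatAccuracies)))
})
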