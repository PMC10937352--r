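## Tab-separated tables: syllable events and the electrode map.
## Parsing is strict — malformed rows are errors naming the row.

#' Validate a syllable event table
#'
#' Checks the event schema (`session_id`, `onset_s`, `offset_s`,
#' `pinyin`, `tone`): onsets before offsets, tones in 1..4, pinyin
#' initials known, and events non-overlapping and sorted within each
#' session. Violations are errors naming the offending rows.
#'
#' @param events data.frame of events.
#' @return the validated data.frame (tone as integer), invisibly sorted
#'   by session then onset order preserved.
#' @export
validateEvents <- function(events) {
  need <- c("session_id", "onset_s", "offset_s", "pinyin", "tone")
  assertThat(all(need %in% names(events)),
             "events table must have columns: %s", paste(need, collapse = ", "))
  n <- nrow(events)
  rows <- seq_len(n)
  bad <- rows[!is.finite(events$onset_s) | !is.finite(events$offset_s) |
              events$onset_s < 0 | events$onset_s >= events$offset_s]
  assertThat(length(bad) == 0,
             "invalid onset/offset at row(s): %s", paste(bad, collapse = ", "))
  bad <- rows[is.na(events$tone) | !(events$tone %in% toneCategories())]
  assertThat(length(bad) == 0,
             "tone outside {1,2,3,4} at row(s): %s", paste(bad, collapse = ", "))
  for (i in rows) {
    # rejects unknown initials with the offending syllable named
    tryCatch(pinyinInitial(events$pinyin[i]),
             error = function(e) stop(sprintf("row %d: %s", i,
                                              conditionMessage(e)),
                                      call. = FALSE))
  }
  for (sid in unique(events$session_id)) {
    ev <- events[events$session_id == sid, ]
    idx <- rows[events$session_id == sid]
    if (nrow(ev) > 1L) {
      unsorted <- which(diff(ev$onset_s) < 0)
      assertThat(length(unsorted) == 0,
                 "session '%s': events not sorted at row(s) %s", sid,
                 paste(idx[unsorted + 1L], collapse = ", "))
      overl <- which(ev$onset_s[-1L] < ev$offset_s[-nrow(ev)])
      assertThat(length(overl) == 0,
                 "session '%s': overlapping events at row(s) %s", sid,
                 paste(idx[overl + 1L], collapse = ", "))
    }
  }
  events$tone <- as.integer(events$tone)
  invisible(events)
}

#' Read and write syllable event tables (TSV)
#'
#' Columns: `session_id`, `onset_s`, `offset_s`, `pinyin`, `tone`.
#' Reading applies [validateEvents()] strictly.
#'
#' @param path TSV file.
#' @param events data.frame of events (for writing).
#' @return `readEvents`: validated data.frame; `writeEvents`: `path`.
#' @export
readEvents <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validateEvents(ev)
  ev$tone <- as.integer(ev$tone)
  ev
}

#' @rdname readEvents
#' @export
writeEvents <- function(events, path) {
  validateEvents(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write electrode tables (TSV)
#'
#' Columns: `channel_id`, `region`, `class`. Regions are checked
#' against the eight-region vocabulary and the class against the
#' study's cortical/subcortical designation; violations name the rows.
#'
#' @param path TSV file.
#' @param emap an [ElectrodeMap-class] (for writing).
#' @return `readElectrodes`: an [ElectrodeMap-class];
#'   `writeElectrodes`: `path`.
#' @export
readElectrodes <- function(path) {
  tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("channel_id", "region", "class")
  assertThat(all(need %in% names(tb)),
             "electrode table must have columns: %s",
             paste(need, collapse = ", "))
  bad <- which(!tb$region %in% brainRegions())
  assertThat(length(bad) == 0,
             "unknown region at row(s): %s", paste(bad, collapse = ", "))
  bad <- which(tb$class != regionClass(tb$region))
  assertThat(length(bad) == 0,
             "cortical/subcortical class contradicts region at row(s): %s",
             paste(bad, collapse = ", "))
  new("ElectrodeMap", table = tb[, need])
}

#' Restrict a recording to the channels of an electrode table
#'
#' Channels present in the recording but absent from the electrode map
#' are dropped with a warning naming them (unmapped contacts carry no
#' region and cannot enter any analysis); channels in the map but
#' missing from the recording are an error.
#'
#' @param rec a [RawRecording-class].
#' @param emap an [ElectrodeMap-class].
#' @return a RawRecording containing exactly the mapped channels, in
#'   map order.
#' @export
alignChannels <- function(rec, emap) {
  assertThat(is(rec, "RawRecording"), "rec must be a RawRecording")
  assertThat(is(emap, "ElectrodeMap"), "emap must be an ElectrodeMap")
  mapped <- channelIds(emap)
  missing <- setdiff(mapped, channelIds(rec))
  assertThat(length(missing) == 0,
             "electrode table channel(s) missing from recording: %s",
             paste(missing, collapse = ", "))
  extra <- setdiff(channelIds(rec), mapped)
  if (length(extra) > 0)
    warning(sprintf("dropping %d unmapped channel(s): %s", length(extra),
                    paste(extra, collapse = ", ")), call. = FALSE)
  idx <- match(mapped, channelIds(rec))
  RawRecording(voltages(rec)[idx, , drop = FALSE], samplingRate(rec),
               mapped, sessionId(rec))
}

#' @rdname readElectrodes
#' @export
writeElectrodes <- function(emap, path) {
  assertThat(is(emap, "ElectrodeMap"), "emap must be an ElectrodeMap")
  utils::write.table(electrodeTable(emap), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
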