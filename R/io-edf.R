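## EDF (European Data Format) reader and writer.
##
## EDF stores a 256-byte fixed header, 256 bytes of header per signal,
## then data records of 16-bit little-endian integers, one contiguous
## block per signal per record. Records here are 1 s long, so sessions
## must span a whole number of seconds. Values are mapped between
## physical units (microvolts) and the 16-bit digital range through the
## per-signal physical/digital min/max fields.

edfPad <- function(x, width) {
  s <- as.character(x)
  long <- nchar(s, type = "bytes") > width
  assertThat(!any(long),
             "EDF header field '%s' exceeds %d bytes",
             s[which(long)[1]], width)
  formatC(s, width = -width)  # left-justified, space padded
}

## Format numbers into a fixed-width ASCII field, dropping significant
## digits until they fit.
edfNum <- function(x, width) {
  s <- vapply(x, function(v) {
    for (dg in seq(width - 1, 1)) {
      cand <- formatC(v, format = "g", digits = dg)
      if (nchar(cand) <= width) return(cand)
    }
    stop(sprintf("cannot format %g into %d bytes", v, width), call. = FALSE)
  }, character(1))
  edfPad(s, width)
}

#' Write a recording to an EDF file
#'
#' Serializes a [RawRecording-class] as EDF with 1 s data records and
#' 16-bit quantization over each channel's observed physical range
#' (microvolts). The session must span a whole number of seconds.
#'
#' @param rec a [RawRecording-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(rec, path) {
  assertThat(is(rec, "RawRecording"), "rec must be a RawRecording")
  x <- voltages(rec)
  rate <- samplingRate(rec)
  assertThat(abs(rate - round(rate)) < 1e-9, "rate must be integer Hz")
  rate <- as.integer(round(rate))
  nrec <- ncol(x) / rate
  assertThat(abs(nrec - round(nrec)) < 1e-9,
             "recording length must be a whole number of seconds")
  nrec <- as.integer(round(nrec))
  ns <- nrow(x)

  physMax <- apply(abs(x), 1L, max)
  physMax[physMax == 0] <- 1
  digMax <- 32767L
  digMin <- -32768L

  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8),                                  # version
    edfPad(paste("X X X", sessionId(rec)), 80),      # patient id (anon)
    edfPad(paste("Startdate X X X X session", sessionId(rec)), 80),
    edfPad("01.01.26", 8), edfPad("00.00.00", 8),    # date, time
    edfPad(256 * (1 + ns), 8),                       # header bytes
    edfPad("", 44),                                  # reserved
    edfPad(nrec, 8),                                 # n data records
    edfPad(1, 8),                                    # record duration (s)
    edfPad(ns, 4)                                    # n signals
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  sig <- paste0(
    paste(edfPad(channelIds(rec), 16), collapse = ""),
    paste(edfPad(rep("sEEG depth electrode", ns), 80), collapse = ""),
    paste(edfPad(rep("uV", ns), 8), collapse = ""),
    paste(edfNum(-physMax, 8), collapse = ""),
    paste(edfNum(physMax, 8), collapse = ""),
    paste(edfNum(rep(digMin, ns), 8), collapse = ""),
    paste(edfNum(rep(digMax, ns), 8), collapse = ""),
    paste(edfPad(rep("", ns), 80), collapse = ""),   # prefiltering
    paste(edfPad(rep(rate, ns), 8), collapse = ""),  # samples per record
    paste(edfPad(rep("", ns), 32), collapse = "")    # reserved
  )
  writeChar(sig, con, eos = NULL, useBytes = TRUE)

  scale <- (digMax - digMin) / (2 * physMax)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * rate + 1L):(r * rate)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, cols] + physMax[ch]) * scale[ch]) + digMin
      dig <- pmin(pmax(dig, digMin), digMax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

readEdfField <- function(raw, off, width) {
  trimws(rawToChar(raw[(off + 1L):(off + width)]))
}

#' Read an EDF file into a RawRecording
#'
#' Parses the header and data records, converts digital values back to
#' physical units (microvolts), and requires a uniform sampling rate
#' across channels.
#'
#' @param path EDF file.
#' @param sessionId session label for the returned object (default: the
#'   file name without extension).
#' @return a [RawRecording-class].
#' @export
readEDF <- function(path, sessionId = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  assertThat(length(raw) >= 256L,
             "not an EDF file: header truncated (%d bytes)", length(raw))
  version <- readEdfField(raw, 0L, 8L)
  assertThat(version == "0", "not an EDF file: version field '%s'", version)
  headerBytes <- as.integer(readEdfField(raw, 184L, 8L))
  nrec <- as.integer(readEdfField(raw, 236L, 8L))
  recDur <- as.numeric(readEdfField(raw, 244L, 8L))
  ns <- as.integer(readEdfField(raw, 252L, 4L))
  assertThat(!is.na(ns) && ns >= 1L, "unreadable EDF header: signal count")
  assertThat(length(raw) >= 256L * (1L + ns),
             "EDF header truncated: %d signals declared", ns)

  sigField <- function(off0, width) {
    vapply(seq_len(ns) - 1L,
           function(i) readEdfField(raw, 256L + off0 * ns + i * width, width),
           character(1))
  }
  labels <- sigField(0L, 16L)
  physMin <- as.numeric(vapply(seq_len(ns) - 1L, function(i)
    readEdfField(raw, 256L + (16L + 80L + 8L) * ns + i * 8L, 8L),
    character(1)))
  physMax <- as.numeric(vapply(seq_len(ns) - 1L, function(i)
    readEdfField(raw, 256L + (16L + 80L + 8L + 8L) * ns + i * 8L, 8L),
    character(1)))
  digMin <- as.numeric(vapply(seq_len(ns) - 1L, function(i)
    readEdfField(raw, 256L + (16L + 80L + 8L + 16L) * ns + i * 8L, 8L),
    character(1)))
  digMax <- as.numeric(vapply(seq_len(ns) - 1L, function(i)
    readEdfField(raw, 256L + (16L + 80L + 8L + 24L) * ns + i * 8L, 8L),
    character(1)))
  nsamp <- as.integer(vapply(seq_len(ns) - 1L, function(i)
    readEdfField(raw, 256L + (16L + 80L + 8L + 32L + 80L) * ns + i * 8L, 8L),
    character(1)))
  assertThat(length(unique(nsamp)) == 1L,
             "mixed sampling rates across channels: %s",
             paste(unique(nsamp), collapse = ", "))
  rate <- nsamp[1] / recDur

  dataBytes <- raw[(headerBytes + 1L):length(raw)]
  vals <- readBin(dataBytes, "integer", n = length(dataBytes) / 2L,
                  size = 2L, signed = TRUE, endian = "little")
  assertThat(length(vals) == nrec * ns * nsamp[1],
             "EDF data size mismatch: %d values, expected %d",
             length(vals), nrec * ns * nsamp[1])

  x <- matrix(0, nrow = ns, ncol = nrec * nsamp[1])
  k <- 0L
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * nsamp[1] + 1L):(r * nsamp[1])
    for (ch in seq_len(ns)) {
      x[ch, cols] <- vals[(k + 1L):(k + nsamp[1])]
      k <- k + nsamp[1]
    }
  }
  gain <- (physMax - physMin) / (digMax - digMin)
  x <- (x - digMin) * gain + physMin
  if (is.null(sessionId))
    sessionId <- sub("\\.[^.]*$", "", basename(path))
  RawRecording(x, rate, labels, sessionId)
}
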