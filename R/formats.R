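# Plain external formats: 16-bit PCM WAV for stimuli, TSV for event and
# electrode tables, JSON for ground truth.

#' Write and read 16-bit PCM WAV audio
#'
#' Minimal canonical RIFF/WAVE I/O for mono stimuli. Samples are clipped to
#' [-1, 1] and quantized to 16 bits on write.
#'
#' @param x numeric vector of samples in [-1, 1].
#' @param fs sample rate (Hz).
#' @param path output file.
#' @return `write_wav` returns `path` invisibly. `read_wav` returns a list
#'   with `x` (samples rescaled to [-1, 1]) and `fs`.
#' @export
write_wav <- function(x, fs, path) {
  x <- pmax(-1, pmin(1, x))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop_format("not a RIFF/WAVE file")
  fs <- NA_integer_; bits <- NA_integer_; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt[1] != 1L || bits != 16L)
        stop_format("only 16-bit PCM WAV is supported")
    } else if (id == "data") {
      x <- readBin(con, "integer", size / 2, size = 2, endian = "little",
                   signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(x)) stop_format("WAV file has no data chunk")
  list(x = x / 32767, fs = fs)
}

#' Write and read event / annotation tables as TSV
#'
#' Standard columns: `onset_s`, `duration_s`, `type`, `value` (or
#' `trial_id`); any data.frame with an `onset_s` column round-trips.
#'
#' @param tab data.frame.
#' @param path file path.
#' @export
write_event_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_tsv
#' @export
read_event_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"onset_s" %in% names(tab)) stop_format("event TSV lacks `onset_s`")
  tab
}

#' Write and read planted ground truth as JSON
#'
#' @param truth a `ground_truth` data.frame.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- jsonlite::fromJSON(path)
  class(out) <- c("ground_truth", "data.frame")
  out
}
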