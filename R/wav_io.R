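# Minimal RIFF/WAVE reader and writer. No audio package ships with the target
# environment, so only what the pipeline needs is implemented: mono (or
# first-channel) PCM 16-bit and IEEE float 32-bit, little-endian.

le_int <- function(raw, offset, size) {
  sum(as.integer(raw[offset + seq_len(size) - 1L]) * 256^(seq_len(size) - 1L))
}

#' Construct a recording object
#'
#' A recording is a normalized mono sample vector plus its sample rate.
#' Amplitudes are dimensionless in \[-1, 1\].
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz (positive).
#' @param source_id free-text identifier carried into downstream tables.
#' @return an object of class `pup_recording`.
#' @export
recording <- function(samples, sample_rate, source_id = "recording") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording must contain at least one sample")
  if (any(!is.finite(samples))) stop("recording contains non-finite samples")
  sample_rate <- as.numeric(sample_rate)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(list(samples = samples, sample_rate = sample_rate,
                 source_id = as.character(source_id)[1L]),
            class = "pup_recording")
}

#' @export
print.pup_recording <- function(x, ...) {
  cat(sprintf("<pup_recording> %s: %.1f ms at %g kHz sampling\n",
              x$source_id, 1000 * length(x$samples) / x$sample_rate,
              x$sample_rate / 1000))
  invisible(x)
}

#' Read a WAV file
#'
#' Supports PCM 16-bit and IEEE float 32-bit. Multi-channel files are reduced
#' to their first channel with a warning.
#'
#' @param path path to a `.wav` file.
#' @param source_id identifier for the returned recording; defaults to the
#'   file name.
#' @return a [recording()] object.
#' @export
read_wav <- function(path, source_id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 12L)
  if (length(hdr) < 12L || rawToChar(hdr[1:4]) != "RIFF" ||
      rawToChar(hdr[9:12]) != "WAVE")
    stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    sz_raw <- readBin(con, "raw", 4L)
    if (length(sz_raw) < 4L) break
    sz <- le_int(sz_raw, 1L, 4L)
    chunk <- readBin(con, "raw", sz)
    if (sz %% 2 == 1) readBin(con, "raw", 1L)  # chunks are word-aligned
    cid <- rawToChar(id)
    if (cid == "fmt ") fmt <- chunk else if (cid == "data") data_raw <- chunk
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("WAV file missing fmt or data chunk: ", path)
  audio_format <- le_int(fmt, 1L, 2L)
  n_channels <- le_int(fmt, 3L, 2L)
  sample_rate <- le_int(fmt, 5L, 4L)
  bits <- le_int(fmt, 15L, 2L)
  if (audio_format == 1L && bits == 16L) {
    vals <- readBin(data_raw, "integer", n = length(data_raw) / 2L, size = 2L,
                    signed = TRUE, endian = "little") / 32768
  } else if (audio_format == 3L && bits == 32L) {
    vals <- readBin(data_raw, "double", n = length(data_raw) / 4L, size = 4L,
                    endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit); expected PCM16 or float32",
                 audio_format, bits))
  }
  if (n_channels > 1L) {
    warning("multichannel WAV: taking first of ", n_channels, " channels")
    vals <- vals[seq(1L, length(vals), by = n_channels)]
  }
  recording(vals, sample_rate, source_id)
}

#' Write a mono WAV file
#'
#' @param samples numeric amplitudes in \[-1, 1\] (clipped if outside) or a
#'   [recording()] object.
#' @param path output path.
#' @param sample_rate sampling rate in Hz; ignored when `samples` is a
#'   recording.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 500000) {
  if (inherits(samples, "pup_recording")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  samples <- pmin(1, pmax(-1, as.numeric(samples)))
  pcm <- as.integer(round(samples * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")        # PCM
  writeBin(1L, con, size = 2L, endian = "little")        # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")        # block align
  writeBin(16L, con, size = 2L, endian = "little")       # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
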