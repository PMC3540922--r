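# Syllable detection, spectrogram computation, and nine-point contour
# extraction.
#
# Detection follows the amplitude-threshold convention of bioacoustic
# workstations: a short-time RMS envelope in dB, a threshold relative to the
# recording's noise floor (median frame RMS), and a hold time that merges
# supra-threshold runs separated by brief dips.

#' Spectrogram parameters
#'
#' Defaults match the analysis settings used for ultrasonic mouse pup
#' recordings at a 500 kHz sampling rate: Hamming window, FFT length 1024
#' (0.49 kHz bin width), 98.43% overlap (16-sample hop), display band
#' 40-130 kHz.
#'
#' @param fft_length FFT length in samples; a power of two, >= 16.
#' @param overlap_fraction window overlap in \[0, 1).
#' @param window taper; only `"hamming"` is implemented.
#' @param freq_min,freq_max retained frequency band, kHz.
#' @return an object of class `pup_spec_params`.
#' @export
spectrogram_params <- function(fft_length = 1024L, overlap_fraction = 0.9843,
                               window = "hamming", freq_min = 40,
                               freq_max = 130) {
  fft_length <- as.integer(fft_length)
  if (fft_length < 16L || bitwAnd(fft_length, fft_length - 1L) != 0L)
    stop("fft_length must be a power of two and at least 16")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  if (freq_min >= freq_max) stop("freq_min must be below freq_max")
  window <- match.arg(window, "hamming")
  structure(list(fft_length = fft_length, overlap_fraction = overlap_fraction,
                 window = window, freq_min = freq_min, freq_max = freq_max),
            class = "pup_spec_params")
}

frame_rms_db <- function(samples, frame_len) {
  n_frames <- length(samples) %/% frame_len
  if (n_frames == 0L) return(numeric(0))
  m <- matrix(samples[seq_len(n_frames * frame_len)], nrow = frame_len)
  rms <- sqrt(colMeans(m^2))
  20 * log10(rms)  # -Inf for all-zero frames, handled by callers
}

#' Detect syllables by amplitude threshold
#'
#' Frames the recording into short non-overlapping RMS windows, estimates the
#' noise floor as the median frame level, marks frames more than
#' `threshold_db` above it as active, and merges active runs separated by
#' silent gaps shorter than `hold_ms`.
#'
#' @param rec a [recording()].
#' @param threshold_db detection threshold in dB above the noise floor.
#' @param hold_ms hold time in ms: gaps shorter than this do not split a
#'   syllable.
#' @param frame_ms envelope frame length in ms.
#' @return a data.frame with columns `start_s`, `end_s`, `duration_ms`,
#'   sorted and non-overlapping; zero rows for silent input.
#' @export
detect_syllables <- function(rec, threshold_db = 10, hold_ms = 5,
                             frame_ms = 0.5) {
  stopifnot(inherits(rec, "pup_recording"))
  if (threshold_db <= 0) stop("threshold_db must be positive")
  if (hold_ms < 0) stop("hold_ms must be non-negative")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0))
  frame_len <- max(1L, as.integer(round(rec$sample_rate * frame_ms / 1000)))
  db <- frame_rms_db(rec$samples, frame_len)
  if (length(db) == 0L || all(!is.finite(db))) return(empty)
  noise_db <- stats::median(db)
  # with exact-zero silence the floor is -Inf; active frames are then simply
  # the non-silent ones (db > -Inf)
  active <- db > noise_db + if (is.finite(noise_db)) threshold_db else 0
  if (!any(active)) return(empty)
  r <- rle(active)
  # merge active runs separated by inactive gaps strictly shorter than hold_ms
  hold_frames <- hold_ms / 1000 * rec$sample_rate / frame_len
  keep_gap <- r$values == FALSE & r$lengths < hold_frames
  keep_gap[c(1L, length(r$values))] <- FALSE  # leading/trailing silence stays
  r2 <- rle(inverse.rle(list(values = r$values | keep_gap,
                             lengths = r$lengths)))
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  sel <- which(r2$values)
  frame_s <- frame_len / rec$sample_rate
  start_s <- (starts2[sel] - 1L) * frame_s
  end_s <- ends2[sel] * frame_s
  data.frame(start_s = start_s, end_s = end_s,
             duration_ms = 1000 * (end_s - start_s))
}

#' Compute a magnitude spectrogram
#'
#' Hamming-windowed short-time FFT with hop
#' `round(fft_length * (1 - overlap_fraction))` samples (at least 1), the
#' frequency axis truncated to `[freq_min, freq_max]` kHz. Linear magnitude is
#' returned, not power.
#'
#' @param rec a [recording()].
#' @param params a [spectrogram_params()] object.
#' @return an object of class `pup_spectrogram` with fields `magnitudes`
#'   (frames x bins), `frame_times` (s, frame centers), `bin_freqs` (kHz).
#' @export
compute_spectrogram <- function(rec, params = spectrogram_params()) {
  stopifnot(inherits(rec, "pup_recording"), inherits(params, "pup_spec_params"))
  nfft <- params$fft_length
  if (length(rec$samples) < nfft)
    stop(sprintf("recording too short: %d samples, need at least fft_length = %d",
                 length(rec$samples), nfft))
  hop <- max(1L, as.integer(round(nfft * (1 - params$overlap_fraction))))
  starts <- seq(1L, length(rec$samples) - nfft + 1L, by = hop)
  n <- 0:(nfft - 1L)
  win <- 0.54 - 0.46 * cos(2 * pi * n / (nfft - 1L))
  all_freqs <- (0:(nfft %/% 2L)) * rec$sample_rate / nfft / 1000
  band <- which(all_freqs >= params$freq_min & all_freqs <= params$freq_max)
  if (length(band) == 0L) stop("no frequency bins inside [freq_min, freq_max]")
  mags <- matrix(0, nrow = length(starts), ncol = length(band))
  chunk <- 2048L
  for (i0 in seq(1L, length(starts), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(starts))
    frames <- matrix(rec$samples[outer(n, starts[idx], "+")], nrow = nfft)
    frames <- frames * win
    sp <- stats::mvfft(frames)
    mags[idx, ] <- t(Mod(sp[band, , drop = FALSE]))
  }
  structure(list(magnitudes = mags,
                 frame_times = (starts - 1L + nfft / 2) / rec$sample_rate,
                 bin_freqs = all_freqs[band],
                 params = params),
            class = "pup_spectrogram")
}

#' @export
print.pup_spectrogram <- function(x, ...) {
  cat(sprintf("<pup_spectrogram> %d frames x %d bins, %.1f-%.1f kHz\n",
              nrow(x$magnitudes), ncol(x$magnitudes),
              min(x$bin_freqs), max(x$bin_freqs)))
  invisible(x)
}

#' Extract the nine-point dominant-frequency contour of a syllable
#'
#' Measurement times are placed at the interior midpoints
#' `start + (i + 0.5) / n_points * duration` (default), or at
#' endpoint-inclusive positions `start + i / (n_points - 1) * duration`.
#' At each time the nearest frame center is taken and the dominant frequency
#' is the bin of maximal magnitude (ties resolved toward the lower bin). The
#' raw contour is then bandpass-filtered with [bandpass_replace()].
#'
#' @param spec a `pup_spectrogram`.
#' @param seg one-row segment (list or data.frame row) with `start_s`, `end_s`.
#' @param n_points number of measurement points (9 in the standard protocol).
#' @param placement `"midpoint"` (default) or `"endpoint"`.
#' @param band_low,band_high contour bandpass bounds in kHz passed to
#'   [bandpass_replace()].
#' @return an object of class `pup_contour`: `raw_khz`, `filtered_khz`
#'   (length `n_points`), and `valid` (FALSE when every raw point is out of
#'   band).
#' @export
extract_contour <- function(spec, seg, n_points = 9L,
                            placement = c("midpoint", "endpoint"),
                            band_low = 41, band_high = 129) {
  stopifnot(inherits(spec, "pup_spectrogram"))
  placement <- match.arg(placement)
  start_s <- as.numeric(seg$start_s)
  end_s <- as.numeric(seg$end_s)
  if (end_s <= start_s) stop("segment must have end_s > start_s")
  ft <- spec$frame_times
  half_frame <- spec$params$fft_length / 2 / diff(range(ft)) # only for message
  if (start_s > max(ft) || end_s < min(ft))
    stop("segment lies outside the spectrogram's time span")
  dur <- end_s - start_s
  if (placement == "midpoint") {
    times <- start_s + (seq_len(n_points) - 0.5) / n_points * dur
  } else {
    times <- start_s + (seq_len(n_points) - 1) / (n_points - 1) * dur
  }
  in_span <- ft >= start_s & ft <= end_s
  if (!any(in_span))
    stop("segment shorter than one frame; use a larger FFT hop or longer segment")
  raw <- vapply(times, function(t) {
    fi <- which.min(abs(ft - t))
    spec$bin_freqs[which.max(spec$magnitudes[fi, ])]
  }, numeric(1))
  filt <- bandpass_replace(raw, low = band_low, high = band_high,
                           error_on_invalid = FALSE)
  structure(list(raw_khz = raw, filtered_khz = filt$values, valid = filt$valid),
            class = "pup_contour")
}

#' @export
print.pup_contour <- function(x, ...) {
  cat("<pup_contour> filtered (kHz):",
      paste(sprintf("%.1f", x$filtered_khz), collapse = " "),
      if (!x$valid) "[invalid: all points out of band]" else "", "\n")
  invisible(x)
}

#' Detect syllables and extract contours from one recording
#'
#' Convenience wrapper running [detect_syllables()], [compute_spectrogram()]
#' and [extract_contour()] and returning the interchange contour table used by
#' every downstream module.
#'
#' @param rec a [recording()].
#' @param params [spectrogram_params()].
#' @param threshold_db,hold_ms detection settings, see [detect_syllables()].
#' @param ... passed to [extract_contour()].
#' @return a data.frame with columns `source_id`, `syllable_index`, `f1..f9`
#'   (filtered kHz), `f1_raw..f9_raw`, `duration_ms`, `start_s`, `valid`.
#' @export
contour_table <- function(rec, params = spectrogram_params(),
                          threshold_db = 10, hold_ms = 5, ...) {
  segs <- detect_syllables(rec, threshold_db = threshold_db, hold_ms = hold_ms)
  if (nrow(segs) == 0L) return(empty_contour_table())
  spec <- compute_spectrogram(rec, params)
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    ct <- extract_contour(spec, segs[i, ], ...)
    row <- c(as.list(stats::setNames(ct$filtered_khz, paste0("f", 1:9))),
             as.list(stats::setNames(ct$raw_khz, paste0("f", 1:9, "_raw"))))
    row$duration_ms <- segs$duration_ms[i]
    row$start_s <- segs$start_s[i]
    row$valid <- ct$valid
    row
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  cbind(data.frame(source_id = rec$source_id,
                   syllable_index = seq_len(nrow(segs))), out)
}

empty_contour_table <- function() {
  cols <- c("source_id", "syllable_index", paste0("f", 1:9),
            paste0("f", 1:9, "_raw"), "duration_ms", "start_s", "valid")
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  out$source_id <- character(0)
  out$valid <- logical(0)
  out
}
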