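# signal_io: WAV round trips, detection, spectrogram framing, contour
# extraction.

test_that("WAV write/read round-trips PCM16 audio", {
  rec <- make_tone(7e4, 0.01)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 5e5)
  expect_equal(length(back$samples), length(rec$samples))
  expect_lt(max(abs(back$samples - rec$samples)), 1 / 32767 + 1e-12)
  not_wav <- withr::local_tempfile(fileext = ".txt", lines = "not audio data")
  expect_error(read_wav(not_wav), "RIFF")
})

test_that("recording validates its invariants", {
  expect_error(recording(numeric(0), 5e5), "at least one sample")
  expect_error(recording(c(0, NA), 5e5), "non-finite")
  expect_error(recording(0.1, 0), "positive")
})

test_that("detection finds nothing in silence or pure zeros", {
  expect_equal(nrow(detect_syllables(recording(numeric(5000), 5e5))), 0L)
  rec1s <- recording(numeric(5e5), 5e5)
  expect_equal(nrow(detect_syllables(rec1s)), 0L)
  expect_error(detect_syllables(recording(1, 5e5), threshold_db = 0))
})

test_that("a tone burst in weak noise is detected at its true extent", {
  rec <- make_bursts(list(c(0.1, 0.05)), total_s = 0.2)
  segs <- detect_syllables(rec)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$duration_ms, 50, tolerance = 5 / 50)
  expect_equal(segs$start_s, 0.1, tolerance = 0.05)
  expect_equal(segs$duration_ms, 1000 * (segs$end_s - segs$start_s))
})

test_that("hold time merges bursts split by a short gap, not a long one", {
  # 3 ms gap < 5 ms hold: one syllable
  rec <- make_bursts(list(c(0.02, 0.02), c(0.043, 0.02)), total_s = 0.1)
  expect_equal(nrow(detect_syllables(rec)), 1L)
  # 8 ms gap > 5 ms hold: two syllables
  rec2 <- make_bursts(list(c(0.02, 0.02), c(0.048, 0.02)), total_s = 0.1)
  segs2 <- detect_syllables(rec2)
  expect_equal(nrow(segs2), 2L)
  expect_true(all(diff(as.vector(t(segs2[, c("start_s", "end_s")]))) >= 0))
})

test_that("detection commutes with leading silence", {
  rec <- make_bursts(list(c(0.05, 0.03)), total_s = 0.12)
  shifted <- recording(c(numeric(0.04 * 5e5), rec$samples), 5e5)
  s1 <- detect_syllables(rec)
  s2 <- detect_syllables(shifted)
  expect_equal(s2$duration_ms, s1$duration_ms, tolerance = 0.05)
  expect_equal(s2$start_s - s1$start_s, 0.04, tolerance = 0.002)
})

test_that("spectrogram framing follows the hop arithmetic", {
  rec <- make_tone(7e4, 0.1)
  sp <- compute_spectrogram(rec)
  hop <- round(1024 * (1 - 0.9843))
  expect_equal(hop, 16)
  expect_equal(nrow(sp$magnitudes), floor((5e4 - 1024) / hop) + 1)
  expect_true(all(diff(sp$frame_times) > 0))
  expect_true(all(diff(sp$bin_freqs) > 0))
})

test_that("spectrogram peaks sit on the tone and the axis is truncated", {
  rec <- make_tone(7e4, 0.02)
  sp <- compute_spectrogram(rec)
  peaks <- sp$bin_freqs[apply(sp$magnitudes, 1, which.max)]
  expect_true(all(abs(peaks - 70) <= 0.5 * 5e5 / 1024 / 1000))
  expect_gte(min(sp$bin_freqs), 40)
  expect_lte(max(sp$bin_freqs), 130)
  expect_true(all(sp$magnitudes >= 0))
  expect_error(compute_spectrogram(recording(numeric(100) + 0.1, 5e5)),
               "fft_length")
})

test_that("contours track constant tones, sweeps, and jumps", {
  seg <- list(start_s = 0.005, end_s = 0.055)
  # constant 70 kHz
  rec <- make_tone(7e4, 0.06)
  ct <- extract_contour(compute_spectrogram(rec), seg)
  expect_length(ct$raw_khz, 9L)
  expect_true(all(abs(ct$raw_khz - 70) <= 0.5))
  expect_identical(ct$filtered_khz, ct$raw_khz)  # in-band filter is a no-op
  # linear sweep 60 -> 100 kHz across the segment
  fs <- 5e5
  t <- (seq_len(0.06 * fs) - 1) / fs
  finst <- ifelse(t < 0.005, 60e3,
                  ifelse(t > 0.055, 100e3, 60e3 + 40e3 * (t - 0.005) / 0.05))
  sweep_rec <- recording(0.5 * sin(2 * pi * cumsum(finst) / fs), fs)
  ct2 <- extract_contour(compute_spectrogram(sweep_rec), seg)
  expected <- 60 + 40 * (seq_len(9) - 0.5) / 9
  expect_true(all(abs(ct2$raw_khz - expected) <= 1))
  # amplitude scaling leaves the contour unchanged
  loud <- recording(2 * sweep_rec$samples / max(abs(2 * sweep_rec$samples)) * 0.9, fs)
  ct3 <- extract_contour(compute_spectrogram(loud), seg)
  expect_identical(ct3$raw_khz, ct2$raw_khz)
  # mid-syllable jump 65 -> 110 kHz: exactly one step
  finst2 <- ifelse(t < 0.03, 65e3, 110e3)
  jump_rec <- recording(0.5 * sin(2 * pi * cumsum(finst2) / fs), fs)
  ct4 <- extract_contour(compute_spectrogram(jump_rec), seg)
  expect_equal(count_steps(ct4$filtered_khz), 1L)
  # segment outside the spectrogram
  expect_error(extract_contour(compute_spectrogram(rec),
                               list(start_s = 5, end_s = 6)), "outside")
})

test_that("endpoint placement spans the segment ends", {
  fs <- 5e5
  t <- (seq_len(0.06 * fs) - 1) / fs
  finst <- ifelse(t < 0.005, 60e3,
                  ifelse(t > 0.055, 100e3, 60e3 + 40e3 * (t - 0.005) / 0.05))
  rec <- recording(0.5 * sin(2 * pi * cumsum(finst) / fs), fs)
  ct <- extract_contour(compute_spectrogram(rec),
                        list(start_s = 0.005, end_s = 0.055),
                        placement = "endpoint")
  expected <- 60 + 40 * (seq_len(9) - 1) / 8
  expect_true(all(abs(ct$raw_khz - expected) <= 1.5))
})
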