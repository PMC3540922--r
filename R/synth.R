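# Synthetic pup-call repertoires with exact ground truth.
#
# The generator emulates the repertoire structure reported for mouse pup
# isolation calls: two frequency bands for non-stepped syllables (low ~70 kHz,
# high ~100 kHz), smooth within-contour modulation whose adjacent-point deltas
# stay well below the 20 kHz step criterion, and discontinuous jumps well
# above it, so the generative step count is unambiguous by construction.

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Specify a synthetic repertoire
#'
#' Defaults encode the stated world of the generator: equal category mix;
#' low band N(70, 4^2) kHz and high band N(100, 5^2) kHz; smooth
#' adjacent-point deltas N(0, s^2) with the per-syllable scale `s` drawn from
#' Uniform(1, 5) kHz (a scale mixture: real non-stepped syllables range from
#' near-flat to strongly modulated, which makes the pooled directional-FM
#' distribution unimodal but heavy-tailed) and |delta| capped at
#' `smooth_cap_khz` = 15 < 20; jump magnitudes N(40, 8^2) kHz floored at
#' `step_floor_khz` = 25 > 20. One-step syllables jump upward once in the
#' second half of the contour (low start, high end); multi-step syllables jump
#' up in the first half and back down in the second (high middle).
#'
#' @param n_syllables number of syllables.
#' @param category_mix named proportions over low/high/one_step/multi_step,
#'   summing to 1.
#' @param low_band,high_band c(mean, sd) of band start frequencies, kHz.
#' @param smooth_sd_range range of the per-syllable smooth-delta sd, kHz.
#' @param smooth_cap_khz cap on |smooth delta|, must be below the step
#'   criterion.
#' @param step_mean_khz,step_sd_khz,step_floor_khz jump magnitude model; the
#'   floor must exceed the step criterion.
#' @param duration_ms_range uniform range of syllable durations, ms.
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @return object of class `pup_repertoire_spec`.
#' @export
repertoire_spec <- function(n_syllables = 4000L,
                            category_mix = c(low = 0.25, high = 0.25,
                                             one_step = 0.25,
                                             multi_step = 0.25),
                            low_band = c(mean = 70, sd = 4),
                            high_band = c(mean = 100, sd = 5),
                            smooth_sd_range = c(1, 5),
                            smooth_cap_khz = 15,
                            step_mean_khz = 40, step_sd_khz = 8,
                            step_floor_khz = 25,
                            duration_ms_range = c(20, 120),
                            seed = 1L) {
  if (is.null(names(category_mix)) ||
      !all(names(category_mix) %in% SYLLABLE_LABELS))
    stop("category_mix must be named with labels among: ",
         paste(SYLLABLE_LABELS, collapse = ", "))
  mix <- stats::setNames(rep(0, 4L), SYLLABLE_LABELS)
  mix[names(category_mix)] <- category_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("category_mix must sum to 1")
  if (any(mix < 0)) stop("category_mix proportions must be non-negative")
  if (smooth_cap_khz >= 20)
    stop("smooth_cap_khz must stay below the 20 kHz step criterion")
  if (step_floor_khz <= 20)
    stop("step_floor_khz must exceed the 20 kHz step criterion")
  structure(list(n_syllables = as.integer(n_syllables), category_mix = mix,
                 low_band = low_band, high_band = high_band,
                 smooth_sd_range = smooth_sd_range,
                 smooth_cap_khz = smooth_cap_khz,
                 step_mean_khz = step_mean_khz, step_sd_khz = step_sd_khz,
                 step_floor_khz = step_floor_khz,
                 duration_ms_range = duration_ms_range,
                 seed = as.integer(seed)),
            class = "pup_repertoire_spec")
}

smooth_deltas <- function(k, s, cap) clamp(stats::rnorm(k, 0, s), -cap, cap)

walk_from <- function(start, deltas, lo, hi) {
  out <- numeric(length(deltas) + 1L)
  out[1L] <- clamp(start, lo, hi)
  for (i in seq_along(deltas)) out[i + 1L] <- clamp(out[i] + deltas[i], lo, hi)
  out
}

#' Generate a synthetic repertoire
#'
#' @param spec a [repertoire_spec()].
#' @return data.frame in the interchange contour layout (`source_id`,
#'   `syllable_index`, `f1..f9`, `f1_raw..f9_raw`, `duration_ms`) plus the
#'   generator-truth column `true_label`.
#' @export
generate_repertoire <- function(spec = repertoire_spec()) {
  stopifnot(inherits(spec, "pup_repertoire_spec"))
  set.seed(spec$seed)
  n <- spec$n_syllables
  cats <- sample(SYLLABLE_LABELS, n, replace = TRUE, prob = spec$category_mix)
  dur <- stats::runif(n, spec$duration_ms_range[1L], spec$duration_ms_range[2L])
  cap <- spec$smooth_cap_khz
  lo_m <- spec$low_band[["mean"]]; lo_s <- spec$low_band[["sd"]]
  hi_m <- spec$high_band[["mean"]]; hi_s <- spec$high_band[["sd"]]
  jump <- function(k = 1L) pmax(stats::rnorm(k, spec$step_mean_khz,
                                             spec$step_sd_khz),
                                spec$step_floor_khz)
  contours <- matrix(0, n, 9L)
  for (i in seq_len(n)) {
    s <- stats::runif(1L, spec$smooth_sd_range[1L], spec$smooth_sd_range[2L])
    ct <- switch(cats[i],
      low = walk_from(stats::rnorm(1L, lo_m, lo_s), smooth_deltas(8L, s, cap),
                      41, 129),
      high = walk_from(stats::rnorm(1L, hi_m, hi_s), smooth_deltas(8L, s, cap),
                       41, 129),
      one_step = {
        # single upward jump in the second half: low start, pre-jump plateau
        # through the middle point, high end
        j <- sample(5:8, 1L)
        pre <- walk_from(stats::rnorm(1L, lo_m, lo_s),
                         smooth_deltas(j - 1L, s, cap), 41, 104)
        target <- clamp(pre[j] + jump(), 70, 129)
        post <- walk_from(target, smooth_deltas(8L - j, s, cap), 70, 129)
        c(pre, post)
      },
      multi_step = {
        # up in the first half, down in the second: high middle point
        j1 <- sample(1:4, 1L)
        j2 <- sample(5:8, 1L)
        pre <- walk_from(stats::rnorm(1L, lo_m, lo_s),
                         smooth_deltas(j1 - 1L, s, cap), 41, 104)
        up <- clamp(pre[j1] + jump(), 70, 129)
        mid <- walk_from(up, smooth_deltas(j2 - j1 - 1L, s, cap), 70, 129)
        down <- max(mid[length(mid)] - jump(), 41)
        post <- walk_from(down, smooth_deltas(8L - j2, s, cap), 41, 104)
        c(pre, mid, post)
      })
    contours[i, ] <- ct
  }
  out <- data.frame(source_id = sprintf("synthetic_seed%d", spec$seed),
                    syllable_index = seq_len(n))
  colnames(contours) <- paste0("f", 1:9)
  out <- cbind(out, as.data.frame(contours))
  raw <- contours
  colnames(raw) <- paste0("f", 1:9, "_raw")
  out <- cbind(out, as.data.frame(raw))
  out$duration_ms <- dur
  out$true_label <- cats
  out
}

#' Synthesize audio for a contour
#'
#' Renders a phase-continuous frequency-modulated tone whose instantaneous
#' frequency passes through the nine contour points (placed at the interior
#' midpoints of the syllable, matching [extract_contour()]'s default),
#' linearly interpolated within jump-free spans and truly discontinuous at
#' the midpoint between two points whose transition exceeds the step
#' criterion. A raised-cosine onset/offset ramp and silent padding complete
#' the recording.
#'
#' @param contour numeric vector of 9 frequencies in \[41, 129\] kHz.
#' @param duration_ms syllable duration, ms.
#' @param sample_rate Hz.
#' @param amplitude peak amplitude in (0, 1\].
#' @param ramp_ms onset/offset ramp, ms.
#' @param pad_ms silent padding on each side, ms.
#' @param source_id identifier for the returned recording.
#' @return a [recording()].
#' @export
synthesize_audio <- function(contour, duration_ms, sample_rate = 500000,
                             amplitude = 0.5, ramp_ms = 5, pad_ms = 60,
                             source_id = "synthetic") {
  contour <- as.numeric(contour)
  if (length(contour) != 9L) stop("contour must have exactly 9 points")
  if (any(contour < 41 | contour > 129))
    stop("contour out of band: all points must lie in [41, 129] kHz")
  dur_s <- duration_ms / 1000
  n_syl <- max(2L, round(dur_s * sample_rate))
  t <- (seq_len(n_syl) - 0.5) / sample_rate
  pt_times <- (seq_len(9L) - 0.5) / 9 * dur_s
  steps <- which(abs(diff(contour)) > 20)
  # instantaneous frequency: piecewise linear through the points inside each
  # jump-free span; held flat before the first and after the last point
  span_bounds <- c(0, (pt_times[steps] + pt_times[steps + 1L]) / 2, dur_s)
  freq <- numeric(n_syl)
  span_start <- c(1L, steps + 1L)
  span_end <- c(steps, 9L)
  for (sp in seq_along(span_start)) {
    sel <- t >= span_bounds[sp] & t <= span_bounds[sp + 1L]
    pts <- span_start[sp]:span_end[sp]
    if (length(pts) == 1L) {
      freq[sel] <- contour[pts]
    } else {
      freq[sel] <- stats::approx(pt_times[pts], contour[pts], xout = t[sel],
                                 rule = 2)$y
    }
  }
  phase <- cumsum(2 * pi * freq * 1000 / sample_rate)
  env <- rep(amplitude, n_syl)
  n_ramp <- min(round(ramp_ms / 1000 * sample_rate), floor(n_syl / 2))
  if (n_ramp > 0L) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
    env[seq_len(n_ramp)] <- env[seq_len(n_ramp)] * ramp
    env[n_syl - n_ramp + seq_len(n_ramp)] <- env[n_syl - n_ramp + seq_len(n_ramp)] *
      rev(ramp)
  }
  pad <- numeric(round(pad_ms / 1000 * sample_rate))
  recording(c(pad, env * sin(phase), pad), sample_rate, source_id)
}
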