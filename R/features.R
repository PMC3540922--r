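# Derived per-syllable quantities and the bimodality-coefficient machinery
# that justifies the classification thresholds.

#' Bandpass-filter a nine-point contour by replacement
#'
#' Dominant-frequency trackers produce spurious values at the spectrogram
#' extremes during low-amplitude portions of a syllable. Values outside
#' `[low, high]` kHz are replaced by the nearest preceding in-band (or
#' already-replaced) value; a leading run of out-of-band values is back-filled
#' from the first in-band value, so the filter never manufactures out-of-band
#' output. The operation is idempotent.
#'
#' @param raw numeric vector of 9 contour frequencies, kHz.
#' @param low,high band bounds in kHz.
#' @param error_on_invalid if TRUE (default), an all-out-of-band contour is an
#'   error; otherwise it is returned unchanged with `valid = FALSE`.
#' @return with `error_on_invalid = TRUE`, the filtered numeric vector;
#'   otherwise a list with `values` and `valid`.
#' @export
bandpass_replace <- function(raw, low = 41, high = 129,
                             error_on_invalid = TRUE) {
  raw <- as.numeric(raw)
  if (length(raw) != 9L) stop("contour must have exactly 9 points")
  in_band <- is.finite(raw) & raw >= low & raw <= high
  if (!any(in_band)) {
    if (error_on_invalid)
      stop("invalid syllable: all 9 contour points outside [", low, ", ", high,
           "] kHz")
    return(list(values = raw, valid = FALSE))
  }
  out <- raw
  first_ok <- which(in_band)[1L]
  if (first_ok > 1L) out[seq_len(first_ok - 1L)] <- out[first_ok]
  for (i in seq(first_ok + 1L, length.out = max(0L, 9L - first_ok))) {
    if (!in_band[i]) out[i] <- out[i - 1L]
  }
  if (error_on_invalid) out else list(values = out, valid = TRUE)
}

#' Adjacent-point frequency transitions of a contour
#'
#' @param contour numeric vector of 9 contour frequencies, kHz.
#' @return the 8 signed deltas `contour[i+1] - contour[i]`, kHz.
#' @export
contour_transitions <- function(contour) {
  contour <- as.numeric(contour)
  if (length(contour) != 9L) stop("contour must have exactly 9 points")
  diff(contour)
}

#' Count frequency steps in a contour
#'
#' A frequency step is a spectro-temporal discontinuity: an adjacent-point
#' transition whose absolute value exceeds `step_threshold_khz` (strictly;
#' set `inclusive = TRUE` for >=).
#'
#' @param contour numeric vector of 9 contour frequencies, kHz.
#' @param step_threshold_khz step criterion, kHz.
#' @param inclusive count transitions equal to the threshold as steps.
#' @return integer count of steps (0..8).
#' @export
count_steps <- function(contour, step_threshold_khz = 20, inclusive = FALSE) {
  d <- abs(contour_transitions(contour))
  if (any(!is.finite(d))) stop("contour contains non-finite values")
  if (inclusive) sum(d >= step_threshold_khz) else sum(d > step_threshold_khz)
}

#' Summarize one contour into classifier features
#'
#' @param contour a `pup_contour` or a numeric vector of 9 filtered kHz values.
#' @param duration_ms syllable duration in ms.
#' @param step_threshold_khz step criterion passed to [count_steps()].
#' @return a one-row data.frame: `start_khz`, `middle_khz`, `end_khz`,
#'   `mean_khz`, `bandwidth_khz`, `n_steps`, `directional_fm_khz`,
#'   `duration_ms`.
#' @export
summarize_syllable <- function(contour, duration_ms = NA_real_,
                               step_threshold_khz = 20) {
  if (inherits(contour, "pup_contour")) {
    if (!contour$valid) stop("invalid contour: all points out of band")
    contour <- contour$filtered_khz
  }
  contour <- as.numeric(contour)
  if (length(contour) != 9L) stop("contour must have exactly 9 points")
  data.frame(start_khz = contour[1L], middle_khz = contour[5L],
             end_khz = contour[9L], mean_khz = mean(contour),
             bandwidth_khz = max(contour) - min(contour),
             n_steps = count_steps(contour, step_threshold_khz),
             directional_fm_khz = contour[9L] - contour[1L],
             duration_ms = as.numeric(duration_ms))
}

#' Build the features table from a contour table
#'
#' Consumes the interchange contour CSV layout (`f1..f9` filtered kHz plus
#' `duration_ms`; one row per syllable). The bandpass replacement is re-applied
#' so that raw Avisoft-style exports can be fed in directly; rows whose nine
#' points are all out of band are flagged `valid = FALSE` with NA features and
#' reported with a warning, not dropped.
#'
#' @param contours data.frame with columns `f1..f9` and optionally
#'   `duration_ms`.
#' @param step_threshold_khz step criterion, kHz.
#' @param band_low,band_high contour bandpass bounds, kHz.
#' @return data.frame of per-syllable features with a `valid` column.
#' @export
features_table <- function(contours, step_threshold_khz = 20,
                           band_low = 41, band_high = 129) {
  fcols <- paste0("f", 1:9)
  missing_cols <- setdiff(fcols, names(contours))
  if (length(missing_cols) > 0L)
    stop("contour table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(contours)
  if (n == 0L) stop("contour table is empty")
  dur <- if ("duration_ms" %in% names(contours)) contours$duration_ms
         else rep(NA_real_, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    raw <- as.numeric(contours[i, fcols])
    filt <- bandpass_replace(raw, low = band_low, high = band_high,
                             error_on_invalid = FALSE)
    if (!filt$valid) {
      row <- data.frame(start_khz = NA_real_, middle_khz = NA_real_,
                        end_khz = NA_real_, mean_khz = NA_real_,
                        bandwidth_khz = NA_real_, n_steps = NA_integer_,
                        directional_fm_khz = NA_real_,
                        duration_ms = as.numeric(dur[i]))
    } else {
      row <- summarize_syllable(filt$values, dur[i], step_threshold_khz)
    }
    row$valid <- filt$valid
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(!res$valid))
    warning(sum(!res$valid),
            " syllable(s) had all contour points out of band and were flagged invalid")
  res
}

#' Bimodality coefficient
#'
#' The moment-based coefficient
#' `b = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))`
#' with `g1` the sample skewness and `g2` the sample excess kurtosis
#' (bias-corrected SAS definitions). Asymptotic reference values: uniform
#' 5/9 ~ 0.555 (the conventional evidence threshold for more than one mode),
#' normal 1/3, a two-point 50/50 mixture 1.
#'
#' @param x numeric sample, n >= 4, non-degenerate.
#' @return object of class `pup_bimodality`: `b`, `skewness`, `kurtosis`
#'   (excess), `n`.
#' @export
bimodality_coefficient <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("sample contains non-finite values")
  n <- length(x)
  if (n < 4L) stop("bimodality coefficient requires n >= 4")
  s <- stats::sd(x)
  if (s == 0) stop("bimodality coefficient undefined for zero-variance sample")
  z <- (x - mean(x)) / s
  g1 <- n / ((n - 1) * (n - 2)) * sum(z^3)
  g2 <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  b <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  structure(list(b = b, skewness = g1, kurtosis = g2, n = n),
            class = "pup_bimodality")
}

#' @export
print.pup_bimodality <- function(x, ...) {
  cat(sprintf("<bimodality> b = %.3f (skewness %.3f, excess kurtosis %.3f, n = %d); b > 5/9 suggests > 1 mode\n",
              x$b, x$skewness, x$kurtosis, x$n))
  invisible(x)
}

#' Suggest a classification boundary from a bimodal sample
#'
#' Used to place the high/low frequency boundary (and to audit the step
#' criterion) per strain: a histogram is built, its two dominant well-separated
#' peaks are located, and the boundary is either the midpoint of the peak
#' centers (`"midway_peaks"`) or the center of the emptiest bin between them
#' (`"histogram_valley"`). If the sample shows no evidence of two modes
#' (bimodality coefficient `b <= 5/9`) no boundary is returned and a warning is
#' raised.
#'
#' @param values numeric sample, kHz; n >= 50.
#' @param mode `"midway_peaks"` or `"histogram_valley"`.
#' @param bin_width_khz histogram bin width, kHz.
#' @param min_separation_bins minimum peak separation, in bins.
#' @return list with `boundary_khz` (NA when unimodal), `histogram`
#'   (data.frame `mid`, `count`), `bimodality`, `peaks_khz`, `unimodal`.
#' @export
suggest_boundary <- function(values, mode = c("midway_peaks", "histogram_valley"),
                             bin_width_khz = 2, min_separation_bins = 3) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (length(values) < 50L) stop("need at least 50 values to place a boundary")
  bim <- bimodality_coefficient(values)
  breaks <- seq(floor(min(values) / bin_width_khz) * bin_width_khz,
                ceiling(max(values) / bin_width_khz) * bin_width_khz +
                  bin_width_khz, by = bin_width_khz)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  hist_df <- data.frame(mid = h$mids, count = h$counts)
  if (bim$b <= 5 / 9) {
    warning(sprintf("no evidence of two modes (b = %.3f <= 5/9); no boundary suggested",
                    bim$b))
    return(list(boundary_khz = NA_real_, histogram = hist_df, bimodality = bim,
                peaks_khz = NA_real_, unimodal = TRUE))
  }
  i1 <- which.max(h$counts)
  cand <- which(abs(seq_along(h$counts) - i1) >= min_separation_bins)
  if (length(cand) == 0L) stop("histogram too narrow to separate two peaks")
  i2 <- cand[which.max(h$counts[cand])]
  peaks <- sort(h$mids[c(i1, i2)])
  between <- which(h$mids > peaks[1L] & h$mids < peaks[2L])
  boundary <- if (mode == "midway_peaks") mean(peaks)
              else h$mids[between[which.min(h$counts[between])]]
  list(boundary_khz = boundary, histogram = hist_df, bimodality = bim,
       peaks_khz = peaks, unimodal = FALSE)
}
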