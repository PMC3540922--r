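# The rule-based syllable classification calculator: a deterministic, total
# mapping from contour features to the four statistically derived syllable
# types, with strain-adjustable frequency boundaries.

SYLLABLE_LABELS <- c("low", "high", "one_step", "multi_step")

#' Strain threshold presets
#'
#' Step criterion 20 kHz for all strains; the high/low mean-frequency boundary
#' is strain-specific: 85 kHz (CBA/CaJ), 73 kHz (IRW), 70 kHz (C57BL/6).
#'
#' @param name strain name, or any name when both thresholds are supplied.
#' @param step_threshold_khz,high_low_boundary_khz explicit thresholds for
#'   strains without a preset.
#' @return object of class `pup_thresholds`: `strain_name`,
#'   `step_threshold_khz`, `high_low_boundary_khz`.
#' @export
strain_preset <- function(name, step_threshold_khz = NULL,
                          high_low_boundary_khz = NULL) {
  presets <- list("CBA/CaJ" = 85, "IRW" = 73, "C57BL/6" = 70)
  if (is.null(high_low_boundary_khz)) {
    if (!name %in% names(presets))
      stop("unknown strain '", name, "'; available presets: ",
           paste(names(presets), collapse = ", "),
           ". Supply high_low_boundary_khz explicitly for other strains.")
    high_low_boundary_khz <- presets[[name]]
  }
  if (is.null(step_threshold_khz)) step_threshold_khz <- 20
  if (step_threshold_khz <= 0) stop("step_threshold_khz must be positive")
  if (high_low_boundary_khz < 41 || high_low_boundary_khz > 129)
    stop("high_low_boundary_khz must lie within the contour band [41, 129] kHz")
  structure(list(strain_name = name,
                 step_threshold_khz = step_threshold_khz,
                 high_low_boundary_khz = high_low_boundary_khz),
            class = "pup_thresholds")
}

#' @export
print.pup_thresholds <- function(x, ...) {
  cat(sprintf("<pup_thresholds> %s: step > %g kHz, high/low boundary %g kHz\n",
              x$strain_name, x$step_threshold_khz, x$high_low_boundary_khz))
  invisible(x)
}

#' Classify one syllable
#'
#' The four rules, applied in order: more than 1 frequency step ->
#' `multi_step`; exactly 1 -> `one_step`; otherwise `high` when the mean
#' contour frequency is greater than or equal to the boundary, else `low`.
#' Total and deterministic.
#'
#' @param features one-row data.frame (or list) with `n_steps` and `mean_khz`.
#' @param thresholds a [strain_preset()] object.
#' @return one of `"low"`, `"high"`, `"one_step"`, `"multi_step"`.
#' @export
classify_syllable <- function(features, thresholds = strain_preset("CBA/CaJ")) {
  n_steps <- as.numeric(features$n_steps)
  mean_khz <- as.numeric(features$mean_khz)
  if (!is.finite(n_steps) || !is.finite(mean_khz))
    stop("features must contain finite n_steps and mean_khz")
  if (n_steps > 1) "multi_step"
  else if (n_steps == 1) "one_step"
  else if (mean_khz >= thresholds$high_low_boundary_khz) "high"
  else "low"
}

#' Classify a table of syllables
#'
#' @param features data.frame of per-syllable features (see
#'   [features_table()]); an optional `valid` column flags rows excluded
#'   upstream, which are labeled NA and reported, not dropped.
#' @param thresholds a [strain_preset()] object.
#' @return object of class `pup_classification`: `labels` (factor, NA for
#'   invalid rows), `proportions` (over the four categories, valid rows),
#'   `n_invalid`, `thresholds`.
#' @export
classify_table <- function(features, thresholds = strain_preset("CBA/CaJ")) {
  if (nrow(features) == 0L) stop("features table is empty")
  valid <- if ("valid" %in% names(features)) features$valid
           else rep(TRUE, nrow(features))
  labels <- rep(NA_character_, nrow(features))
  for (i in which(valid)) {
    labels[i] <- classify_syllable(features[i, ], thresholds)
  }
  labels <- factor(labels, levels = SYLLABLE_LABELS)
  props <- prop.table(table(labels[valid]))
  structure(list(labels = labels,
                 proportions = as.numeric(props[SYLLABLE_LABELS]) |>
                   stats::setNames(SYLLABLE_LABELS),
                 n_invalid = sum(!valid),
                 thresholds = thresholds),
            class = "pup_classification")
}

#' @export
print.pup_classification <- function(x, ...) {
  cat(sprintf("<pup_classification> %d syllables (%d invalid) at boundary %g kHz\n",
              length(x$labels), x$n_invalid,
              x$thresholds$high_low_boundary_khz))
  print(round(x$proportions, 3))
  invisible(x)
}

all_injective_maps <- function(from, to) {
  # all injective mappings from -> to, as a list of named character vectors
  if (length(from) == 0L) return(list(character(0)))
  out <- list()
  for (t in to) {
    rest <- all_injective_maps(from[-1L], setdiff(to, t))
    out <- c(out, lapply(rest, function(m) c(stats::setNames(t, from[1L]), m)))
  }
  out
}

#' Agreement (coherence) between two labelings
#'
#' Percent of identically-labeled syllables after an optimal one-to-one
#' mapping of the label alphabets (needed when comparing anonymous cluster
#' indices with named calculator categories). The mapping maximizing total
#' agreement is found by exhaustive search over injective maps from the
#' smaller alphabet into the larger.
#'
#' @param labels_a,labels_b equal-length label vectors (factors, characters,
#'   or integers). Pairs with an NA on either side are excluded from the
#'   comparison.
#' @return object of class `pup_agreement`: `coherence_pct`, `confusion`
#'   (contingency table in the mapped space), `mapping`, `n`.
#' @export
agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  if (length(labels_a) == 0L) stop("label vectors are empty")
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) stop("no non-missing label pairs to compare")
  ua <- unique(a); ub <- unique(b)
  swap <- length(ua) > length(ub)
  if (swap) { tmp <- a; a <- b; b <- tmp; tmp <- ua; ua <- ub; ub <- tmp }
  tab <- table(factor(a, ua), factor(b, ub))
  n_maps <- prod(length(ub) - seq_along(ua) + 1L)
  if (n_maps <= 1e6) {
    maps <- all_injective_maps(ua, ub)
    scores <- vapply(maps, function(m) sum(tab[cbind(ua, m[ua])]), numeric(1))
    best <- maps[[which.max(scores)]]
    best_score <- max(scores)
  } else {
    # greedy fallback for pathologically large alphabets
    best <- stats::setNames(character(length(ua)), ua)
    t2 <- matrix(as.numeric(tab), nrow(tab), dimnames = dimnames(tab))
    for (step in seq_along(ua)) {
      idx <- which(t2 == max(t2), arr.ind = TRUE)[1L, ]
      best[rownames(t2)[idx[1L]]] <- colnames(t2)[idx[2L]]
      t2[idx[1L], ] <- -Inf
      t2[, idx[2L]] <- -Inf
    }
    best_score <- sum(tab[cbind(ua, best[ua])])
  }
  a_mapped <- best[a]
  confusion <- table(a_mapped = factor(a_mapped, ub), b = factor(b, ub))
  structure(list(coherence_pct = 100 * best_score / n,
                 confusion = confusion,
                 mapping = best, n = n, swapped = swap),
            class = "pup_agreement")
}

#' @export
print.pup_agreement <- function(x, ...) {
  cat(sprintf("<pup_agreement> %.1f%% coherence over %d syllables\n",
              x$coherence_pct, x$n))
  print(x$confusion)
  invisible(x)
}

#' Reference per-age syllable counts of the CBA/CaJ data set
#'
#' Published sample sizes of the clustering data set by postnatal age (p5,
#' p7, p11, p13); used for arithmetic sanity checks. Their sum is the printed
#' total of 15,116 syllables.
#'
#' @return named integer vector.
#' @export
cba_syllable_counts <- function() {
  c(p5 = 3145L, p7 = 4329L, p11 = 4560L, p13 = 3082L)
}
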