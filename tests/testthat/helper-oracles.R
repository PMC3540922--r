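# Independent oracles and small signal builders used across the suite.
# The oracles deliberately use plain loops and their own formulas so they
# share no code path with the implementations they check.

# direct-moment bimodality oracle: explicit sums, no shared code
oracle_bimodality <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s2 <- sum((x - m)^2) / (n - 1)
  s <- sqrt(s2)
  g1 <- (n / ((n - 1) * (n - 2))) * sum((x - m)^3) / s^3
  g2 <- (n * (n + 1) / ((n - 1) * (n - 2) * (n - 3))) * sum((x - m)^4) / s^4 -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# exhaustive O(n^3) agglomeration with its own xi implementation
oracle_agglomerate <- function(X, gv, k_keep = integer(0)) {
  xi_of <- function(e) {
    v <- e$ss / e$n - (e$ls / e$n)^2
    v[v < 0] <- 0
    -e$n * sum(0.5 * log(gv + v))
  }
  ents <- lapply(seq_len(nrow(X)), function(i)
    list(n = 1, ls = X[i, ], ss = X[i, ]^2, members = i))
  parts <- list()
  dists <- numeric(0)
  while (length(ents) > 1) {
    m <- length(ents)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        mer <- list(n = ents[[i]]$n + ents[[j]]$n,
                    ls = ents[[i]]$ls + ents[[j]]$ls,
                    ss = ents[[i]]$ss + ents[[j]]$ss)
        d <- xi_of(ents[[i]]) + xi_of(ents[[j]]) - xi_of(mer)
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    ents[[i]] <- list(n = ents[[i]]$n + ents[[j]]$n,
                      ls = ents[[i]]$ls + ents[[j]]$ls,
                      ss = ents[[i]]$ss + ents[[j]]$ss,
                      members = c(ents[[i]]$members, ents[[j]]$members))
    ents[[j]] <- NULL
    dists <- c(dists, best[1])
    if (length(ents) %in% k_keep) {
      assign <- integer(nrow(X))
      for (c in seq_along(ents)) assign[ents[[c]]$members] <- c
      parts[[as.character(length(ents))]] <- assign
    }
  }
  list(parts = parts, dists = dists)
}

# naive double-loop silhouette on standardized variables
oracle_silhouette <- function(X, labels) {
  Xs <- scale(as.matrix(X))
  n <- nrow(Xs)
  d <- as.matrix(stats::dist(Xs))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(c) mean(d[i, labels == c]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# canonical relabeling so partitions can be compared up to renaming
canonical_partition <- function(x) match(x, unique(x))

make_tone <- function(freq_hz, dur_s, fs = 5e5, amp = 0.5) {
  recording(amp * sin(2 * pi * freq_hz * (seq_len(round(dur_s * fs)) - 1) / fs),
            fs, "tone")
}

# tone burst(s) embedded in weak Gaussian noise; bursts given as
# list(c(start_s, dur_s), ...)
make_bursts <- function(bursts, total_s, freq_hz = 7e4, fs = 5e5, amp = 0.5,
                        noise_sd = 1e-4, seed = 42) {
  set.seed(seed)
  x <- stats::rnorm(round(total_s * fs), 0, noise_sd)
  t <- (seq_along(x) - 1) / fs
  for (b in bursts) {
    idx <- which(t >= b[1] & t < b[1] + b[2])
    x[idx] <- x[idx] + amp * sin(2 * pi * freq_hz * t[idx])
  }
  recording(x, fs, "bursts")
}

fcols <- paste0("f", 1:9)
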