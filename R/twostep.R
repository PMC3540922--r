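# Two-step cluster analysis: CF-entry pre-clustering (BIRCH-style), the
# log-likelihood merge distance for continuous variables, greedy agglomerative
# merging, BIC-based selection of the number of clusters with a two-stage
# ratio rule, and the silhouette of cohesion.
#
# A cluster feature (CF) entry stores (n, per-variable sum, per-variable sum
# of squares); every operation below works on these sufficient statistics, so
# merges are exact and the original rows are only touched for the final
# assignment and the silhouette.

cf_variance <- function(n, ls, ss) {
  v <- ss / n - (ls / n)^2
  v[v < 0] <- 0
  v
}

# tightness xi(v) = -n_v * sum_k 0.5 * log(gv_k + var_vk); gv is the global
# per-variable variance acting as a regularizer so singletons are well-defined
cf_xi <- function(n, ls, ss, gv) {
  if (length(n) == 0L) return(numeric(0))
  v <- cf_variance(n, ls, ss)
  -n * rowSums(0.5 * log(sweep(v, 2, gv, "+")))
}

# distances from one CF entry (ne, lse, sse, xie) to a set of entries
cf_dists_to_cf <- function(ne, lse, sse, xie, n, ls, ss, gv, xi) {
  nm <- n + ne
  lsm <- sweep(ls, 2, lse, "+")
  ssm <- sweep(ss, 2, sse, "+")
  v <- ssm / nm - (lsm / nm)^2
  v[v < 0] <- 0
  xim <- -nm * rowSums(0.5 * log(sweep(v, 2, gv, "+")))
  xi + xie - xim
}

cf_pair_dists <- function(n, ls, ss, gv, xi = cf_xi(n, ls, ss, gv)) {
  L <- length(n)
  Nij <- outer(n, n, "+")
  acc <- matrix(0, L, L)
  for (k in seq_along(gv)) {
    LSij <- outer(ls[, k], ls[, k], "+")
    SSij <- outer(ss[, k], ss[, k], "+")
    v <- SSij / Nij - (LSij / Nij)^2
    v[v < 0] <- 0
    acc <- acc + 0.5 * log(gv[k] + v)
  }
  D <- outer(xi, xi, "+") + Nij * acc
  diag(D) <- Inf
  D
}

population_variances <- function(X) {
  n <- nrow(X)
  v <- apply(X, 2, function(col) sum((col - mean(col))^2) / n)
  pmax(v, 1e-12)
}

#' Log-likelihood distance between two clusters
#'
#' `d(a, b) = xi(a) + xi(b) - xi(a U b)` with the tightness
#' `xi(v) = -n_v * sum_k 0.5 * log(gv_k + var_vk)`, where `gv_k` is the global
#' variance of variable k and `var_vk` the within-cluster (population)
#' variance. Symmetric and non-negative; merging identical singletons costs 0.
#'
#' @param a,b cluster-feature entries: lists with `n` (count), `linear_sum`
#'   and `square_sum` (numeric vectors over the same variables).
#' @param global_variances per-variable global variances.
#' @return non-negative scalar distance.
#' @export
log_likelihood_distance <- function(a, b, global_variances) {
  p <- length(global_variances)
  if (length(a$linear_sum) != p || length(b$linear_sum) != p)
    stop("entries and global_variances must share the same variable set")
  one <- function(e) cf_xi(e$n, matrix(e$linear_sum, 1L),
                           matrix(e$square_sum, 1L), global_variances)
  merged <- list(n = a$n + b$n, linear_sum = a$linear_sum + b$linear_sum,
                 square_sum = a$square_sum + b$square_sum)
  one(a) + one(b) - one(merged)
}

#' Screen clustering variables for collinearity
#'
#' Two-step clustering is unreliable when input variables are correlated above
#' |r| = 0.9; this computes all pairwise Pearson correlations and flags such
#' pairs with a warning. Constant variables have undefined correlations and
#' are flagged as such.
#'
#' @param data data.frame or matrix of numeric clustering variables
#'   (>= 2 columns, >= 3 rows).
#' @param r_threshold flagging threshold on |r|.
#' @return object of class `pup_collinearity`: `pairwise_r` (symmetric matrix,
#'   unit diagonal), `flagged_pairs` (data.frame), `undefined_vars`.
#' @export
check_collinearity <- function(data, r_threshold = 0.9) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (ncol(X) < 2L || nrow(X) < 3L)
    stop("need at least 2 variables and 3 rows")
  sds <- apply(X, 2, stats::sd)
  undefined <- colnames(X)[sds == 0]
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  pairs <- which(upper.tri(r) & (is.na(r) | abs(r) > r_threshold),
                 arr.ind = TRUE)
  flagged <- data.frame(var1 = colnames(X)[pairs[, 1L]],
                        var2 = colnames(X)[pairs[, 2L]],
                        r = r[pairs])
  if (nrow(flagged) > 0L)
    warning("variable pair(s) with |r| > ", r_threshold, " or undefined r: ",
            paste(paste(flagged$var1, flagged$var2, sep = "~"), collapse = ", "))
  structure(list(pairwise_r = r, flagged_pairs = flagged,
                 undefined_vars = undefined),
            class = "pup_collinearity")
}

#' Pre-cluster rows into CF entries
#'
#' Sequential BIRCH-style pass: each row is absorbed into its closest entry
#' (log-likelihood distance) when within the current threshold, otherwise it
#' opens a new entry. When the number of entries exceeds the capacity
#' `max_branches ^ max_depth` the structure is rebuilt with a larger threshold.
#' The entry set is height-collapsed (a flat leaf list with the capacity the
#' tree shape implies); see the methods vignette.
#'
#' @param data numeric matrix/data.frame of clustering variables.
#' @param max_branches,max_depth CF-tree shape; capacity is
#'   `max_branches ^ max_depth` (512 at the defaults 8 and 3).
#' @param disable return one singleton entry per row (oracle mode).
#' @param global_variances per-variable global variances; computed from `data`
#'   when NULL.
#' @return object of class `pup_cf_entries`: `n`, `linear_sum`, `square_sum`
#'   (entries x variables), `row_entry` (row -> entry index),
#'   `global_variances`, `threshold`.
#' @export
precluster <- function(data, max_branches = 8L, max_depth = 3L,
                       disable = FALSE, global_variances = NULL) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L) stop("need at least one row")
  if (max_branches < 2L) stop("max_branches must be at least 2")
  if (max_depth < 1L) stop("max_depth must be at least 1")
  gv <- if (is.null(global_variances)) population_variances(X)
        else pmax(global_variances, 1e-12)
  if (disable) {
    return(structure(list(n = rep(1, nrow(X)), linear_sum = X,
                          square_sum = X^2, row_entry = seq_len(nrow(X)),
                          global_variances = gv, threshold = 0),
                     class = "pup_cf_entries"))
  }
  cap <- as.integer(max_branches)^as.integer(max_depth)
  p <- ncol(X)
  en <- numeric(0)
  els <- matrix(0, 0L, p)
  ess <- matrix(0, 0L, p)
  exi <- numeric(0)
  threshold <- 0
  row_entry <- integer(nrow(X))

  reinsert <- function(thr) {
    # re-insert current entries (as CFs) into a fresh list, merging within thr
    m <- length(en)
    nn <- numeric(0); nls <- matrix(0, 0L, p); nss <- matrix(0, 0L, p)
    nxi <- numeric(0)
    remap <- integer(m)
    for (e in seq_len(m)) {
      xie <- cf_xi(en[e], els[e, , drop = FALSE], ess[e, , drop = FALSE], gv)
      if (length(nn) > 0L) {
        d <- cf_dists_to_cf(en[e], els[e, ], ess[e, ], xie, nn, nls, nss, gv, nxi)
        j <- which.min(d)
        if (d[j] <= thr) {
          nn[j] <- nn[j] + en[e]
          nls[j, ] <- nls[j, ] + els[e, ]
          nss[j, ] <- nss[j, ] + ess[e, ]
          nxi[j] <- cf_xi(nn[j], nls[j, , drop = FALSE], nss[j, , drop = FALSE], gv)
          remap[e] <- j
          next
        }
      }
      nn <- c(nn, en[e]); nls <- rbind(nls, els[e, ]); nss <- rbind(nss, ess[e, ])
      nxi <- c(nxi, xie)
      remap[e] <- length(nn)
    }
    en <<- nn; els <<- nls; ess <<- nss; exi <<- nxi
    remap
  }

  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    placed <- FALSE
    if (length(en) > 0L) {
      xi_x <- -sum(0.5 * log(gv))
      d <- cf_dists_to_cf(1, x, x^2, xi_x, en, els, ess, gv, exi)
      j <- which.min(d)  # ties resolve to the lowest index
      if (d[j] <= threshold) {
        en[j] <- en[j] + 1
        els[j, ] <- els[j, ] + x
        ess[j, ] <- ess[j, ] + x^2
        exi[j] <- cf_xi(en[j], els[j, , drop = FALSE], ess[j, , drop = FALSE], gv)
        row_entry[i] <- j
        placed <- TRUE
      }
    }
    if (!placed) {
      en <- c(en, 1)
      els <- rbind(els, x)
      ess <- rbind(ess, x^2)
      exi <- c(exi, -sum(0.5 * log(gv)))
      row_entry[i] <- length(en)
    }
    while (length(en) > cap) {
      D <- cf_pair_dists(en, els, ess, gv, exi)
      nnd <- apply(D, 1, min)
      # raise threshold enough to guarantee progress: at least the closest
      # pair merges, and repeated rebuilds grow the radius geometrically
      threshold <- max(min(nnd), stats::quantile(nnd, 0.25, names = FALSE),
                       2 * threshold, 1e-12)
      remap <- reinsert(threshold)
      row_entry[seq_len(i)] <- remap[row_entry[seq_len(i)]]
    }
  }
  rownames(els) <- rownames(ess) <- NULL
  structure(list(n = en, linear_sum = els, square_sum = ess,
                 row_entry = row_entry, global_variances = gv,
                 threshold = threshold),
            class = "pup_cf_entries")
}

#' Agglomerate CF entries into a merge tree
#'
#' Greedy pairwise merging by minimum log-likelihood distance down to one
#' cluster, recording the partition of the entries at every cluster count
#' `k <= k_max` and the distance of each merge. Ties break toward the first
#' pair in column-major order (deterministic).
#'
#' @param entries a `pup_cf_entries` object from [precluster()].
#' @param k_max largest cluster count for which a partition is recorded.
#' @return object of class `pup_merge_tree`: `partitions` (list indexed by
#'   as.character(k): entry -> cluster index in 1..k), `merge_dists` (named
#'   vector, `merge_dists[as.character(k)]` = distance of the merge producing
#'   k clusters), `n_entries`.
#' @export
agglomerate <- function(entries, k_max = 15L) {
  stopifnot(inherits(entries, "pup_cf_entries"))
  gv <- entries$global_variances
  n <- entries$n
  ls <- entries$linear_sum
  ss <- entries$square_sum
  L <- length(n)
  partitions <- list()
  merge_dists <- numeric(0)
  comp <- seq_len(L)
  canon <- function() match(comp, unique(comp))
  if (L <= k_max) partitions[[as.character(L)]] <- canon()
  if (L == 1L) {
    return(structure(list(partitions = partitions, merge_dists = merge_dists,
                          n_entries = L),
                     class = "pup_merge_tree"))
  }
  xi <- cf_xi(n, ls, ss, gv)
  D <- cf_pair_dists(n, ls, ss, gv, xi)
  active <- rep(TRUE, L)
  m <- L
  while (m > 1L) {
    idx <- which.min(D)  # first minimum in column-major order
    i <- (idx - 1L) %% L + 1L
    j <- (idx - 1L) %/% L + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    d <- D[idx]
    n[i] <- n[i] + n[j]
    ls[i, ] <- ls[i, ] + ls[j, ]
    ss[i, ] <- ss[i, ] + ss[j, ]
    xi[i] <- cf_xi(n[i], ls[i, , drop = FALSE], ss[i, , drop = FALSE], gv)
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    comp[comp == j] <- i
    others <- which(active & seq_len(L) != i)
    if (length(others) > 0L) {
      dnew <- cf_dists_to_cf(n[i], ls[i, ], ss[i, ], xi[i],
                             n[others], ls[others, , drop = FALSE],
                             ss[others, , drop = FALSE], gv, xi[others])
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
    D[i, i] <- Inf
    m <- m - 1L
    merge_dists[as.character(m)] <- d
    if (m <= k_max) partitions[[as.character(m)]] <- canon()
  }
  structure(list(partitions = partitions, merge_dists = merge_dists,
                 n_entries = L),
            class = "pup_merge_tree")
}

cluster_cfs <- function(entries, partition) {
  k <- max(partition)
  p <- ncol(entries$linear_sum)
  n <- numeric(k); ls <- matrix(0, k, p); ss <- matrix(0, k, p)
  for (c in seq_len(k)) {
    sel <- partition == c
    n[c] <- sum(entries$n[sel])
    ls[c, ] <- colSums(entries$linear_sum[sel, , drop = FALSE])
    ss[c, ] <- colSums(entries$square_sum[sel, , drop = FALSE])
  }
  list(n = n, linear_sum = ls, square_sum = ss)
}

#' Choose the number of clusters
#'
#' Two-stage rule on the merge tree: (1) `BIC(k) = -2 * sum_clusters xi +
#' 2 * p * k * log(n)` is computed for every recorded `k`; the initial
#' estimate is the smallest `k` at which the BIC improvement falls below
#' `bic_ratio` times the first improvement. (2) Among `k <= k_init` the ratio
#' of successive merge distances is examined; if the largest ratio dominates
#' the second largest by `dist_ratio` its `k` wins, otherwise the larger of
#' the two candidate `k`s is taken. Finally, a unimodality guard (this
#' package's own design): the two-cluster partition is projected onto the axis
#' joining its centroids and `k = 1` is returned when the projection's
#' bimodality coefficient is `<= 5/9`, i.e. when there is no distributional
#' evidence for more than one cluster.
#'
#' @param tree a `pup_merge_tree` from [agglomerate()].
#' @param entries the `pup_cf_entries` the tree was built from.
#' @param data the original rows (needed for the unimodality guard; may be
#'   NULL to skip it).
#' @param bic_ratio,dist_ratio stage thresholds (SPSS does not publish its
#'   constants; these literature-standard values are configurable).
#' @param unimodal_guard logical; disable to get the raw two-stage result.
#' @return list: `k`, `bic_curve` (data.frame `k`, `bic`), `k_init`,
#'   `dist_ratios`.
#' @export
choose_k <- function(tree, entries, data = NULL, bic_ratio = 0.04,
                     dist_ratio = 1.15, unimodal_guard = TRUE) {
  stopifnot(inherits(tree, "pup_merge_tree"))
  ks <- sort(as.integer(names(tree$partitions)))
  n_total <- sum(entries$n)
  p <- ncol(entries$linear_sum)
  gv <- entries$global_variances
  bic <- vapply(ks, function(k) {
    cfs <- cluster_cfs(entries, tree$partitions[[as.character(k)]])
    -2 * sum(cf_xi(cfs$n, cfs$linear_sum, cfs$square_sum, gv)) +
      2 * p * k * log(n_total)
  }, numeric(1))
  bic_curve <- data.frame(k = ks, bic = bic)
  if (length(ks) == 1L) {
    return(list(k = ks, bic_curve = bic_curve, k_init = ks,
                dist_ratios = numeric(0)))
  }
  dbic <- diff(bic)  # dbic[i] = BIC(ks[i+1]) - BIC(ks[i])
  if (dbic[1L] >= 0) {
    k_init <- ks[1L]
  } else {
    r1 <- dbic / dbic[1L]
    small <- which(r1 < bic_ratio)
    k_init <- if (length(small) > 0L) ks[small[1L]] else ks[length(ks)]
  }
  k_hat <- k_init
  dist_ratios <- numeric(0)
  if (k_init > 2L) {
    md <- tree$merge_dists
    r2_ks <- 2:k_init
    dist_ratios <- vapply(r2_ks, function(k) {
      dk <- md[as.character(k)]
      dk1 <- md[as.character(k - 1L)]
      if (!is.finite(dk) || dk == 0) {
        if (!is.finite(dk1) || dk1 == 0) 1 else Inf
      } else dk1 / dk
    }, numeric(1))
    names(dist_ratios) <- r2_ks
    ord <- order(dist_ratios, decreasing = TRUE)
    top <- ord[1L]
    second <- if (length(ord) > 1L) ord[2L] else NA_integer_
    k_hat <- if (is.na(second) ||
                 dist_ratios[top] > dist_ratio * dist_ratios[second]) {
      r2_ks[top]
    } else {
      max(r2_ks[top], r2_ks[second])
    }
  }
  if (unimodal_guard && k_hat >= 2L && !is.null(data) &&
      "2" %in% names(tree$partitions)) {
    X <- as.matrix(data)
    storage.mode(X) <- "double"
    Xs <- scale(X)
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
    assign2 <- tree$partitions[["2"]][entries$row_entry]
    if (length(unique(assign2)) == 2L && nrow(X) >= 4L) {
      c1 <- colMeans(Xs[assign2 == 1L, , drop = FALSE])
      c2 <- colMeans(Xs[assign2 == 2L, , drop = FALSE])
      proj <- as.numeric(Xs %*% (c2 - c1))
      if (stats::sd(proj) > 0) {
        if (bimodality_coefficient(proj)$b <= 5 / 9) k_hat <- 1L
      } else {
        k_hat <- 1L
      }
    }
  }
  list(k = as.integer(k_hat), bic_curve = bic_curve, k_init = k_init,
       dist_ratios = dist_ratios)
}

#' Average silhouette of cohesion
#'
#' Textbook silhouette `mean((b_i - a_i) / max(a_i, b_i))` on z-standardized
#' variables with Euclidean distance; `a_i` is the mean distance to the
#' point's own cluster, `b_i` the smallest mean distance to another cluster.
#' Values above 0.5 indicate highly separable clusters. Singleton clusters
#' contribute 0.
#'
#' @param data numeric matrix/data.frame of the clustering variables.
#' @param assignments integer cluster labels, one per row; at least two
#'   non-empty clusters.
#' @return scalar in \[-1, 1\].
#' @export
silhouette_cohesion <- function(data, assignments) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  assignments <- as.integer(factor(assignments))
  k <- max(assignments)
  if (k < 2L) stop("silhouette undefined for a single cluster")
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  n <- nrow(Xs)
  sizes <- tabulate(assignments, k)
  rs <- rowSums(Xs^2)
  S <- matrix(0, n, k)  # S[i, c] = sum of distances from i to members of c
  for (c in seq_len(k)) {
    Xc <- Xs[assignments == c, , drop = FALSE]
    d2 <- outer(rs, rowSums(Xc^2), "+") - 2 * Xs %*% t(Xc)
    d2[d2 < 0] <- 0
    S[, c] <- rowSums(sqrt(d2))
  }
  own <- cbind(seq_len(n), assignments)
  a <- S[own] / pmax(sizes[assignments] - 1L, 1L)
  Sother <- S / rep(sizes, each = n)
  Sother[own] <- Inf
  b <- apply(Sother, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[assignments] == 1L] <- 0
  s[!is.finite(s)] <- 0  # duplicate-point degeneracies
  mean(s)
}

#' Fit a two-step cluster model
#'
#' Full pipeline: collinearity screen, CF pre-clustering, agglomerative
#' merging, BIC-based choice of k, assignment of every row to its nearest
#' final cluster by log-likelihood distance, and the average silhouette of
#' cohesion. The standard variable set for pup syllables is the step count
#' plus the start, middle and end contour frequencies; variables are used
#' unstandardized (the log-likelihood distance normalizes through the
#' variance terms).
#'
#' @param features data.frame of per-syllable features (e.g. from
#'   [features_table()]); rows with missing/non-finite values in `variables`
#'   are rejected and reported.
#' @param variables character vector of clustering variable names.
#' @param max_branches,max_depth CF capacity parameters, see [precluster()].
#' @param k_max largest candidate cluster count.
#' @param k fixed cluster count (overrides selection) or NULL.
#' @param bic_ratio,dist_ratio,unimodal_guard passed to [choose_k()].
#' @param use_precluster set FALSE to agglomerate singleton entries (exact
#'   mode for small n).
#' @return object of class `pup_twostep`: `k`, `assignments` (nearest final
#'   cluster per row), `tree_assignments` (the merge-tree partition each row's
#'   CF entry belongs to; equals `assignments` for well-separated clusters),
#'   `sizes`, `centers`, `variances`, `bic_curve`, `silhouette`, `variables`,
#'   `n_entries`, `rejected_rows`, `k_init`.
#' @export
fit_twostep <- function(features,
                        variables = c("n_steps", "start_khz", "middle_khz",
                                      "end_khz"),
                        max_branches = 8L, max_depth = 3L, k_max = 15L,
                        k = NULL, bic_ratio = 0.04, dist_ratio = 1.15,
                        unimodal_guard = TRUE, use_precluster = TRUE) {
  missing_vars <- setdiff(variables, names(features))
  if (length(missing_vars) > 0L)
    stop("features table is missing variable(s): ",
         paste(missing_vars, collapse = ", "))
  X_all <- as.matrix(features[, variables, drop = FALSE])
  storage.mode(X_all) <- "double"
  ok <- rowSums(!is.finite(X_all)) == 0L
  rejected <- which(!ok)
  X <- X_all[ok, , drop = FALSE]
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 complete rows to cluster")
  if (n < 100L)
    warning("two-step clustering is designed for large samples; n = ", n,
            " rows may be unreliable")
  check_collinearity(X)
  entries <- precluster(X, max_branches = max_branches, max_depth = max_depth,
                        disable = !use_precluster)
  tree <- agglomerate(entries, k_max = min(k_max, length(entries$n)))
  sel <- choose_k(tree, entries, data = X, bic_ratio = bic_ratio,
                  dist_ratio = dist_ratio, unimodal_guard = unimodal_guard)
  k_final <- if (is.null(k)) sel$k else as.integer(k)
  if (!as.character(k_final) %in% names(tree$partitions))
    stop("no partition recorded for k = ", k_final)
  part <- tree$partitions[[as.character(k_final)]]
  cfs <- cluster_cfs(entries, part)
  gv <- entries$global_variances
  tree_assignments <- part[entries$row_entry]
  # assign each original row to the nearest final cluster
  if (k_final > 1L) {
    xi_c <- cf_xi(cfs$n, cfs$linear_sum, cfs$square_sum, gv)
    xi_x <- -sum(0.5 * log(gv))
    dmat <- vapply(seq_len(k_final), function(c) {
      nm <- cfs$n[c] + 1
      lsm <- sweep(X, 2, cfs$linear_sum[c, ], "+")
      ssm <- sweep(X^2, 2, cfs$square_sum[c, ], "+")
      v <- ssm / nm - (lsm / nm)^2
      v[v < 0] <- 0
      xim <- -nm * rowSums(0.5 * log(sweep(v, 2, gv, "+")))
      xi_c[c] + xi_x - xim
    }, numeric(nrow(X)))
    assignments <- max.col(-dmat, ties.method = "first")
  } else {
    assignments <- rep(1L, nrow(X))
  }
  present <- sort(unique(assignments))
  if (length(present) < k_final) {
    warning("cluster(s) emptied by nearest-cluster reassignment; relabeling")
    assignments <- match(assignments, present)
    k_final <- length(present)
  }
  sizes <- tabulate(assignments, k_final)
  centers <- t(vapply(seq_len(k_final), function(c)
    colMeans(X[assignments == c, , drop = FALSE]), numeric(ncol(X))))
  variances <- t(vapply(seq_len(k_final), function(c)
    apply(X[assignments == c, , drop = FALSE], 2,
          function(v) sum((v - mean(v))^2) / length(v)), numeric(ncol(X))))
  colnames(centers) <- colnames(variances) <- variables
  sil <- if (k_final >= 2L) silhouette_cohesion(X, assignments) else NA_real_
  full_assign <- rep(NA_integer_, nrow(X_all))
  full_assign[ok] <- assignments
  full_tree_assign <- rep(NA_integer_, nrow(X_all))
  full_tree_assign[ok] <- tree_assignments
  structure(list(k = k_final, assignments = full_assign,
                 tree_assignments = full_tree_assign, sizes = sizes,
                 centers = centers, variances = variances,
                 bic_curve = sel$bic_curve, silhouette = sil,
                 variables = variables, n_entries = length(entries$n),
                 rejected_rows = rejected, k_init = sel$k_init),
            class = "pup_twostep")
}

#' @export
print.pup_twostep <- function(x, ...) {
  cat(sprintf("<pup_twostep> k = %d clusters over %d syllables (%d CF entries)\n",
              x$k, sum(x$sizes), x$n_entries))
  cat(sprintf("  variables: %s\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("  average silhouette of cohesion: %.3f\n", x$silhouette))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}
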