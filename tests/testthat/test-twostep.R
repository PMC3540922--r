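# twostep_cluster: distances, preclustering, agglomeration vs brute force,
# k selection, silhouette, full fits.

test_that("collinearity screen flags duplicated and constant variables", {
  set.seed(10)
  x <- rnorm(100)
  expect_warning(rep1 <- check_collinearity(data.frame(a = x, b = x)),
                 "a~b")
  expect_equal(rep1$pairwise_r["a", "b"], 1)
  expect_equal(nrow(rep1$flagged_pairs), 1L)
  big <- matrix(rnorm(2e4), ncol = 2, dimnames = list(NULL, c("u", "v")))
  rep2 <- check_collinearity(big)
  expect_lt(abs(rep2$pairwise_r["u", "v"]), 0.05)
  expect_equal(nrow(rep2$flagged_pairs), 0L)
  expect_warning(rep3 <- check_collinearity(data.frame(a = x, b = 1)))
  expect_equal(rep3$undefined_vars, "b")
  expect_true(isSymmetric(unname(rep2$pairwise_r)))
})

test_that("log-likelihood distance: identity, symmetry, closed form", {
  gv <- c(1, 2)
  a <- list(n = 1, linear_sum = c(1, 2), square_sum = c(1, 4))
  expect_equal(log_likelihood_distance(a, a, gv), 0, tolerance = 1e-9)
  set.seed(11)
  for (i in 1:10) {
    e1 <- list(n = sample(1:5, 1), linear_sum = rnorm(2), square_sum = runif(2, 5, 9))
    e2 <- list(n = sample(1:5, 1), linear_sum = rnorm(2), square_sum = runif(2, 5, 9))
    expect_identical(log_likelihood_distance(e1, e2, gv),
                     log_likelihood_distance(e2, e1, gv))
    expect_gte(log_likelihood_distance(e1, e2, gv), 0)
  }
  # two singletons Delta apart in one variable with unit global variance
  for (delta in c(0.5, 2, 10)) {
    s1 <- list(n = 1, linear_sum = 0, square_sum = 0)
    s2 <- list(n = 1, linear_sum = delta, square_sum = delta^2)
    expect_equal(log_likelihood_distance(s1, s2, 1), log(1 + delta^2 / 4),
                 tolerance = 1e-12)
  }
  expect_error(log_likelihood_distance(a, list(n = 1, linear_sum = 1,
                                               square_sum = 1), gv),
               "variable set")
})

test_that("preclustering respects capacity, purity, and duplicates", {
  set.seed(12)
  X <- matrix(rnorm(20), ncol = 2)
  ent <- precluster(X, disable = TRUE)
  expect_equal(length(ent$n), 10L)
  expect_true(all(ent$n == 1))
  # duplicates collapse into one entry with the right multiplicity
  Xd <- matrix(rep(c(1, 2), each = 7), ncol = 2)
  entd <- precluster(Xd)
  expect_equal(length(entd$n), 1L)
  expect_equal(entd$n, 7)
  expect_equal(entd$linear_sum[1, ], c(7, 14))
  # 4 well-separated Gaussians: bounded leaf count, no mixed entries
  centers <- matrix(c(0, 0, 40, 0, 0, 40, 40, 40), ncol = 2, byrow = TRUE)
  lab <- sample(1:4, 1000, replace = TRUE)
  Xg <- centers[lab, ] + matrix(rnorm(2000), ncol = 2)
  entg <- precluster(Xg)
  expect_lte(length(entg$n), 8^3)
  expect_equal(sum(entg$n), 1000)
  purity <- tapply(lab, entg$row_entry, function(v) length(unique(v)))
  expect_true(all(purity == 1))
  # conservation of sufficient statistics
  expect_equal(colSums(entg$linear_sum), colSums(Xg))
  expect_equal(colSums(entg$square_sum), colSums(Xg^2))
})

test_that("agglomeration equals the exhaustive brute-force oracle", {
  set.seed(13)
  X <- matrix(rnorm(60), ncol = 2) +
    5 * cbind(rep(0:2, each = 10), rep(c(0, 1, 0), each = 10))
  gv <- apply(X, 2, function(col) mean((col - mean(col))^2))
  ent <- precluster(X, disable = TRUE, global_variances = gv)
  tree <- agglomerate(ent, k_max = 30)
  bf <- oracle_agglomerate(X, gv, k_keep = 1:30)
  for (k in names(bf$parts)) {
    expect_equal(canonical_partition(tree$partitions[[k]][ent$row_entry]),
                 canonical_partition(bf$parts[[k]]))
  }
  ks <- sort(as.integer(names(tree$merge_dists)), decreasing = TRUE)
  expect_equal(unname(tree$merge_dists[as.character(ks)]), bf$dists,
               tolerance = 1e-9)
  # minimum merge distance non-decreasing along the greedy sequence
  expect_true(all(diff(tree$merge_dists[as.character(ks)]) >= -1e-9))
})

test_that("agglomeration trivia: far groups last, identical entries free", {
  far <- matrix(c(0, 0.1, 100, 100.1), ncol = 1)
  ent <- precluster(far, disable = TRUE)
  tree <- agglomerate(ent, k_max = 4)
  expect_equal(sort(tabulate(tree$partitions[["2"]])), c(2, 2))
  same <- matrix(rep(3, 5), ncol = 1)
  ts <- agglomerate(precluster(same, disable = TRUE), k_max = 5)
  expect_true(all(abs(ts$merge_dists) < 1e-9))
})

test_that("choose_k recovers ground truth and collapses unimodal data", {
  set.seed(14)
  centers <- matrix(c(0, 0, 30, 0, 0, 30, 30, 30), ncol = 2, byrow = TRUE)
  lab <- sample(1:4, 4000, replace = TRUE)
  X <- centers[lab, ] + matrix(rnorm(8000), ncol = 2)
  fit <- fit_twostep(as.data.frame(X), variables = c("V1", "V2"))
  expect_equal(fit$k, 4L)
  expect_gt(fit$silhouette, 0.9)
  g1 <- data.frame(a = rnorm(1000, 70, 4), b = rnorm(1000, 70, 4))
  expect_equal(fit_twostep(g1, variables = c("a", "b"))$k, 1L)
})

test_that("silhouette matches the textbook oracle and flags non-structure", {
  set.seed(15)
  X <- matrix(rnorm(120), ncol = 2)
  labs <- rep(1:3, each = 20)
  expect_lt(abs(silhouette_cohesion(X, labs) - oracle_silhouette(X, labs)),
            1e-9)
  if (requireNamespace("cluster", quietly = TRUE)) {
    Xs <- scale(X)
    ora <- mean(cluster::silhouette(labs, dist(Xs))[, 3])
    expect_lt(abs(silhouette_cohesion(X, labs) - ora), 1e-9)
  }
  # two tight separated clusters vs an arbitrary split of one cloud
  tight <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
                 matrix(rnorm(100, 10, 0.1), ncol = 2))
  expect_gt(silhouette_cohesion(tight, rep(1:2, each = 50)), 0.9)
  cloud <- matrix(rnorm(400), ncol = 2)
  expect_lt(abs(silhouette_cohesion(cloud, rep(1:2, 100))), 0.1)
  expect_error(silhouette_cohesion(cloud, rep(1, 200)), "single cluster")
})

test_that("full fit recovers synthetic categories; robust without step variable", {
  rep_df <- generate_repertoire(repertoire_spec(n_syllables = 1500, seed = 21))
  feats <- features_table(rep_df)
  fit <- fit_twostep(feats)
  expect_equal(fit$k, 4L)
  expect_gte(agreement(fit$assignments, rep_df$true_label)$coherence_pct, 95)
  # dropping the step count must move only a small minority of syllables
  fit_nostep <- fit_twostep(feats, variables = c("start_khz", "middle_khz",
                                                 "end_khz"),
                            k = fit$k)
  agr <- agreement(fit$assignments, fit_nostep$assignments)
  expect_gte(agr$coherence_pct, 90)
  expect_equal(sum(fit$sizes), nrow(feats))
})

test_that("small fits equal the brute-force hierarchy and reject bad rows", {
  set.seed(16)
  X <- data.frame(a = c(rnorm(15, 0), rnorm(15, 30)), b = rnorm(30))
  expect_warning(fit <- fit_twostep(X, variables = c("a", "b"),
                                    use_precluster = FALSE, k = 2),
                 "large samples")
  gv <- apply(as.matrix(X), 2, function(col) mean((col - mean(col))^2))
  bf <- oracle_agglomerate(as.matrix(X), gv, k_keep = 2)
  # the merge-tree partition is structurally identical to the oracle; the
  # nearest-cluster reassignment may legitimately move individual boundary
  # points, so it is held to near-agreement
  expect_equal(canonical_partition(fit$tree_assignments),
               canonical_partition(bf$parts[["2"]]))
  expect_gte(agreement(fit$assignments, bf$parts[["2"]])$coherence_pct, 90)
  Xna <- X
  Xna$a[3] <- NA
  expect_warning(fit2 <- fit_twostep(Xna, variables = c("a", "b"), k = 2,
                                     use_precluster = FALSE))
  expect_equal(fit2$rejected_rows, 3L)
  expect_true(is.na(fit2$assignments[3]))
})

test_that("row order only permutes labels, not the partition", {
  rep_df <- generate_repertoire(repertoire_spec(n_syllables = 300, seed = 22))
  feats <- features_table(rep_df)
  set.seed(23)
  perm <- sample(nrow(feats))
  f1 <- fit_twostep(feats, use_precluster = FALSE, k = 4)
  f2 <- fit_twostep(feats[perm, ], use_precluster = FALSE, k = 4)
  expect_equal(agreement(f1$assignments[perm], f2$assignments)$coherence_pct,
               100)
})

test_that("choose_k is stable across seeded replicates", {
  ks <- vapply(1:20, function(s) {
    rep_df <- generate_repertoire(repertoire_spec(n_syllables = 500,
                                                  seed = 100 + s))
    fit_twostep(features_table(rep_df), k_max = 10)$k
  }, integer(1))
  expect_gte(sum(ks == 4L), 18L)
})
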