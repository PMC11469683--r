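# Exhaustive oracle: best 2-cluster L1 partition of a 1-D set by brute force
brute_force_l1_k2 <- function(x) {
  n <- length(x)
  best <- list(inertia = Inf)
  for (mask in 1:(2^n - 2)) {
    in1 <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    c1 <- median(x[in1])
    c2 <- median(x[!in1])
    inertia <- sum(abs(x[in1] - c1)) + sum(abs(x[!in1] - c2))
    if (inertia < best$inertia) {
      best <- list(inertia = inertia, centroids = sort(c(c1, c2)))
    }
  }
  best
}

test_that("city-block k-means matches the brute-force L1 optimum in 1-D", {
  x <- c(0, 0, 1, 10, 10, 11)
  oracle <- brute_force_l1_k2(x)
  expect_equal(oracle$centroids, c(0, 10))
  expect_equal(oracle$inertia, 2)
  fit <- fit_states(matrix(x, ncol = 1), k = 2, replicates = 5, seed = 1)
  expect_equal(sort(drop(fit$centroids)), oracle$centroids)
  expect_equal(fit$inertia, oracle$inertia)
})

test_that("identical frames give zero inertia with an empty-cluster reseed", {
  X <- matrix(1, 10, 3)
  expect_message(fit <- fit_states(X, 2, replicates = 1, seed = 1),
                 "reseeded empty cluster")
  expect_equal(fit$inertia, 0)
})

test_that("the reported inertia is the minimum over replicates and never increases with more", {
  set.seed(5)
  X <- rbind(matrix(rnorm(200, 0), 50, 4), matrix(rnorm(200, 3), 50, 4),
             matrix(rnorm(200, -3), 50, 4))
  f1 <- fit_states(X, 3, replicates = 1, seed = 9)
  f5 <- fit_states(X, 3, replicates = 5, seed = 9)
  expect_equal(f5$inertia, min(f5$inertia_by_replicate))
  expect_lte(f5$inertia, f1$inertia)  # replicate seeds nest (seed + r)
  expect_equal(f1$inertia, f5$inertia_by_replicate[1])
})

test_that("a converged solution is a fixed point of one Lloyd iteration", {
  set.seed(6)
  X <- rbind(matrix(rnorm(300, 0, 0.2), 75, 4),
             matrix(rnorm(300, 2, 0.2), 75, 4))
  fit <- fit_states(X, 2, replicates = 3, seed = 2, rel_tol = 0)
  Xt <- t(X)
  near <- .l1_nearest(Xt, t(fit$centroids))
  expect_identical(near$assignment, fit$assignments)
  C2 <- .group_col_medians(Xt, near$assignment, 2L)
  expect_equal(t(C2), fit$centroids, tolerance = 1e-12)
})

test_that("the elbow rule maximises perpendicular distance to the endpoint chord", {
  inertia <- c("2" = 100, "3" = 40, "4" = 10, "5" = 9, "6" = 8, "7" = 7)
  # independent oracle: perpendicular point-line distances computed directly
  ks <- 2:7
  chord <- c(7 - 2, inertia[6] - inertia[1])
  d <- abs((ks - 2) * chord[2] - (inertia - inertia[1]) * chord[1]) /
    sqrt(sum(chord^2))
  expect_equal(unname(which.max(d[2:5])) + 2L, 4L)
  expect_equal(select_k_elbow(inertia), 4L)
})

test_that("a linear inertia decline yields the smallest interior k with a warning", {
  inertia <- setNames(seq(100, 50, by = -10), 2:7)
  expect_warning(k <- select_k_elbow(inertia), "no elbow")
  expect_equal(k, 3L)
})

test_that("non-monotone inertia curves are smoothed isotonically with a warning", {
  inertia <- c("2" = 100, "3" = 40, "4" = 10, "5" = 12, "6" = 8, "7" = 7)
  expect_warning(k <- select_k_elbow(inertia), "not non-increasing")
  expect_equal(k, 4L)
})

test_that("state descriptors match closed-form values on canonical graphs", {
  # complete graph with unit weights: everything one hop away
  n <- 5
  cent <- rep(1, n * (n - 1) / 2)
  d <- describe_state(cent, network_labels = rep(c("A", "B"), length.out = n))
  expect_equal(d$global_mean_connectivity, 1)
  expect_equal(d$global_efficiency, 1)

  # two disconnected 3-cliques: modularity 1/2 (exhaustive-partition oracle)
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1
  W[4:6, 4:6] <- 1
  diag(W) <- 0
  idx <- edge_index(6)
  cl <- describe_state(W[cbind(idx[, 1], idx[, 2])],
                       network_labels = rep("X", 6))
  # oracle: brute force over all 2^6 bipartitions (optimum is symmetric)
  m <- sum(W) / 2
  deg <- rowSums(W)
  bestQ <- -Inf
  for (mask in 0:63) {
    grp <- as.logical(bitwAnd(mask, 2^(0:5)))
    Q <- 0
    for (i in 1:6) for (j in 1:6) {
      if (grp[i] == grp[j]) Q <- Q + W[i, j] - deg[i] * deg[j] / (2 * m)
    }
    bestQ <- max(bestQ, Q / (2 * m))
  }
  expect_equal(bestQ, 0.5)
  expect_equal(cl$modularity, 0.5)

  # ring of 4 unit edges: symmetry forces equal centrality everywhere
  Wr <- matrix(0, 4, 4)
  Wr[cbind(1:4, c(2, 3, 4, 1))] <- 1
  Wr <- Wr + t(Wr)
  idx4 <- edge_index(4)
  dr <- describe_state(Wr[cbind(idx4[, 1], idx4[, 2])],
                       network_labels = c("P", "Q", "P", "Q"))
  expect_equal(unname(dr$centrality_by_network["P"]),
               unname(dr$centrality_by_network["Q"]), tolerance = 1e-10)

  expect_error(describe_state(rep(0, 10), network_labels = rep("A", 5)),
               "degenerate")
})

test_that("state naming follows the maximal-centrality network", {
  # a hub network: regions 1-2 ("HUB") strongly connected to everything
  n <- 6
  W <- matrix(0.1, n, n)
  W[1:2, ] <- 1
  W[, 1:2] <- 1
  diag(W) <- 0
  idx <- edge_index(n)
  d <- describe_state(W[cbind(idx[, 1], idx[, 2])],
                      network_labels = c("HUB", "HUB", "PER", "PER",
                                         "PER", "PER"))
  expect_identical(d$name, "HUB")
})

test_that("centroid matching recovers permutations and tolerates noise", {
  set.seed(8)
  ref <- matrix(rnorm(4 * 50), 4, 50)
  perm <- c(2, 1, 4, 3)
  cand <- ref[perm, ]
  # cand[i, ] = ref[perm[i], ]; matching must map reference i -> cand row
  p <- match_states(cand, ref)
  expect_equal(ref, cand[p, ])

  noisy <- cand + matrix(rnorm(200, sd = sd(ref) / 10), 4, 50)
  expect_equal(match_states(noisy, ref), p)

  expect_equal(match_states(ref[1, , drop = FALSE],
                            ref[1, , drop = FALSE]), 1L)
})

test_that("planted states are recovered from a small synthetic cohort", {
  cohort <- get_small_cohort()
  pooled <- do.call(rbind, lapply(cohort$timeseries, function(ts) {
    edge_time_series(zscore_regional(ts))
  }))
  fit <- fit_states(pooled, 4, replicates = 5, seed = 3)
  truth <- unlist(cohort$ground_truth$true_sequences, use.names = FALSE)
  tab <- table(truth, fit$assignments)
  agreement <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(agreement, 0.95)

  # matched centroids correlate strongly with the planted edge patterns
  tpl <- vapply(cohort$ground_truth$templates, `[[`, numeric(30),
                "activation_pattern")
  idx <- edge_index(30)
  ref <- t(apply(tpl, 2, function(q) (q %o% q)[cbind(idx[, 1], idx[, 2])]))
  p <- match_states(fit$centroids, ref)
  for (s in 1:4) {
    expect_gte(cor(fit$centroids[p[s], ], ref[s, ]), 0.8)
  }
})

test_that("pooled assignments split back into per-subject sequences", {
  a <- c(1L, 1L, 2L, 3L, 3L, 3L)
  out <- split_assignments(a, c(s1 = 2L, s2 = 4L))
  expect_identical(out$s1, c(1L, 1L))
  expect_identical(out$s2, c(2L, 3L, 3L, 3L))
  expect_error(split_assignments(a, c(s1 = 2L)), "frame counts")
})
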