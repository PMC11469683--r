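#' City-block k-means over pooled edge-time-series frames
#'
#' Lloyd iterations under the L1 (city-block) metric: frames are assigned to
#' the nearest centroid by L1 distance and each centroid is updated to the
#' componentwise *median* of its members (the L1-optimal centroid, i.e. the
#' "cluster median"). `replicates` seeded k-means++-style initialisations
#' (distance-proportional sampling under L1) are run and the one
#' with minimal total within-cluster L1 distance (inertia) is returned, so
#' adding replicates can never increase the reported inertia. An iteration
#' that empties a cluster reseeds that centroid from the frame farthest from
#' its assigned centroid (logged via `message()`).
#'
#' When `stride > 1` the centroids are fitted on every `stride`-th pooled
#' frame (a uniform temporal subsample) and all frames are then assigned to
#' the fixed centroids; this bounds memory/time at large cohort scale and is
#' off (`stride = 1`) by default.
#'
#' @param pooled_edges Frames x edges matrix (frames pooled across subjects).
#' @param k Number of states (>= 2).
#' @param replicates Number of seeded restarts (default 5).
#' @param seed Integer seed; replicate `r` uses `seed + r` so replicate sets
#'   nest.
#' @param max_iter Lloyd iteration cap per replicate.
#' @param rel_tol Convergence also declared when the relative inertia
#'   improvement of an iteration falls below this (stops the long tail in
#'   which single frames shuffle between equivalent clusters); set to 0 to
#'   require exact assignment stability.
#' @param stride Subsampling stride for fitting (1 = use all frames).
#' @return Object of class `state_set`: list with `k`, `centroids`
#'   (k x edges), `assignments` (per pooled frame), `inertia`,
#'   `inertia_by_replicate` and `iterations`.
#' @export
fit_states <- function(pooled_edges, k, replicates = 5L, seed = 1L,
                       max_iter = 100L, rel_tol = 1e-6, stride = 1L) {
  X <- as.matrix(pooled_edges)
  n <- nrow(X)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of pooled frames")
  fit_idx <- seq(1L, n, by = stride)
  Xt <- t(X[fit_idx, , drop = FALSE])  # edges x frames, frames contiguous

  best <- NULL
  inertia_by_rep <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    C <- kmeanspp_init(Xt, k)
    assign_prev <- integer(0)
    inertia_prev <- Inf
    iter <- 0L
    repeat {
      iter <- iter + 1L
      near <- .l1_nearest(Xt, C)
      a <- near$assignment
      # empty-cluster rule: reseed from the farthest point
      empty <- setdiff(seq_len(k), unique(a))
      for (e in empty) {
        far <- which.max(near$distance)
        C[, e] <- Xt[, far]
        near$distance[far] <- 0
        a[far] <- e
        message("reseeded empty cluster ", e, " from farthest frame")
      }
      inertia <- sum(near$distance)
      if (identical(a, assign_prev) || iter >= max_iter ||
          (inertia_prev - inertia) < rel_tol * inertia) {
        break
      }
      assign_prev <- a
      inertia_prev <- inertia
      Cnew <- .group_col_medians(Xt, a, k)
      nan_col <- which(colSums(is.na(Cnew)) > 0)
      if (length(nan_col)) Cnew[, nan_col] <- C[, nan_col]
      C <- Cnew
    }
    inertia_by_rep[r] <- inertia
    if (is.null(best) || inertia < best$inertia) {
      best <- list(C = C, inertia = inertia, iterations = iter)
    }
  }

  full_assign <- .l1_nearest(t(X), best$C)
  structure(list(
    k = k,
    centroids = t(best$C),
    assignments = full_assign$assignment,
    inertia = if (stride == 1L) best$inertia else sum(full_assign$distance),
    inertia_by_replicate = inertia_by_rep,
    iterations = best$iterations
  ), class = "state_set")
}

# k-means++-style seeding under the L1 metric: first centroid uniform, each
# subsequent centroid sampled with probability proportional to the distance
# to the nearest centroid chosen so far.
kmeanspp_init <- function(Xt, k) {
  n <- ncol(Xt)
  C <- matrix(0, nrow(Xt), k)
  C[, 1L] <- Xt[, sample.int(n, 1L)]
  d <- .l1_nearest(Xt, C[, 1L, drop = FALSE])$distance
  for (c in seq_len(k - 1L) + 1L) {
    pick <- if (all(d == 0)) sample.int(n, 1L) else sample.int(n, 1L, prob = d)
    C[, c] <- Xt[, pick]
    d_new <- .l1_nearest(Xt, C[, c, drop = FALSE])$distance
    d <- pmin(d, d_new)
  }
  C
}

#' @export
print.state_set <- function(x, ...) {
  cat("state_set: k =", x$k, "states over", ncol(x$centroids),
      "edges;", length(x$assignments), "frames; L1 inertia =",
      format(x$inertia, digits = 6), "\n")
  invisible(x)
}

#' Fit states over a range of k and record the inertia curve
#'
#' @param pooled_edges Frames x edges matrix.
#' @param k_range Candidate numbers of states (default 2:7).
#' @inheritParams fit_states
#' @return List with `fits` (named list of `state_set` by k) and
#'   `inertia_by_k` (named numeric vector).
#' @export
fit_states_range <- function(pooled_edges, k_range = 2:7, replicates = 5L,
                             seed = 1L, max_iter = 100L, stride = 1L) {
  fits <- lapply(k_range, function(k) {
    fit_states(pooled_edges, k, replicates = replicates, seed = seed,
               max_iter = max_iter, stride = stride)
  })
  names(fits) <- as.character(k_range)
  list(fits = fits,
       inertia_by_k = setNames(vapply(fits, `[[`, numeric(1), "inertia"),
                               names(fits)))
}

#' Select the number of states by the elbow criterion
#'
#' Returns the candidate k whose point `(k, inertia)` lies at maximal
#' perpendicular distance from the straight line joining the first and last
#' points of the inertia curve (the "kneedle" rule), with ties broken toward
#' smaller k. A non-monotone curve is smoothed by decreasing isotonic
#' regression first (with a warning); if no interior point separates from the
#' chord (a near-linear decline) the smallest interior k is returned with a
#' "no elbow" warning.
#'
#' @param inertia_by_k Named numeric vector, names = candidate k (>= 3 values).
#' @return Selected k (integer).
#' @export
select_k_elbow <- function(inertia_by_k) {
  if (length(inertia_by_k) < 3L) stop("need at least 3 candidate k values")
  ks <- as.numeric(names(inertia_by_k))
  if (anyNA(ks)) stop("inertia_by_k must be named by candidate k")
  o <- order(ks)
  ks <- ks[o]
  inertia <- as.numeric(inertia_by_k)[o]
  if (any(diff(inertia) > 0)) {
    warning("inertia curve is not non-increasing; smoothing isotonically")
    inertia <- -isoreg(ks, -inertia)$yf
  }
  p1 <- c(ks[1L], inertia[1L])
  p2 <- c(ks[length(ks)], inertia[length(ks)])
  chord <- p2 - p1
  chord_len <- sqrt(sum(chord^2))
  d <- vapply(seq_along(ks), function(i) {
    v <- c(ks[i], inertia[i]) - p1
    abs(v[1L] * chord[2L] - v[2L] * chord[1L]) / chord_len
  }, numeric(1))
  d[c(1L, length(d))] <- -Inf  # endpoints are never an elbow
  tol <- 1e-8 * max(abs(inertia[1L] - inertia[length(inertia)]), 1)
  if (max(d) <= tol) {
    warning("no elbow: inertia declines linearly; returning smallest interior k")
    return(as.integer(ks[2L]))
  }
  as.integer(ks[which.max(d)])  # which.max takes the first (smallest k) on ties
}

#' Graph-theoretical descriptors of a state centroid
#'
#' Reconstructs the regions x regions co-fluctuation matrix of a centroid and
#' computes: global mean connectivity (mean of the *signed* edge values);
#' global efficiency, modularity and eigenvector centrality on the
#' elementwise-absolute-value matrix (path lengths and centralities are not
#' defined for signed weights; edge length is `1/|w|`). Global efficiency is
#' the mean over ordered region pairs of inverse shortest-path length;
#' modularity is the best of `louvain_restarts` seeded Louvain runs;
#' eigenvector centrality is the principal eigenvector of `|W|`, normalised
#' to unit Euclidean norm and averaged within each resting-state network.
#' The state is named after the network with maximal mean centrality.
#'
#' @param centroid Numeric edge vector (length `n*(n-1)/2`).
#' @param index Edge index from [edge_index()]; inferred when omitted.
#' @param network_labels Character vector, network of each region.
#' @param louvain_restarts Number of seeded Louvain restarts (default 10).
#' @return List with `global_mean_connectivity`, `global_efficiency`,
#'   `modularity`, `centrality_by_network` (named vector) and `name`.
#' @export
describe_state <- function(centroid, index = NULL, network_labels,
                           louvain_restarts = 10L) {
  W <- frame_matrix(centroid, index)
  n <- nrow(W)
  if (length(network_labels) != n) {
    stop("network_labels must have one entry per region")
  }
  if (all(W == 0)) stop("degenerate all-zero state centroid")
  gmc <- mean(centroid)
  Wa <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(Wa, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / D
  diag(inv) <- NA
  geff <- mean(inv, na.rm = TRUE)  # disconnected pairs contribute 1/Inf = 0
  q <- -Inf
  for (r in seq_len(louvain_restarts)) {
    set.seed(r)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    qr_ <- igraph::modularity(cl)
    if (qr_ > q) q <- qr_  # strict improvement => ties keep the lowest seed
  }
  ev <- eigen(Wa, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  if (sum(v) < 0) v <- -v  # Perron vector, fixed sign; already unit norm
  cent <- tapply(v, network_labels, mean)
  cent <- cent[unique(network_labels)]
  list(global_mean_connectivity = gmc,
       global_efficiency = geff,
       modularity = q,
       centrality_by_network = cent,
       name = names(cent)[which.max(cent)])
}

#' Match two sets of state centroids
#'
#' Finds the permutation `p` maximising the summed Pearson correlation
#' between `centroids[p[i], ]` and `reference_centroids[i, ]` by exhaustive
#' search over permutations (k is small; k! is cheap for k <= 8).
#'
#' @param centroids k x edges matrix.
#' @param reference_centroids k x edges matrix.
#' @return Integer permutation `p` with `centroids[p[i], ]` matched to
#'   reference state `i`.
#' @export
match_states <- function(centroids, reference_centroids) {
  C <- as.matrix(centroids)
  R <- as.matrix(reference_centroids)
  if (!all(dim(C) == dim(R))) stop("centroid sets must have equal dimensions")
  k <- nrow(C)
  if (k == 1L) return(1L)
  if (k > 8L) stop("exhaustive matching supports k <= 8")
  S <- suppressWarnings(cor(t(R), t(C)))  # S[i, j] = cor(ref i, centroid j)
  S[is.na(S)] <- 0
  perms <- all_permutations(k)
  scores <- apply(perms, 1L, function(p) sum(S[cbind(seq_len(k), p)]))
  as.integer(perms[which.max(scores), ])
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      out[row, ] <- append(sub[i, ], k, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Relabel pooled frame assignments per subject
#'
#' Splits a pooled assignment vector back into per-subject state sequences
#' using the frame counts of each subject, in pooling order.
#'
#' @param assignments Pooled assignment vector from [fit_states()].
#' @param n_frames_by_subject Named integer vector of frames per subject, in
#'   the order the subjects were pooled.
#' @return Named list of per-subject integer state sequences.
#' @export
split_assignments <- function(assignments, n_frames_by_subject) {
  if (sum(n_frames_by_subject) != length(assignments)) {
    stop("frame counts do not sum to the pooled assignment length")
  }
  f <- rep(names(n_frames_by_subject), n_frames_by_subject)
  split(assignments, factor(f, levels = names(n_frames_by_subject)))
}
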