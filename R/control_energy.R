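#' Stabilised adjacency for continuous-time linear dynamics
#'
#' `A = W / (lambda_max(W) + c) - I`, the standard normalisation that places
#' all eigenvalues of `A` in `[-2, 0)` for any symmetric nonnegative `W`, so
#' the linear system `x' = A x + B u` is stable.
#'
#' @param W Symmetric nonnegative connectome matrix (zero diagonal).
#' @param c Positive stabilisation constant (default 1).
#' @return The `A` matrix.
#' @export
normalize_adjacency <- function(W, c = 1) {
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-10) stop("connectome must be symmetric")
  if (any(W < 0)) stop("connectome weights must be nonnegative")
  if (all(W == 0)) stop("degenerate all-zero connectome")
  if (c <= 0) stop("c must be positive")
  lam <- max(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  W / (lam + c) - diag(nrow(W))
}

#' Controllability Gramian by the augmented matrix exponential
#'
#' Computes `W_T = integral_0^T exp(A t) B B' exp(A' t) dt` with `B = I`
#' exactly (to matrix-exponential precision) via the block-triangular
#' augmented matrix `[[-A, I], [0, A']]`: if its exponential at `T` has
#' blocks `F12`, `F22`, then `W_T = F22' F12`. No quadrature step size is
#' involved.
#'
#' @param A Stable system matrix.
#' @param horizon Control horizon `T` (> 0).
#' @return Symmetric positive-definite Gramian matrix.
#' @export
control_gramian <- function(A, horizon = 1) {
  if (horizon <= 0) stop("horizon must be positive")
  n <- nrow(A)
  M <- rbind(cbind(-A, diag(n)),
             cbind(matrix(0, n, n), t(A)))
  Fm <- as.matrix(Matrix::expm(M * horizon))
  W <- t(Fm[n + seq_len(n), n + seq_len(n)]) %*% Fm[seq_len(n), n + seq_len(n)]
  (W + t(W)) / 2
}

#' Build a control system from a structural connectome
#'
#' Bundles the stabilised adjacency `A`, the state propagator `exp(A T)`,
#' the controllability Gramian `W_T` and its (possibly regularised) inverse
#' factorisation, computed once per subject and reused for every framewise
#' transition. The input matrix `B` is the identity: every region is a
#' control node. A Gramian whose condition number exceeds `cond_threshold`
#' is inverted by a relative-tolerance eigenvalue pseudo-inverse with a
#' logged warning.
#'
#' The default horizon `T = 3` sits where a global loss of structural
#' coupling is clearly expressed in the energy (the natural-decay difference
#' between weak and intact connectomes compounds with `T`); see
#' [horizon_energy_stability()] to examine the dependence on `T`.
#'
#' @param W Structural connectome (symmetric, nonnegative, zero diagonal).
#' @param c Stabilisation constant (default 1).
#' @param horizon Control horizon `T` (default 3).
#' @param cond_threshold Condition-number threshold for regularised solves.
#' @return Object of class `control_system`.
#' @export
control_system <- function(W, c = 1, horizon = 3, cond_threshold = 1e12) {
  A <- normalize_adjacency(W, c)
  n <- nrow(A)
  eigA <- eigen(A, symmetric = TRUE)
  E <- eigA$vectors %*% (exp(eigA$values * horizon) * t(eigA$vectors))
  G <- control_gramian(A, horizon)
  eigG <- eigen(G, symmetric = TRUE)
  cond <- eigG$values[1L] / eigG$values[n]
  if (!is.finite(cond) || cond > cond_threshold) {
    warning(sprintf(
      "ill-conditioned Gramian (condition number %.3g); using pseudo-inverse",
      cond))
    keep <- eigG$values > eigG$values[1L] * 1e-12
    inv_vals <- ifelse(keep, 1 / eigG$values, 0)
  } else {
    inv_vals <- 1 / eigG$values
  }
  Ginv <- eigG$vectors %*% (inv_vals * t(eigG$vectors))
  structure(list(A = A, horizon = horizon, E = E, gramian = G,
                 gramian_inverse = Ginv, condition_number = cond,
                 eig = eigA, region_labels = rownames(W)),
            class = "control_system")
}

#' @export
print.control_system <- function(x, ...) {
  cat("control_system:", nrow(x$A), "regions; horizon =", x$horizon,
      "; Gramian condition number =", format(x$condition_number, digits = 4),
      "\n")
  invisible(x)
}

#' Minimum control energy of one activity transition
#'
#' For `x' = A x + u` over horizon `T`, the minimum-energy input steering
#' `x0` to `xf` is `u*(t) = exp(A'(T - t)) W_T^{-1} v` with
#' `v = xf - exp(A T) x0`; total energy is the quadratic form
#' `v' W_T^{-1} v` and the per-region energy is
#' `integral_0^T u_i*(t)^2 dt`, computed in closed form through the spectral
#' decomposition of the (symmetric) `A`. Per-region energies sum exactly to
#' the total.
#'
#' @param sys A [control_system()].
#' @param x0,xf Initial and target activity states (length-n vectors).
#' @return List with `total` (scalar) and `regional` (length-n vector).
#' @export
min_control_energy <- function(sys, x0, xf) {
  n <- nrow(sys$A)
  if (length(x0) != n || length(xf) != n) stop("state dimension mismatch")
  if (!all(is.finite(x0)) || !all(is.finite(xf))) stop("states must be finite")
  v <- xf - drop(sys$E %*% x0)
  p <- drop(sys$gramian_inverse %*% v)
  total <- sum(v * p)
  # regional_i = int_0^T (exp(A's) p)_i^2 ds, spectral closed form
  Q <- sys$eig$vectors
  lam <- sys$eig$values
  cvec <- drop(crossprod(Q, p))
  S <- outer(lam, lam, "+")
  G <- (exp(S * sys$horizon) - 1) / S  # lam < 0 => S < 0, never 0/0
  M <- G * outer(cvec, cvec)
  regional <- rowSums((Q %*% M) * Q)
  list(total = total, regional = regional)
}

#' Minimum control energy of every framewise transition
#'
#' Treats the z-scored regional activity of frame `t` as the system state and
#' computes the minimum control energy of the transition from frame `t` to
#' frame `t + 1` for every consecutive pair, reusing the propagator and
#' Gramian factorisation of `sys`.
#'
#' @param z Frames x regions matrix of z-scored activity; column names, when
#'   present, must match the system's region labels in order.
#' @param sys A [control_system()].
#' @return Numeric vector of length `frames - 1` (all `>= 0`).
#' @export
framewise_energy <- function(z, sys) {
  z <- as.matrix(z)
  n <- nrow(sys$A)
  if (ncol(z) != n) stop("region count mismatch between activity and system")
  if (!is.null(colnames(z)) && !is.null(sys$region_labels) &&
      !identical(colnames(z), sys$region_labels)) {
    stop("region order of the activity matrix does not match the connectome")
  }
  if (nrow(z) < 2L) stop("need at least 2 frames")
  X0 <- t(z[-nrow(z), , drop = FALSE])
  XF <- t(z[-1L, , drop = FALSE])
  V <- XF - sys$E %*% X0
  P <- sys$gramian_inverse %*% V
  colSums(V * P)
}

#' Aggregate framewise energies into a state-transition energy matrix
#'
#' Cell `(i, j)` is the mean minimum control energy over all frame pairs
#' whose state sequence goes `i -> j`. Transition types never observed in
#' the sequence are missing (`NA`).
#'
#' @param energies Energies of consecutive frame pairs
#'   (length `length(seq) - 1`).
#' @param seq Frame-wise state labels.
#' @param k Number of states.
#' @return `k` x `k` matrix with `NA` for unobserved transitions.
#' @export
energy_transition_matrix <- function(energies, seq, k) {
  if (length(energies) != length(seq) - 1L) {
    stop("need exactly one energy per consecutive frame pair")
  }
  from <- seq[-length(seq)]
  to <- seq[-1L]
  out <- matrix(NA_real_, k, k)
  sums <- matrix(0, k, k)
  cnt <- matrix(0L, k, k)
  for (t in seq_along(energies)) {
    sums[from[t], to[t]] <- sums[from[t], to[t]] + energies[t]
    cnt[from[t], to[t]] <- cnt[from[t], to[t]] + 1L
  }
  out[cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
  out
}

#' Z-score energy matrices against the healthy-control distribution
#'
#' Each cell `(i, j)` of each subject's energy matrix is transformed to
#' `(value - mean_HC) / sd_HC` using the healthy-control values of that cell
#' (sample SD). Missing cells stay missing; a cell with fewer than 2
#' non-missing HC values or zero HC SD is unusable and set to `NA` for all
#' subjects, with a warning.
#'
#' @param matrices Named list of k x k energy matrices (one per subject).
#' @param hc_ids Subject ids forming the reference (control) group.
#' @return Named list of z-scored matrices, same shape.
#' @export
zscore_vs_controls <- function(matrices, hc_ids) {
  if (!all(hc_ids %in% names(matrices))) stop("unknown control ids")
  k <- nrow(matrices[[1L]])
  arr <- array(unlist(matrices), dim = c(k, k, length(matrices)),
               dimnames = list(NULL, NULL, names(matrices)))
  hc <- arr[, , hc_ids, drop = FALSE]
  mu <- apply(hc, c(1, 2), mean, na.rm = TRUE)
  sdv <- apply(hc, c(1, 2), sd, na.rm = TRUE)
  n_hc <- apply(!is.na(hc), c(1, 2), sum)
  bad <- n_hc < 2L | sdv == 0 | !is.finite(sdv)
  if (any(bad)) {
    warning(sum(bad), " cell(s) unusable: <2 control values or zero control SD")
    mu[bad] <- NA_real_
    sdv[bad] <- NA_real_
  }
  lapply(matrices, function(m) (m - mu) / sdv)
}

#' Mean framewise energy across a grid of control horizons
#'
#' Recomputes the mean framewise minimum control energy of the same activity
#' under several control horizons, to examine how strongly results depend on
#' the horizon choice.
#'
#' @param z Frames x regions activity matrix.
#' @param W Structural connectome.
#' @param horizons Grid of horizons (default 0.5, 1, 3, 5).
#' @param c Stabilisation constant.
#' @return Data.frame with `horizon` and `mean_energy`.
#' @export
horizon_energy_stability <- function(z, W, horizons = c(0.5, 1, 3, 5),
                                     c = 1) {
  data.frame(
    horizon = horizons,
    mean_energy = vapply(horizons, function(Th) {
      mean(framewise_energy(z, control_system(W, c = c, horizon = Th)))
    }, numeric(1))
  )
}

#' Total, persistence and transition control energy
#'
#' Means over the non-missing cells of the full matrix (total CE), its
#' diagonal (persistence CE: staying in a state), and its off-diagonal
#' (transition CE: changing state). A summary whose cells are all missing is
#' `NA`; an all-missing matrix is an error.
#'
#' @param m k x k energy matrix (possibly z-scored), `NA` for unobserved.
#' @return Named numeric vector `c(total, persistence, transition)`.
#' @export
summarize_energy <- function(m) {
  if (all(is.na(m))) stop("all-missing energy matrix")
  d <- diag(m)
  off <- m[row(m) != col(m)]
  c(total = mean(m, na.rm = TRUE),
    persistence = if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE),
    transition = if (all(is.na(off))) NA_real_ else mean(off, na.rm = TRUE))
}
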