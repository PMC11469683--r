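#' Z-score regional time series
#'
#' Transforms each region's signal to z-scores using its temporal mean and
#' *population* SD (denominator `n`, not `n - 1`). The population convention is
#' what makes the edge-time-series identity exact: the temporal mean of the
#' co-fluctuation product of two z-scored regions equals their Pearson
#' correlation.
#'
#' @param ts Numeric matrix, frames x regions. Column names (region labels)
#'   are preserved.
#' @return Matrix of the same shape with each column standardised.
#' @export
zscore_regional <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stop("need at least 2 frames to z-score")
  if (anyNA(ts)) stop("time series contains missing values")
  mu <- colMeans(ts)
  cent <- sweep(ts, 2L, mu, "-")
  sd_pop <- sqrt(colMeans(cent^2))
  bad <- which(sd_pop == 0)
  if (length(bad)) {
    lab <- if (!is.null(colnames(ts))) colnames(ts)[bad] else as.character(bad)
    stop("zero temporal variance in region(s): ", paste(lab, collapse = ", "))
  }
  sweep(cent, 2L, sd_pop, "/")
}

#' Edge (region-pair) index for `n` regions
#'
#' Upper-triangle pairs `(i, j)` with `i < j`, ordered row-major:
#' (1,2), (1,3), ..., (1,n), (2,3), ...
#'
#' @param n Number of regions.
#' @return Integer matrix with columns `i` and `j`, one row per edge.
#' @export
edge_index <- function(n) {
  if (n < 2L) stop("need at least 2 regions")
  idx <- t(combn(n, 2L))
  colnames(idx) <- c("i", "j")
  idx
}

#' Edge time series from z-scored regional signals
#'
#' The edge time series of a region pair is the framewise product of the two
#' z-scored regional signals: `e_ij(t) = z_i(t) * z_j(t)`. Each frame then
#' carries a full (regions x regions) co-fluctuation network; only the upper
#' triangle is stored (see [frame_matrix()] to reconstruct a frame). The
#' temporal mean of each edge column equals the Pearson correlation of the
#' pair, an identity the construction inherits from the population-SD
#' z-scoring.
#'
#' @param z Frames x regions matrix of z-scored signals (see
#'   [zscore_regional()]). Inputs failing the z-score contract (column mean 0,
#'   population SD 1 within `tol`) are rejected.
#' @param tol Tolerance for the z-score contract check.
#' @return Frames x edges matrix; column names are `regionA|regionB`, and the
#'   pair index is attached as attribute `"edge_index"`.
#' @export
edge_time_series <- function(z, tol = 1e-6) {
  z <- as.matrix(z)
  mu <- colMeans(z)
  sd_pop <- sqrt(colMeans(sweep(z, 2L, mu, "-")^2))
  if (any(abs(mu) > tol) || any(abs(sd_pop - 1) > tol)) {
    stop("input is not z-scored (population SD); call zscore_regional() first")
  }
  n <- ncol(z)
  idx <- edge_index(n)
  e <- z[, idx[, 1L], drop = FALSE] * z[, idx[, 2L], drop = FALSE]
  labs <- colnames(z)
  if (is.null(labs)) labs <- paste0("R", seq_len(n))
  colnames(e) <- paste(labs[idx[, 1L]], labs[idx[, 2L]], sep = "|")
  attr(e, "edge_index") <- idx
  e
}

#' Reconstruct one frame's co-fluctuation matrix
#'
#' Builds the symmetric regions x regions matrix for a single frame from an
#' edge vector. The diagonal (squared z-scores) is not stored in the edge
#' representation; supply `diagonal` to fill it, otherwise it is zero.
#'
#' @param edges Numeric vector of edge values (length `n*(n-1)/2`).
#' @param index Edge index as returned by [edge_index()]; inferred from the
#'   length of `edges` when omitted.
#' @param diagonal Optional length-`n` diagonal.
#' @return Symmetric `n` x `n` matrix.
#' @export
frame_matrix <- function(edges, index = NULL, diagonal = NULL) {
  m <- length(edges)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-8) stop("edge vector length is not n*(n-1)/2")
  n <- as.integer(round(n))
  if (is.null(index)) index <- edge_index(n)
  W <- matrix(0, n, n)
  W[cbind(index[, 1L], index[, 2L])] <- edges
  W <- W + t(W)
  if (!is.null(diagonal)) diag(W) <- diagonal
  W
}
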