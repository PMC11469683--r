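#' Total number of state transitions
#'
#' Counts frames `t` with `s(t) != s(t+1)`.
#'
#' @param seq Integer vector of frame-wise state labels (length >= 2).
#' @return Integer count.
#' @export
total_transitions <- function(seq) {
  if (length(seq) < 2L) stop("state sequence must have length >= 2")
  sum(seq[-length(seq)] != seq[-1L])
}

#' Fractional occupancy of each state
#'
#' Fraction of frames spent in each state; sums to 1. States never visited
#' have occupancy 0.
#'
#' @param seq Integer vector of state labels.
#' @param k Number of states.
#' @return Numeric vector of length `k`.
#' @export
fractional_occupancy <- function(seq, k) {
  if (length(seq) < 1L) stop("state sequence must be non-empty")
  if (any(seq < 1L | seq > k)) stop("state labels must lie in 1..k")
  tabulate(seq, nbins = k) / length(seq)
}

#' Directional transition-probability matrix
#'
#' Row `i` holds the probabilities of moving from state `i` to each state
#' `j`, including persistence (`j = i`), normalised by the total number of
#' frame pairs starting in `i`. Rows of states that never occur among frames
#' `1..T-1` (no outgoing pairs) are missing (`NA`), matching the convention
#' that transition probabilities from unvisited states are missing values.
#' The matrix is directional: `T[i, j]` and `T[j, i]` generally differ.
#'
#' @param seq Integer vector of state labels (length >= 2).
#' @param k Number of states.
#' @return `k` x `k` matrix; non-missing rows sum to 1.
#' @export
transition_probabilities <- function(seq, k) {
  counts <- transition_counts(seq, k)
  out <- counts / rowSums(counts)
  out[rowSums(counts) == 0, ] <- NA_real_
  out
}

#' Raw ordered transition-pair counts
#'
#' @inheritParams transition_probabilities
#' @return `k` x `k` integer matrix of consecutive-pair counts.
#' @export
transition_counts <- function(seq, k) {
  if (length(seq) < 2L) stop("state sequence must have length >= 2")
  if (any(seq < 1L | seq > k)) stop("state labels must lie in 1..k")
  from <- factor(seq[-length(seq)], levels = seq_len(k))
  to <- factor(seq[-1L], levels = seq_len(k))
  counts <- unclass(table(from, to))
  dimnames(counts) <- NULL
  counts
}

#' Per-subject dynamics summary
#'
#' @inheritParams transition_probabilities
#' @return List with `total_transitions`, `fractional_occupancy` and
#'   `transition_probability`.
#' @export
dynamics_summary <- function(seq, k) {
  list(total_transitions = total_transitions(seq),
       fractional_occupancy = fractional_occupancy(seq, k),
       transition_probability = transition_probabilities(seq, k))
}
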