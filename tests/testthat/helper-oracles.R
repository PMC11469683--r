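# Independent discretised optimal-control oracle: Euler-discretise
# x' = Ax + u over n_steps and take the minimum-norm input reaching xf;
# energy = v' G^-1 v with the discrete reachability Gramian
# G = dt * sum_m Ad^m Ad'^m and v = xf - Ad^N x0.
euler_energy_oracle <- function(A, x0, xf, horizon = 1, n_steps = 1000) {
  n <- nrow(A)
  dt <- horizon / n_steps
  Ad <- diag(n) + dt * A
  G <- matrix(0, n, n)
  P <- diag(n)
  for (m in seq_len(n_steps)) {
    G <- G + P %*% t(P) * dt
    P <- Ad %*% P
  }
  v <- xf - P %*% x0
  drop(t(v) %*% solve(G, v))
}
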