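# euler_energy_oracle (the discretised optimal-control oracle) lives in
# helper-oracles.R and is shared with the acceptance checks.

random_system <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, 0.1, 1)
  W <- W + t(W)
  W
}

test_that("adjacency normalisation has the closed 2x2 form and a stable spectrum", {
  A <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2, 2), c = 1)
  expect_equal(A, matrix(c(-1, 0.5, 0.5, -1), 2, 2))
  expect_equal(sort(eigen(A)$values), c(-1.5, -0.5))

  for (seed in 1:5) {
    W <- random_system(8, seed)
    ev <- eigen(normalize_adjacency(W, 1), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev < 0))
    expect_true(all(ev >= -2))
    # scaling W leaves the spectrum inside [-2, 0)
    ev2 <- eigen(normalize_adjacency(W * 50, 1), symmetric = TRUE,
                 only.values = TRUE)$values
    expect_true(all(ev2 < 0 & ev2 >= -2))
  }
  expect_error(normalize_adjacency(matrix(0, 3, 3)), "all-zero")
})

test_that("the augmented-exponential Gramian matches closed form and quadrature", {
  # scalar: A = -1, T = 1 => W_T = (1 - exp(-2)) / 2
  G1 <- control_gramian(matrix(-1, 1, 1), 1)
  expect_equal(drop(G1), (1 - exp(-2)) / 2, tolerance = 1e-12)

  # random 5-node system vs Simpson quadrature of exp(At) exp(A't)
  A <- normalize_adjacency(random_system(5, 3), 1)
  eigA <- eigen(A, symmetric = TRUE)
  expA <- function(t) eigA$vectors %*% (exp(eigA$values * t) * t(eigA$vectors))
  ns <- 400
  h <- 1 / ns
  Gq <- matrix(0, 5, 5)
  for (i in 0:ns) {
    wgt <- if (i == 0 || i == ns) 1 else if (i %% 2 == 1) 4 else 2
    E <- expA(i * h)
    Gq <- Gq + wgt * E %*% t(E)
  }
  Gq <- Gq * h / 3
  expect_equal(control_gramian(A, 1), Gq, tolerance = 1e-8)
})

test_that("scalar minimum control energy matches the analytic value", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)  # gives A eigenvalues -0.5, -1.5
  sys <- control_system(W, horizon = 1)
  # project onto the symmetric eigenmode: behaves as scalar a = -0.5
  q <- c(1, 1) / sqrt(2)
  e <- min_control_energy(sys, q * 0, q * 1)
  a <- -0.5
  analytic <- 1 / ((exp(2 * a) - 1) / (2 * a))
  expect_equal(e$total, analytic, tolerance = 1e-10)
})

test_that("energy is zero on the natural trajectory and decomposes regionally", {
  for (seed in 1:5) {
    W <- random_system(7, seed + 20)
    sys <- control_system(W, horizon = 1)
    set.seed(seed)
    x0 <- rnorm(7)
    xf <- rnorm(7)
    e <- min_control_energy(sys, x0, xf)
    expect_gte(e$total, 0)
    expect_equal(sum(e$regional), e$total, tolerance = 1e-8 * abs(e$total))
    expect_true(all(e$regional >= -1e-12))
    # steering to the free endpoint costs nothing
    e0 <- min_control_energy(sys, x0, drop(sys$E %*% x0))
    expect_lt(abs(e0$total), 1e-20)
  }
})

test_that("closed-form energies agree with the discretised optimal-control oracle", {
  set.seed(99)
  for (trial in 1:10) {
    n <- sample(3:10, 1)
    W <- random_system(n, trial + 50)
    sys <- control_system(W, horizon = 1)
    x0 <- rnorm(n)
    xf <- rnorm(n)
    e <- min_control_energy(sys, x0, xf)
    oracle <- euler_energy_oracle(sys$A, x0, xf)
    expect_lt(abs(e$total - oracle) / oracle, 0.005)
  }
})

test_that("framewise energies are nonnegative, quadratically homogeneous and aligned", {
  W <- random_system(6, 7)
  sys <- control_system(W)
  set.seed(7)
  Z <- zscore_regional(matrix(rnorm(50 * 6), 50, 6))
  en <- framewise_energy(Z, sys)
  expect_length(en, 49L)
  expect_true(all(en >= 0))

  # identical consecutive frames still cost energy (the system decays)
  x <- rnorm(6)
  Z2 <- rbind(x, x)
  e2 <- framewise_energy(Z2, sys)
  expect_gt(e2, 0)

  # doubling both endpoints quadruples the energy
  e4 <- framewise_energy(2 * Z2, sys)
  expect_equal(e4, 4 * e2, tolerance = 1e-10)

  colnames(Z) <- paste0("X", 1:6)
  sys$region_labels <- paste0("Y", 1:6)
  expect_error(framewise_energy(Z, sys), "region order")
})

test_that("energies aggregate into a state-transition matrix with missing cells", {
  m <- energy_transition_matrix(c(5, 7), c(1, 1, 2), 2)
  expect_equal(m[1, 1], 5)
  expect_equal(m[1, 2], 7)
  expect_true(is.na(m[2, 1]) && is.na(m[2, 2]))

  m2 <- energy_transition_matrix(c(4, 1, 6), c(1, 2, 1, 2), 2)
  expect_equal(m2[1, 2], 5)  # mean of the two 1 -> 2 energies

  m3 <- energy_transition_matrix(rep(2, 9), rep(1, 10), 4)
  expect_equal(sum(!is.na(m3)), 1L)
  expect_equal(m3[1, 1], 2)

  expect_error(energy_transition_matrix(1:3, c(1, 2, 1), 2), "one energy per")
})

test_that("z-scoring against controls centres the control distribution per cell", {
  mk <- function(v) matrix(v, 1, 1)
  mats <- list(h1 = mk(1), h2 = mk(2), h3 = mk(3), p1 = mk(2), p2 = mk(5))
  z <- zscore_vs_controls(mats, c("h1", "h2", "h3"))
  expect_equal(drop(z$p1), 0)
  expect_equal(drop(z$p2), 3)

  two <- list(h1 = mk(1), h2 = mk(3), p = mk(3))
  z2 <- zscore_vs_controls(two, c("h1", "h2"))
  expect_equal(drop(z2$p), 1 / sqrt(2), tolerance = 1e-12)

  # after z-scoring, the control group has mean ~0 and sample SD ~1 per cell
  set.seed(30)
  mats4 <- lapply(1:12, function(i) matrix(rexp(4), 2, 2))
  names(mats4) <- paste0("s", 1:12)
  z4 <- zscore_vs_controls(mats4, paste0("s", 1:6))
  hc <- simplify2array(z4[1:6])
  expect_equal(apply(hc, c(1, 2), mean), matrix(0, 2, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(hc, c(1, 2), sd), matrix(1, 2, 2), tolerance = 1e-10,
               ignore_attr = TRUE)

  # zero control SD flags the cell unusable
  expect_warning(
    zd <- zscore_vs_controls(list(a = mk(1), b = mk(1), p = mk(2)),
                             c("a", "b")), "unusable")
  expect_true(is.na(drop(zd$p)))
})

test_that("energy summaries average the right cells and propagate missingness", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]
  s <- summarize_energy(m)
  expect_equal(unname(s), c(2.5, 2.5, 2.5))

  m2 <- matrix(c(1, NA, NA, 3), 2, 2)
  s2 <- summarize_energy(m2)
  expect_equal(unname(s2["total"]), 2)
  expect_equal(unname(s2["persistence"]), 2)
  expect_true(is.na(s2["transition"]))

  expect_error(summarize_energy(matrix(NA_real_, 2, 2)), "all-missing")
})

test_that("weaker structural integrity raises the energy of module-aligned activity", {
  # activity expressed in the connectome's modules (the cohort's regime):
  # a globally weaker connectome decays such activity faster, so steering it
  # between frames costs more input
  n <- 40
  module <- rep_len(1:4, n)
  tpl <- generate_module_templates(4, module, seed = 5)
  P <- matrix(0.25 / 3, 4, 4)
  diag(P) <- 0.75
  sim <- generate_subject_timeseries(tpl, P, n_frames = 60, noise_sd = 0.02,
                                     seed = 17)
  Z <- zscore_regional(sim$timeseries)
  colnames(Z) <- NULL
  means <- vapply(c(1, 0.85, 0.7), function(integ) {
    W <- generate_structural_connectome(n, 4, integrity = integ, seed = 55)
    mean(framewise_energy(Z, control_system(W)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))  # energy increases as integrity drops
})
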