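#' Generate near-orthogonal state activation templates
#'
#' Draws `k` unit-norm activation patterns over `n_regions` regions by
#' orthonormalising a Gaussian random matrix (QR), so pairwise cosine
#' similarity is 0 and trivially within any bound `max_cosine >= 0`. These
#' templates stand in for the robust whole-brain coactivation patterns that
#' connectivity states express.
#'
#' @param k Number of states (>= 2).
#' @param n_regions Number of regions (>= k).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param max_cosine Upper bound on pairwise |cosine|; checked post hoc.
#' @return List of `k` templates, each a list with `state_id`,
#'   `activation_pattern` (unit-norm numeric vector) and `name_hint`.
#' @export
generate_state_templates <- function(k, n_regions, seed, max_cosine = 0.3) {
  if (k < 2L) stop("k must be >= 2")
  if (k > n_regions) stop("k must not exceed n_regions")
  set.seed(seed)
  M <- matrix(rnorm(n_regions * k), n_regions, k)
  Q <- qr.Q(qr(M))[, seq_len(k), drop = FALSE]
  # deterministic sign convention: largest-magnitude loading positive
  for (c in seq_len(k)) {
    i <- which.max(abs(Q[, c]))
    if (Q[i, c] < 0) Q[, c] <- -Q[, c]
  }
  G <- abs(crossprod(Q))
  diag(G) <- 0
  if (max(G) > max_cosine) stop("templates exceed the cosine bound")  # QR => 0
  lapply(seq_len(k), function(s) {
    list(state_id = s, activation_pattern = Q[, s], name_hint = paste0("S", s))
  })
}

#' Generate module-aligned state activation templates
#'
#' Like [generate_state_templates()] but the activation patterns are
#' piecewise constant over a module partition of the regions: a random
#' module-loading matrix is lifted to region space and orthonormalised, so
#' the `k` templates are exactly orthogonal unit vectors that live in the
#' span of the module indicator vectors. When the structural connectome has
#' the same module partition, these templates lie in its leading (slow)
#' eigenmodes — the structure-function coupling seen in real brains, and the
#' regime in which white-matter integrity measurably shapes control energy.
#'
#' @param k Number of states (2 <= k <= number of modules).
#' @param module Integer module assignment, one entry per region.
#' @param seed Integer seed.
#' @return List of `k` templates as in [generate_state_templates()].
#' @export
generate_module_templates <- function(k, module, seed) {
  n_modules <- length(unique(module))
  if (k < 2L) stop("k must be >= 2")
  if (k > n_modules) stop("k must not exceed the number of modules")
  set.seed(seed)
  L <- matrix(rnorm(n_modules * k), n_modules, k)
  M <- L[module, , drop = FALSE]           # lift to regions
  Q <- qr.Q(qr(M))[, seq_len(k), drop = FALSE]  # still piecewise constant
  for (c in seq_len(k)) {
    i <- which.max(abs(Q[, c]))
    if (Q[i, c] < 0) Q[, c] <- -Q[, c]
  }
  lapply(seq_len(k), function(s) {
    list(state_id = s, activation_pattern = Q[, s], name_hint = paste0("S", s))
  })
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param P Row-stochastic k x k matrix.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  check_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

check_stochastic <- function(P, tol = 1e-8) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("Markov matrix must be square")
  if (any(P < -tol)) stop("Markov matrix has negative entries")
  if (any(abs(rowSums(P) - 1) > tol)) {
    stop("Markov matrix rows must sum to 1 (row-stochastic)")
  }
  invisible(P)
}

#' Simulate a Markov chain of state labels
#'
#' @param P Row-stochastic transition matrix.
#' @param n_frames Chain length.
#' @param init Initial distribution; defaults to the stationary distribution,
#'   which removes burn-in sensitivity.
#' @return Integer vector of states in `1..k`.
#' @export
simulate_markov_chain <- function(P, n_frames, init = NULL) {
  check_stochastic(P)
  k <- nrow(P)
  if (is.null(init)) init <- stationary_distribution(P)
  s <- integer(n_frames)
  s[1L] <- sample.int(k, 1L, prob = init)
  for (t in seq_len(n_frames - 1L)) {
    s[t + 1L] <- sample.int(k, 1L, prob = P[s[t], ])
  }
  s
}

#' Simulate one subject's regional time series from a hidden state chain
#'
#' Frame `t` is `amplitude(t) * pattern[s(t)] + noise`, where `s` is a hidden
#' Markov chain over the templates, the amplitude magnitude is drawn from
#' `Uniform(amplitude_range)` (bounded away from 0) with a random sign when
#' `random_sign = TRUE`, and noise is i.i.d. Gaussian. The random sign makes
#' the *regional* signal sign-ambiguous per frame while the *edge* pattern
#' (pairwise products) stays sign-stable per state, which is what frame
#' clustering relies on.
#'
#' @param templates Output of [generate_state_templates()].
#' @param markov_matrix Row-stochastic k x k matrix over the templates.
#' @param n_frames Number of frames (>= 2).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' The amplitude magnitude range is kept narrow by default so that the edge
#' geometry is dominated by which state is active rather than by amplitude
#' shells: a wide range (e.g. 0.5--1.5) makes the low-amplitude frames of all
#' states collapse toward the origin and form a spurious central cluster.
#'
#' @param amplitude_range Length-2 range for |amplitude|.
#' @param random_sign Randomise amplitude sign per frame.
#' @return List with `timeseries` (frames x regions matrix, columns named
#'   `R001`, ...) and `state_sequence` (the hidden chain).
#' @export
generate_subject_timeseries <- function(templates, markov_matrix, n_frames,
                                        noise_sd, seed,
                                        amplitude_range = c(0.8, 1.2),
                                        random_sign = TRUE) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  check_stochastic(markov_matrix)
  if (nrow(markov_matrix) != length(templates)) {
    stop("Markov matrix order must equal the number of templates")
  }
  n_regions <- length(templates[[1L]]$activation_pattern)
  pat <- vapply(templates, `[[`, numeric(n_regions), "activation_pattern")
  set.seed(seed)
  s <- simulate_markov_chain(markov_matrix, n_frames)
  amp <- runif(n_frames, amplitude_range[1L], amplitude_range[2L])
  if (random_sign) amp <- amp * sample(c(-1, 1), n_frames, replace = TRUE)
  X <- t(pat[, s, drop = FALSE]) * amp
  if (noise_sd > 0) {
    X <- X + matrix(rnorm(n_frames * n_regions, sd = noise_sd),
                    n_frames, n_regions)
  }
  colnames(X) <- sprintf("R%03d", seq_len(n_regions))
  list(timeseries = X, state_sequence = s)
}

#' Generate a synthetic weighted structural connectome
#'
#' Stochastic block structure with log-normal positive weights: regions are
#' assigned to `n_modules` modules and within-module pairs receive heavier
#' weights than between-module pairs, mimicking the modular, fully
#' positive-weight character of streamline-count connectomes. All weights are
#' scaled by `integrity`, the multiplicative white-matter integrity factor
#' used to plant group differences.
#'
#' The default weight scale puts the spectral radius of a 100-region matrix
#' near 1, the regime in which the stabilised dynamics `A = W/(lambda_max +
#' c) - I` (with `c = 1`) remain sensitive to a global integrity loss; much
#' larger raw weights would be normalised away.
#'
#' @param n_regions Number of regions.
#' @param n_modules Number of modules (>= 1).
#' @param integrity Multiplicative weight factor in (0, 1].
#' @param seed Integer seed.
#' @param weight_within,weight_between Log-normal medians of within- and
#'   between-module weights (streamline-weight units).
#' @param weight_sdlog Log-normal log-SD of the weights.
#' @return Symmetric, hollow-diagonal, nonnegative `n_regions` x `n_regions`
#'   matrix with region names `R001`, ...
#' @export
generate_structural_connectome <- function(n_regions, n_modules, integrity,
                                           seed, weight_within = 0.04,
                                           weight_between = 0.002,
                                           weight_sdlog = 0.3) {
  if (n_modules < 1L) stop("n_modules must be >= 1")
  if (integrity <= 0 || integrity > 1) stop("integrity must be in (0, 1]")
  set.seed(seed)
  module <- rep_len(seq_len(n_modules), n_regions)
  idx <- edge_index(n_regions)
  within <- module[idx[, 1L]] == module[idx[, 2L]]
  mlog <- ifelse(within, log(weight_within), log(weight_between))
  w <- exp(rnorm(nrow(idx), mean = mlog, sd = weight_sdlog)) * integrity
  W <- frame_matrix(w, idx)
  rownames(W) <- colnames(W) <- sprintf("R%03d", seq_len(n_regions))
  W
}

#' Default configuration for the synthetic cohort
#'
#' Study conditions emulated: 200 analysed frames per scan (a 202-volume
#' acquisition minus 2 discarded volumes), 100 regions in 8 resting-state
#' networks, 4 hidden connectivity states, three groups of 20 subjects
#' (healthy controls HC, cognitively preserved CP, cognitively impaired CI).
#' CI subjects get reduced off-diagonal Markov mass (fewer state transitions:
#' persistence 0.85 vs 0.75, i.e. ~30 vs ~50 expected transitions in 200
#' frames, the directionality and scale of the empirical groups) and reduced
#' structural integrity (0.7 vs 1.0). CI cognitive deficits of -3.5 residual
#' SDs are planted on three domains so the impairment rule (>= 2 of 7 domains
#' below -2 HC-referenced SDs) recovers the group.
#'
#' @return Named list of generator settings; edit fields to change scenarios.
#' @export
default_cohort_config <- function() {
  persist <- function(d, k = 4L) {
    P <- matrix((1 - d) / (k - 1L), k, k)
    diag(P) <- d
    P
  }
  domains <- c("executive_function", "verbal_memory",
               "information_processing_speed", "verbal_fluency",
               "visuospatial_memory", "working_memory", "attention")
  deficits <- matrix(0, nrow = 4L, ncol = 7L,
                     dimnames = list(c("HC", "CP", "MCI", "CI"), domains))
  deficits["MCI", c("information_processing_speed", "verbal_memory",
                    "attention")] <- -1.8
  deficits["CI", c("information_processing_speed", "verbal_memory",
                   "attention")] <- -3.5
  list(
    group_sizes = c(HC = 20L, CP = 20L, CI = 20L),
    k = 4L,
    n_regions = 100L,
    n_frames = 200L,
    n_networks = 8L,
    n_modules = 4L,
    noise_sd = 0.02,
    amplitude_range = c(0.8, 1.2),
    markov = list(HC = persist(0.75), CP = persist(0.75),
                  MCI = persist(0.80), CI = persist(0.85)),
    integrity = c(HC = 1.0, CP = 1.0, MCI = 0.85, CI = 0.7),
    cognitive = list(
      domains = domains,
      baseline = 50,
      noise_sd = 5,
      age_beta = -0.3,
      sex_beta = 1.0,
      education_beta = 3.0,
      deficit_sd_units = deficits  # group x domain, in residual-SD units
    )
  )
}

#' Generate a full synthetic cohort with ground truth
#'
#' Produces subject metadata (group, age, sex, binary education, 7 raw
#' cognitive domain scores), per-subject regional time series driven by
#' hidden group-specific Markov chains over shared state templates,
#' per-subject structural connectomes scaled by group integrity, region
#' metadata (8 resting-state network labels), and the complete ground truth
#' (templates, Markov matrices, true state sequences, integrity factors).
#' Cognitive raw scores are a linear function of age/sex/education plus the
#' planted group deficit plus Gaussian noise, so HC-referenced adjustment has
#' real structure to remove. Fully reproducible for a fixed seed.
#'
#' @param config Configuration list, see [default_cohort_config()].
#' @param seed Integer seed.
#' @return List with `subjects` (data.frame), `regions` (data.frame of region
#'   and network labels), `timeseries` and `connectomes` (named lists of
#'   matrices), and `ground_truth`.
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = 1L) {
  gs <- config$group_sizes
  if (any(gs < 1L)) stop("all group sizes must be >= 1")
  if (!all(names(gs) %in% c("HC", "CP", "MCI", "CI"))) {
    stop("groups must be among HC, CP, MCI, CI")
  }
  k <- config$k
  n_regions <- config$n_regions
  set.seed(seed)
  template_seed <- sample.int(.Machine$integer.max, 1L)
  # module-aligned templates: coactivation patterns live in the structural
  # modules, so integrity loss measurably raises control energy
  module <- rep_len(seq_len(config$n_modules), n_regions)
  templates <- generate_module_templates(k, module, seed = template_seed)

  groups <- rep(names(gs), gs)
  n_subj <- length(groups)
  ids <- sprintf("sub%03d", seq_len(n_subj))

  set.seed(seed + 1L)
  subj_seeds <- sample.int(.Machine$integer.max, 2L * n_subj)
  age <- round(runif(n_subj, 30, 60), 1)
  sex <- sample(0:1, n_subj, replace = TRUE)
  education <- sample(0:1, n_subj, replace = TRUE)

  cg <- config$cognitive
  n_dom <- length(cg$domains)
  scores <- matrix(NA_real_, n_subj, n_dom, dimnames = list(ids, cg$domains))
  for (i in seq_len(n_subj)) {
    deficit <- cg$deficit_sd_units[groups[i], ] * cg$noise_sd
    scores[i, ] <- cg$baseline + cg$age_beta * (age[i] - 45) +
      cg$sex_beta * sex[i] + cg$education_beta * education[i] +
      deficit + rnorm(n_dom, sd = cg$noise_sd)
  }

  ts_list <- vector("list", n_subj)
  sc_list <- vector("list", n_subj)
  true_seq <- vector("list", n_subj)
  names(ts_list) <- names(sc_list) <- names(true_seq) <- ids
  for (i in seq_len(n_subj)) {
    g <- groups[i]
    sim <- generate_subject_timeseries(
      templates, config$markov[[g]], config$n_frames, config$noise_sd,
      seed = subj_seeds[i], amplitude_range = config$amplitude_range)
    ts_list[[i]] <- sim$timeseries
    true_seq[[i]] <- sim$state_sequence
    sc_list[[i]] <- generate_structural_connectome(
      n_regions, config$n_modules, config$integrity[[g]],
      seed = subj_seeds[n_subj + i])
  }

  network_names <- c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN", "DGM")
  networks <- rep_len(network_names[seq_len(config$n_networks)], n_regions)
  regions <- data.frame(region = sprintf("R%03d", seq_len(n_regions)),
                        network = networks, stringsAsFactors = FALSE)

  subjects <- data.frame(subject_id = ids, group = groups, age = age,
                         sex = sex, education = education,
                         stringsAsFactors = FALSE)
  subjects <- cbind(subjects, as.data.frame(scores, row.names = NULL))

  list(
    subjects = subjects,
    regions = regions,
    timeseries = ts_list,
    connectomes = sc_list,
    ground_truth = list(
      templates = templates,
      markov_matrix_by_group = config$markov[unique(groups)],
      true_sequences = true_seq,
      connectome_integrity_by_group = config$integrity[unique(groups)]
    )
  )
}

#' Write a cohort to delimited text files
#'
#' Emits `SUBJ_timeseries.tsv` (frames x regions, header = region names) and
#' `SUBJ_connectome.tsv` per subject, plus `subjects.tsv`, `regions.tsv` and
#' `ground_truth.json`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$timeseries)) {
    write.table(cohort$timeseries[[id]],
                file.path(dir, paste0(id, "_timeseries.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cohort$connectomes[[id]],
                file.path(dir, paste0(id, "_connectome.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$regions, file.path(dir, "regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cohort$ground_truth
  json <- list(
    templates = lapply(gt$templates, function(s)
      list(state_id = s$state_id, name_hint = s$name_hint,
           activation_pattern = s$activation_pattern)),
    markov_matrix_by_group = gt$markov_matrix_by_group,
    true_sequences = gt$true_sequences,
    connectome_integrity_by_group = as.list(gt$connectome_integrity_by_group)
  )
  jsonlite::write_json(json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject time-series or connectome TSV
#'
#' @param path File written by [write_cohort()] (tab-delimited, header row).
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}
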