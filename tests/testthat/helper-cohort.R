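# Shared fixtures. The full-scale default cohort pipeline is expensive, so it
# is computed lazily once per session and memoised for the tests that need it.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small cohort for unit-level end-to-end checks (seconds, not minutes)
small_cohort_config <- function() {
  cfg <- default_cohort_config()
  cfg$group_sizes <- c(HC = 6L, CP = 6L, CI = 6L)
  cfg$n_regions <- 30L
  cfg$n_frames <- 80L
  cfg
}

get_small_cohort <- function() {
  memo("small_cohort", generate_cohort(small_cohort_config(), seed = 7L))
}

# full default cohort (study conditions): 20 HC / 20 CP / 20 CI, 200 frames,
# 100 regions, 4 planted states
get_default_cohort <- function() {
  memo("default_cohort", generate_cohort(default_cohort_config(), seed = 42L))
}

get_pooled_edges <- function() {
  memo("pooled_edges", {
    cohort <- get_default_cohort()
    do.call(rbind, lapply(cohort$timeseries, function(ts) {
      edge_time_series(zscore_regional(ts))
    }))
  })
}

# k = 2..7 sweep with 5 replicates on the pooled default-cohort edges
get_state_sweep <- function() {
  memo("state_sweep",
       fit_states_range(get_pooled_edges(), 2:7, replicates = 5L, seed = 42L))
}

get_default_pipeline <- function() {
  memo("default_pipeline", {
    cohort <- get_default_cohort()
    sweep <- get_state_sweep()
    k <- select_k_elbow(sweep$inertia_by_k)
    fit <- sweep$fits[[as.character(k)]]
    n_frames <- vapply(cohort$timeseries, nrow, integer(1))
    sequences <- split_assignments(fit$assignments, n_frames)
    subj <- cohort$subjects
    subj$total_transitions <-
      vapply(sequences[subj$subject_id], total_transitions, numeric(1))
    energy_mats <- lapply(subj$subject_id, function(id) {
      sys <- control_system(cohort$connectomes[[id]])
      z <- zscore_regional(cohort$timeseries[[id]])
      energy_transition_matrix(framewise_energy(z, sys), sequences[[id]], k)
    })
    names(energy_mats) <- subj$subject_id
    zmats <- zscore_vs_controls(energy_mats,
                                subj$subject_id[subj$group == "HC"])
    ce <- t(vapply(zmats, summarize_energy, numeric(3)))
    subj$total_ce <- ce[, "total"]
    subj$persistence_ce <- ce[, "persistence"]
    subj$transition_ce <- ce[, "transition"]
    list(cohort = cohort, k = k, fit = fit, sequences = sequences,
         subjects = subj, energy = energy_mats, energy_z = zmats)
  })
}
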