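#!/usr/bin/env Rscript
# Edge time series, pooled city-block k-means over k = 2..7, elbow model
# order, per-subject state sequences and graph-theoretical state
# descriptors. Reads results/cohort, writes results/states/.

library(brainstates)

dir.create("results/states", recursive = TRUE, showWarnings = FALSE)
subjects <- read.delim("results/cohort/subjects.tsv")
regions <- read.delim("results/cohort/regions.tsv")

message("computing edge time series for ", nrow(subjects), " subjects ...")
edges <- lapply(subjects$subject_id, function(id) {
  ts <- read_matrix_tsv(sprintf("results/cohort/%s_timeseries.tsv", id))
  edge_time_series(zscore_regional(ts))
})
pooled <- do.call(rbind, edges)

message("clustering ", nrow(pooled), " pooled frames (k = 2..7) ...")
sweep <- fit_states_range(pooled, 2:7, replicates = 5L, seed = 42L)
k <- select_k_elbow(sweep$inertia_by_k)
message("elbow selects k = ", k, " connectivity states")
write.table(data.frame(k = as.integer(names(sweep$inertia_by_k)),
                       inertia = sweep$inertia_by_k),
            "results/states/inertia_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fit <- sweep$fits[[as.character(k)]]
n_frames <- setNames(rep(200L, nrow(subjects)), subjects$subject_id)
sequences <- split_assignments(fit$assignments, n_frames)
seq_tab <- do.call(rbind, lapply(names(sequences), function(id) {
  data.frame(subject_id = id, frame = seq_along(sequences[[id]]),
             state = sequences[[id]])
}))
write.table(seq_tab, "results/states/state_sequences.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

desc <- do.call(rbind, lapply(seq_len(k), function(s) {
  d <- describe_state(fit$centroids[s, ], network_labels = regions$network)
  data.frame(state = s, name = d$name,
             global_mean_connectivity = d$global_mean_connectivity,
             global_efficiency = d$global_efficiency,
             modularity = d$modularity,
             t(d$centrality_by_network))
}))
write.table(desc, "results/states/state_descriptors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("state names (network of maximal eigenvector centrality): ",
        paste(sprintf("S%d=%s", desc$state, desc$name), collapse = ", "))
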