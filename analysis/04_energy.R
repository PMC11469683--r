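#!/usr/bin/env Rscript
# Network-control-theory energies: per-subject framewise minimum control
# energy on the structural connectome, aggregated into k x k state-transition
# energy matrices, z-scored against the healthy controls, and summarised as
# total / persistence / transition control energy. Writes results/energy.tsv.

library(brainstates)

subjects <- read.delim("results/cohort/subjects.tsv")
seqs <- read.delim("results/states/state_sequences.tsv")
k <- max(seqs$state)
by_subj <- split(seqs$state, seqs$subject_id)

message("computing control energies (horizon T = 3) ...")
mats <- lapply(subjects$subject_id, function(id) {
  W <- read_matrix_tsv(sprintf("results/cohort/%s_connectome.tsv", id))
  rownames(W) <- colnames(W)
  z <- zscore_regional(
    read_matrix_tsv(sprintf("results/cohort/%s_timeseries.tsv", id)))
  sys <- control_system(W)
  energy_transition_matrix(framewise_energy(z, sys), by_subj[[id]], k)
})
names(mats) <- subjects$subject_id

hc_ids <- subjects$subject_id[subjects$group == "HC"]
zmats <- zscore_vs_controls(mats, hc_ids)

flat <- function(m, prefix) {
  v <- as.vector(t(m))
  names(v) <- paste0(prefix, rep(seq_len(k), each = k), "_", seq_len(k))
  as.data.frame(t(v))
}
rows <- lapply(subjects$subject_id, function(id) {
  s <- summarize_energy(zmats[[id]])
  cbind(data.frame(subject_id = id, total_ce = s["total"],
                   persistence_ce = s["persistence"],
                   transition_ce = s["transition"], row.names = NULL),
        flat(mats[[id]], "E"), flat(zmats[[id]], "zE"))
})
energy <- do.call(rbind, rows)
write.table(energy, "results/energy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
g <- subjects$group
message(sprintf(
  "wrote results/energy.tsv; mean transition CE (HC-z): HC %.2f, CP %.2f, CI %.2f",
  mean(energy$transition_ce[g == "HC"], na.rm = TRUE),
  mean(energy$transition_ce[g == "CP"], na.rm = TRUE),
  mean(energy$transition_ce[g == "CI"], na.rm = TRUE)))
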