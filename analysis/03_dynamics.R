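#!/usr/bin/env Rscript
# Per-subject state dynamics: total transitions, fractional occupancy and
# directional transition probabilities. Reads results/states, writes
# results/dynamics.tsv.

library(brainstates)

seqs <- read.delim("results/states/state_sequences.tsv")
k <- max(seqs$state)
by_subj <- split(seqs$state, seqs$subject_id)

rows <- lapply(names(by_subj), function(id) {
  d <- dynamics_summary(by_subj[[id]], k)
  tp <- as.vector(t(d$transition_probability))
  names(tp) <- paste0("T", rep(seq_len(k), each = k), "_", seq_len(k))
  cbind(data.frame(subject_id = id, total_transitions = d$total_transitions),
        as.data.frame(t(setNames(d$fractional_occupancy,
                                 paste0("FO", seq_len(k))))),
        as.data.frame(t(tp)))
})
dyn <- do.call(rbind, rows)
write.table(dyn, "results/dynamics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/dynamics.tsv (", nrow(dyn), " subjects, k = ", k, ")")
message(sprintf("mean total transitions: %.1f", mean(dyn$total_transitions)))
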