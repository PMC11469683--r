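#!/usr/bin/env Rscript
# Generate the default synthetic cohort and write it to results/cohort/:
# 20 HC / 20 CP / 20 CI subjects, 200-frame scans over 100 regions in 8
# resting-state networks, 4 planted connectivity states driven by hidden
# group-specific Markov chains, per-subject structural connectomes (CI
# integrity 0.7), and raw cognitive domain scores with planted CI deficits.

library(brainstates)

seed <- 42L
cohort <- generate_cohort(default_cohort_config(), seed = seed)
write_cohort(cohort, "results/cohort")

tt <- vapply(cohort$ground_truth$true_sequences, total_transitions, numeric(1))
g <- cohort$subjects$group
message(sprintf("wrote %d subjects to results/cohort (seed %d)",
                nrow(cohort$subjects), seed))
message(sprintf("planted mean total transitions: HC %.1f, CP %.1f, CI %.1f",
                mean(tt[g == "HC"]), mean(tt[g == "CP"]),
                mean(tt[g == "CI"])))
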