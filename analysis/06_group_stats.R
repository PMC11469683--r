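#!/usr/bin/env Rscript
# Covariate-adjusted group statistics over the dynamics and energy measures:
# linear or Quade rank ANCOVA (routed by KS normality) with CI-vs-CP
# contrasts, Bonferroni families per analysis block, and partial correlations
# of transitions with energy. Writes results/group_stats.tsv.

library(brainstates)

subjects <- read.delim("results/cohort/subjects.tsv")
dyn <- read.delim("results/dynamics.tsv")
energy <- read.delim("results/energy.tsv")
stopifnot(identical(dyn$subject_id, subjects$subject_id),
          identical(energy$subject_id, subjects$subject_id))
covs <- subjects[, c("age", "sex", "education")]
grp <- subjects$group
k <- sum(grepl("^FO", names(dyn)))

block <- function(measures, data) {
  res <- do.call(rbind, lapply(measures, function(m) {
    compare_groups(data[[m]], grp, covs, measure = m)
  }))
  res$p_bonferroni <- bonferroni(res$p_raw, nrow(res))
  res
}

results <- rbind(
  block("total_transitions", dyn),
  block(paste0("FO", seq_len(k)), dyn),
  block(c("total_ce", "persistence_ce", "transition_ce"), energy)
)
write.table(results, "results/group_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("group comparisons (CI vs CP beta, Bonferroni-corrected p):")
print(results[, c("measure", "method", "F", "p_bonferroni", "beta")],
      row.names = FALSE)

pc <- partial_correlation(dyn$total_transitions, energy$transition_ce, covs)
message(sprintf(
  "partial correlation (transitions vs transition CE | age, sex, education): r = %.2f, p = %.3g, n = %d",
  pc$r, pc$p, pc$n))
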