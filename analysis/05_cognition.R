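#!/usr/bin/env Rscript
# Healthy-control-referenced cognitive z-scores (adjusted for age, sex and
# binary education with HC-fitted models) and CP / MCI / CI classification.
# Writes results/cognition.tsv and compares recovered with planted labels.

library(brainstates)

subjects <- read.delim("results/cohort/subjects.tsv")
domains <- c("executive_function", "verbal_memory",
             "information_processing_speed", "verbal_fluency",
             "visuospatial_memory", "working_memory", "attention")

z <- adjust_and_zscore(subjects[, domains],
                       subjects[, c("age", "sex", "education")],
                       subjects$group == "HC")
label <- classify_cognition(z)

out <- cbind(subjects[, c("subject_id", "group")],
             as.data.frame(z), classified = label)
write.table(out, "results/cognition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

patients <- subjects$group %in% c("CP", "MCI", "CI")
agree <- mean(label[patients] == subjects$group[patients])
message(sprintf(
  "wrote results/cognition.tsv; planted patient labels recovered: %.0f%%",
  100 * agree))
print(table(planted = subjects$group[patients],
            classified = label[patients]))
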