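#!/usr/bin/env Rscript
# Step 6 — clinical association statistics.
#
# Correlates the pattern subject scores with the clinical table
# (normality-gated Pearson/Spearman, FDR-adjusted as one family), repeats
# the severity association with severity partialled out for the
# neurocognitive scores, and compares scores and SBM mixing coefficients
# between groups.

library(icapattern)

scores <- read.table("results/demo/scores.tsv", sep = "\t", header = TRUE)
clinical <- read.table("results/demo/cohort/clinical.tsv", sep = "\t",
                       header = TRUE)
merged <- merge(scores, clinical, by = c("subject_id", "group"))
pat <- merged[merged$group == "patient", ]

assoc <- association_table(pat, "pattern_score",
                           c("severity_score", "sdmt", "fluency",
                             "external_pattern_score"))
cat("pattern-score associations in the patient group (FDR-adjusted):\n")
print(assoc[, c("y", "method", "estimate", "p_value", "q_value", "n")],
      row.names = FALSE, digits = 3)

# neurocognitive associations with severity partialled out
partial <- association_table(pat, "pattern_score", c("sdmt", "fluency"),
                             covariates = "severity_score")
cat("\nwith severity as covariate:\n")
print(partial[, c("y", "method", "estimate", "p_value", "q_value")],
      row.names = FALSE, digits = 3)

grp <- group_compare(merged$pattern_score, merged$group,
                     varname = "pattern_score")
cat(sprintf("\ngroup difference in pattern scores (%s test): p = %.3g\n",
            grp$test, grp$p_value))

write.table(rbind(assoc, partial), "results/demo/clinical_stats.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
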