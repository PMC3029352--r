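#!/usr/bin/env Rscript
# Step 2 — call differential regulation against control roots.
#
# Median-centres each sample, runs the one-sample t-test per probe and
# condition, adjusts with Benjamini-Hochberg within each condition, and
# calls up/none/down at ratio >= 1.5 and adjusted p <= 0.05 (inclusive).
# Reports the per-condition counts and the unique-up fractions, the two
# internal-consistency views of the experiment.

suppressMessages(library(nodclass))

ds <- read_expression_table("results/nodule_matrix.tsv", panel = "nodule")
calls <- call_regulation(normalize_dataset(ds), analysis_config())
write_calls(calls, "results/nodule_calls.tsv")

cnt <- per_condition_counts(calls)
uf <- unique_up_fraction(calls)
utils::write.table(merge(cnt, uf[, c("condition", "n_unique", "fraction")]),
                   "results/de_counts.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
ov <- pairwise_overlap(calls)
utils::write.table(ov$up, "results/overlap_up.tsv", sep = "\t", quote = FALSE)

cat(sprintf("%d of %d probes differentially regulated\n",
            length(de_probes(calls)), nrow(calls$call)))
print(calls)
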