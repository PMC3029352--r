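#!/usr/bin/env Rscript
# Step 6 — root qRT-PCR activation/repression patterns.
#
# Runs delta-delta-Ct relative quantification against the ubiquitin-like
# reference gene, calls the five-symbol vector per gene over the eight
# root conditions, matches the activation (A1-A4) and repression (R1-R4)
# archetypes, and checks recovery of the planted patterns.

suppressMessages(library(nodclass))

ct <- read_ct_table("results/root_ct.tsv")
res <- classify_gene_panel(ct, analysis_config())
utils::write.table(res, "results/root_patterns.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

truth <- utils::read.delim("results/root_truth.tsv", stringsAsFactors = FALSE)
want <- ifelse(truth$pattern == "none", "unclassified", truth$pattern)
got <- res$pattern[match(truth$gene_id, res$gene_id)]
cat("pattern recovery:\n")
print(table(planted = want, recovered = got))
cat(sprintf("overall: %.1f%%\n", 100 * mean(got == want)))
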