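#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study material.
#
# Builds (i) a nodule expression dataset: seven nodule conditions vs a
# common control, four replicates each, with known class membership planted
# for all sixteen expression classes over a genome-like non-differential
# background, and (ii) a qRT-PCR Ct table over the eight root conditions
# plus control, three repetitions, with the eight activation/repression
# archetypes planted. Writes the TSVs every later step consumes, plus the
# truth tables.

suppressMessages(library(nodclass))
dir.create("results", showWarnings = FALSE)
seed <- 20110127

cfg <- sim_config(seed = seed)
sim <- generate_nodule_dataset(cfg)
write_expression_table(sim$dataset, "results/nodule_matrix.tsv")
write_annotations(sim$dataset$annotations, "results/nodule_annotations.tsv")
utils::write.table(sim$truth[order(sim$truth$probe_id), ],
                   "results/nodule_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

pc <- stats::setNames(rep(12L, 9), c(paste0("A", 1:4), paste0("R", 1:4), "none"))
simr <- generate_root_qpcr(pc, sim_config(seed = seed + 1))
write_ct_table(simr$ct, "results/root_ct.tsv")
utils::write.table(simr$truth, "results/root_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("nodule dataset: %d probes x %d samples (%d planted DE)\n",
            nrow(sim$dataset$values), ncol(sim$dataset$values),
            sum(sim$truth$class_label != "not_DE")))
cat(sprintf("root Ct table: %d genes + reference, %d samples\n",
            nrow(simr$ct$ct) - 1, ncol(simr$ct$ct)))
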