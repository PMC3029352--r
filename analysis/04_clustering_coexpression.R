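#!/usr/bin/env Rscript
# Step 4 — cluster condition profiles and query co-expression neighbours.
#
# Clusters the seven nodule conditions over the mean profiles of the
# regulated probes (Pearson correlation distance, average linkage) and
# writes the dendrogram as Newick; the nitrogen-fixing time points (WT10,
# WT14) are expected to merge first. Also runs a co-expression query
# around one planted immature-nodule probe at Pearson r >= 0.8.

suppressMessages(library(nodclass))

ds <- read_expression_table("results/nodule_matrix.tsv")
calls <- read_calls("results/nodule_calls.tsv")
cm <- condition_means(ds)[de_probes(calls), ]

tree <- average_linkage(pearson_distance(t(cm)))
linkage_newick(tree, "results/condition_tree.nwk")
first <- sort(tree$labels[-tree$merge[1, ]])
cat("first condition merge:", paste(first, collapse = " + "),
    sprintf("(height %.3f)\n", tree$height[1]))

truth <- utils::read.delim("results/nodule_truth.tsv", stringsAsFactors = FALSE)
ref <- truth$probe_id[truth$class_label == "zone1_2"][1]
hits <- coexpression_query(ref, cm, threshold = analysis_config()$coexpr_threshold)
utils::write.table(hits, "results/coexpression_hits.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
same <- truth$class_label[match(hits$probe_id, truth$probe_id)] == "zone1_2"
cat(sprintf("co-expression around %s: %d hits at r >= 0.8, %.0f%% from its own class\n",
            ref, nrow(hits), 100 * mean(same)))
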