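#!/usr/bin/env Rscript
# Step 5 — cross-platform qualitative concordance.
#
# Emulates the comparison of two platforms profiling the same material:
# a second dataset is simulated from the same planted truth (an
# independent noise draw standing in for an independent hybridisation
# series), both are called, and per-probe call signs are compared over the
# shared wild-type/nitrate conditions. Discordance is summarised overall
# and within the probes regulated in exactly one condition, which are
# expected to carry most of it.

suppressMessages(library(nodclass))
seed <- 20110127

calls_a <- read_calls("results/nodule_calls.tsv")
sim_b <- generate_nodule_dataset(sim_config(seed = seed + 7))
calls_b <- call_regulation(normalize_dataset(sim_b$dataset))

shared <- c("WT4", "WT10", "WT14", "NN")
restrict <- function(calls, keep) {
  for (f in c("call", "ratio", "p_raw", "p_adj"))
    if (!is.null(calls[[f]])) calls[[f]] <- calls[[f]][, keep, drop = FALSE]
  calls$conditions <- keep
  calls
}
rep_ <- concordance(restrict(calls_a, shared), restrict(calls_b, shared))
print(rep_)

single <- single_condition_flag(calls_a)
verd <- rep_$verdicts
disc_single <- mean(single[verd$probe_a[!verd$concordant]])
cat(sprintf("%.0f%% of discordant probes are single-condition calls\n",
            100 * disc_single))
writeLines(jsonlite::toJSON(list(
  n_compared = rep_$n_compared, n_concordant = rep_$n_concordant,
  fraction_pct = rep_$fraction,
  discordant_single_condition_pct = 100 * disc_single
), auto_unbox = TRUE, pretty = TRUE), "results/concordance.json")
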