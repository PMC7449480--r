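#!/usr/bin/env Rscript
# Step 3 -- information-gain feature ranking.
#
# Ranks all 103 parameters by the expected entropy reduction of their best
# threshold split on the working set (held-back patients excluded, as the
# final evaluation must never see them).

suppressPackageStartupMessages(library(doaindex))

tab <- read.table("scratch/feature_table.tsv", sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE)
plan <- make_split(unique(tab$patient_id), n_heldback = 3, seed = 7)
write_split(plan, "results/split_plan.tsv")
cat(sprintf("split: %d working / %d held-back patients\n",
            length(plan$working), length(plan$held_back)))

work <- tab[tab$patient_id %in% plan$working, ]
parts <- split_feature_table(work)
rk <- rank_features(parts$x, parts$meta$state)
write.table(rk, "results/feature_ranking.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("top 10 parameters by information gain (working set):\n")
print(head(rk, 10), row.names = FALSE)
cat("wrote results/feature_ranking.tsv and results/split_plan.tsv\n")
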