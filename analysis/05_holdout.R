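#!/usr/bin/env Rscript
# Step 5 -- final evaluation on the held-back patients.
#
# Trains the chosen compound indicator (RBF-kernel SVM, 20 features selected
# on the working set) on all working patients and evaluates it, together with
# the best single EEG and AEP parameters, on the held-back patients: pooled
# P_K with a patient-level bootstrap confidence interval.

suppressPackageStartupMessages(library(doaindex))

tab <- read.table("scratch/feature_table.tsv", sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE)
plan <- read_split("results/split_plan.tsv")
cat(sprintf("holdout: %s\n", paste(plan$held_back, collapse = ", ")))

res <- final_holdout_evaluation(tab, plan,
                                spec = classifier_spec("svm_rbf", C = 1),
                                n_features = 20, B = 2000, seed = 7)
write.table(res, "results/holdout.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("pooled P_K on the held-back patients (95% bootstrap CI):\n")
print(res, row.names = FALSE)
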