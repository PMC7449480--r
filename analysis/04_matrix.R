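#!/usr/bin/env Rscript
# Step 4 -- the classifier comparison matrices.
#
# On the working set, leave-one-patient-out cross-validation of every
# classifier family over growing top-n feature subsets (feature selection
# redone inside each training fold), with the SVM cost picked over the
# canonical C grid; then the modality comparison (EEG-only vs AEP-only vs
# combined) and the EEG low-pass sweep (f_high 30/49/90 Hz).

suppressPackageStartupMessages(library(doaindex))

tab <- read.table("scratch/feature_table.tsv", sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE)
plan <- read_split("results/split_plan.tsv")
work <- tab[tab$patient_id %in% plan$working, ]

n_values <- c(1, 2, 5, 10, 20)
specs <- c(
  lapply(c(0.1, 1, 10), function(C) classifier_spec("svm_rbf", C = C, grid_mode = TRUE)),
  list(classifier_spec("svm_linear", C = 0.1, grid_mode = TRUE),
       classifier_spec("naive_bayes"), classifier_spec("naive_bayes_kernel"),
       classifier_spec("logistic"), classifier_spec("mlp"),
       classifier_spec("tree_c45"), classifier_spec("bayes_net")))

cat("running classifier x n-features matrix on the working set ...\n")
led <- run_matrix(work, specs, n_values = n_values)
write.table(led, "results/matrix_ledger.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
best <- led[led$best, c("classifier", "C", "n_features", "pk_mean", "pk_sd")]
best <- best[order(-best$pk_mean), ]
cat("best patient-wise mean P_K per classifier:\n")
print(best, row.names = FALSE)

cat("\nmodality comparison (svm_rbf, n = 20):\n")
mod <- run_matrix(work, list(classifier_spec("svm_rbf", C = 1)),
                  n_values = 20, modalities = c("EEG", "AEP", "combined"))
write.table(mod, "results/modality_ledger.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
print(mod[, c("modality", "pk_mean", "pk_sd")], row.names = FALSE)

cat("\nEEG low-pass sweep (EEG-only, svm_rbf, n = 7):\n")
fh <- run_matrix(work, list(classifier_spec("svm_rbf", C = 1)),
                 n_values = 7, modalities = "EEG", f_high_values = c(30, 49, 90))
write.table(fh, "results/fhigh_ledger.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
print(fh[, c("f_high", "pk_mean", "pk_sd")], row.names = FALSE)
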