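#!/usr/bin/env Rscript
# Step 4 — RUSBoost classification.
#
# The two most discriminant variables (SNR_min, b_max) feed a RUSBoost
# ensemble of depth-2 trees, evaluated by 15-fold (leave-one-out)
# cross-validation; out-of-fold scores are pooled into one ROC and both
# the cross-validated and training-set metrics are reported.

suppressPackageStartupMessages(library(mfvepris))

patients <- read_patient_table("results/patients.csv")
X <- patients[, c("snr_min", "bmax_ms")]
names(X) <- c("snr_min", "bmax_ms")
y <- as.integer(patients$group == "RIS_conv")

rep <- cross_validate(X, y, folds = nrow(X), seed = 20231L + 23L,
                      n_rounds = 30, tree_depth = 2, ratio = 1)

jsonlite::write_json(
  list(sensitivity = rep$sensitivity, specificity = rep$specificity,
       auc = rep$auc, confusion = as.data.frame(rep$confusion),
       training = rep$training, folds = rep$folds,
       predictions = rep$predictions),
  "results/classifier_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

message(sprintf(
  "leave-one-out: sensitivity %.2f, specificity %.2f, AUC %.2f",
  rep$sensitivity, rep$specificity, rep$auc))
message(sprintf(
  "training set:  sensitivity %.2f, specificity %.2f, AUC %.2f",
  rep$training$sensitivity, rep$training$specificity, rep$training$auc))
message("confusion matrix (truth x prediction):")
print(rep$confusion)
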