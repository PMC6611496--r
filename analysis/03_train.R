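#!/usr/bin/env Rscript
# Stage 3: train both regression models on the selection set.
#
# Fits the polynomial-kernel support vector regression (order 2,
# epsilon 0.0282, box constraint 0.0049, 30% holdout) and the median
# ensemble of ten 5-neuron Levenberg-Marquardt networks (per-member
# 70:15:15 splits, Nguyen-Widrow init, patience 20), then writes
# denormalized per-eye predictions for the verification set and the
# training reports. Re-derives the preparation deterministically from the
# same master seed, so stages stay consistent.
#
# Usage: Rscript analysis/03_train.R [--seed <int>]

suppressPackageStartupMessages(library(iolml))

args <- commandArgs(trailingOnly = TRUE)
seed <- 1L
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

cohort <- read_cohort_csv("results/cohort.csv")
prep <- prepare_cohort(cohort, seed = derive_seed(seed, "split"))

svm <- fit_svm_rm(prep$selection_norm,
                  svm_config(seed = derive_seed(seed, "svm")))
cat(sprintf("SVM-RM holdout MSE (normalized): %.5f\n", svm$holdout_mse))

mlnn <- fit_mlnn_em(prep$selection_norm,
                    mlnn_config(seed = derive_seed(seed, "mlnn")))
cat("MLNN-EM per-member MSE summary (normalized):\n")
print(round(mlnn$report$summary, 5))

pred <- data.frame(
  eye_id = prep$verification$eye_id,
  svm_rm = predict_iol(svm, prep$verification_norm, prep$normalizer),
  mlnn_em = predict_iol(mlnn, prep$verification_norm, prep$normalizer)
)
utils::write.csv(pred, "results/predictions.csv", row.names = FALSE)
utils::write.csv(mlnn$report$per_member, "results/mlnn_report.csv",
                 row.names = FALSE)
jsonlite::write_json(
  list(svm_holdout_mse = svm$holdout_mse,
       mlnn_summary = as.data.frame(mlnn$report$summary)),
  "results/training_report.json", auto_unbox = TRUE, digits = NA
)
cat(sprintf("wrote predictions for %d verification eyes\n", nrow(pred)))
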