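#!/usr/bin/env Rscript
# Stage 4: prediction-error evaluation and paired statistics.
#
# Back-calculates each model's residual refraction from its predicted lens
# power, summarizes prediction errors (ME/MAE/MedAE/SD/extremes, % within
# ±0.25/0.50/0.75/1.00 D) per axial-length subgroup (SHORT <= 22 mm,
# 22 < MEDIUM < 24, LONG >= 24) against the clinical baseline, and runs
# the paired-test battery (Wilcoxon on absolute errors; McNemar with
# Yates and the sign test per threshold; Bonferroni per subgroup table).
#
# Usage: Rscript analysis/04_evaluate.R [--seed <int>]

suppressPackageStartupMessages(library(iolml))

args <- commandArgs(trailingOnly = TRUE)
seed <- 1L
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

ver <- utils::read.csv("results/verification.csv", stringsAsFactors = FALSE)
pred <- utils::read.csv("results/predictions.csv", stringsAsFactors = FALSE)
stopifnot(identical(ver$eye_id, pred$eye_id))

err <- refractive_error_table(
  ver, list(`SVM-RM` = pred$svm_rm, `MLNN-EM` = pred$mlnn_em)
)
rep <- evaluation_report(err)
write_report(rep, "results/report")
utils::write.csv(err, "results/errors.csv", row.names = FALSE)

all_s <- rep$summaries[rep$summaries$subgroup == "ALL", ]
cat("ALL-eyes prediction errors:\n")
print(all_s, digits = 3, row.names = FALSE)
wt <- rep$tests[rep$tests$subgroup == "ALL" & rep$tests$test == "wilcoxon", ]
cat("\nWilcoxon (absolute errors), ALL group:\n")
print(wt[, c("comparison", "statistic", "p_value", "p_adjusted")],
      digits = 3, row.names = FALSE)
cat("\nfull tables under results/report/\n")
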