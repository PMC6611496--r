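#!/usr/bin/env Rscript
# Stage 2: clean the cohort and build the training tables.
#
# Applies the clinical inclusion/exclusion rules (ranges, acuity,
# astigmatism, keywords, fellow-eye AL concordance, 3-sigma outliers),
# derives the per-eye ideal lens power through the reversed vergence model
# (SRK/T ELP, A = 119.1), splits 70/30 into selection and verification,
# fits the [-1, 1] normalizer on the selection set and clears
# out-of-range verification eyes. Writes the exclusion report, both raw
# tables, and the normalizer parameters.
#
# Usage: Rscript analysis/02_prepare.R [--seed <int>]

suppressPackageStartupMessages(library(iolml))

args <- commandArgs(trailingOnly = TRUE)
seed <- 1L
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

cohort <- read_cohort_csv("results/cohort.csv")
prep <- prepare_cohort(cohort, seed = derive_seed(seed, "split"))

excl <- prep$cohort[!is.na(prep$cohort$exclusion_reason),
                    c("eye_id", "patient_id", "exclusion_reason")]
utils::write.csv(excl, "results/exclusions.csv", row.names = FALSE)
utils::write.csv(prep$selection, "results/selection.csv", row.names = FALSE)
utils::write.csv(prep$verification, "results/verification.csv",
                 row.names = FALSE)
jsonlite::write_json(
  list(variables = prep$normalizer$variables,
       min = as.list(prep$normalizer$min),
       max = as.list(prep$normalizer$max)),
  "results/normalizer.json", auto_unbox = TRUE, digits = NA
)

cat(sprintf("input %d eyes; excluded %d (%s)\n", nrow(prep$cohort), nrow(excl),
            paste(names(sort(table(excl$exclusion_reason), decreasing = TRUE)),
                  collapse = ", ")))
cat(sprintf("selection %d eyes, verification %d eyes (%d out of trained range)\n",
            nrow(prep$selection), nrow(prep$verification),
            nrow(prep$out_of_range)))
cat(sprintf("ideal lens power: mean %.2f D, SD %.2f D, range [%.2f, %.2f]\n",
            mean(prep$selection$iol_ideal_d), sd(prep$selection$iol_ideal_d),
            min(prep$selection$iol_ideal_d), max(prep$selection$iol_ideal_d)))
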