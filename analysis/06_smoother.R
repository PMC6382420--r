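#!/usr/bin/env Rscript
# Positional-smoothing caller: Gaussian 100-gene-window smoothing of the
# genomically ordered 1p and 19q expression, two-branch clustering of the
# concatenated profiles.

suppressPackageStartupMessages(library(codelcall))

d <- read_dataset("results/data/cohort")
am <- dataset_arm_map(d)
sp <- build_smoothed_profiles(d$expr, am, smooth_params(window = 100))
dir.create("results/smoother", recursive = TRUE, showWarnings = FALSE)
write_smoothed_profiles(sp, "results/smoother/smoothed_profiles.tsv")

calls <- call_by_smoothed_profile(sp)
ev <- run_evaluate(calls, d, out_dir = "results/smoother")
cat(sprintf("sens %.3f, spec %.3f, acc %.3f, AUC %.4f\n",
            ev$metrics$sensitivity, ev$metrics$specificity,
            ev$metrics$accuracy, ev$auc))
writeLines(dendrogram_newick(attr(calls, "tree")),
           "results/smoother/dendrogram.nwk")
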