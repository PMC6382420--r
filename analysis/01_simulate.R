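#!/usr/bin/env Rscript
# Build the simulated study cohorts every later analysis step reads.
#
# The main cohort mirrors the structure the callers assume: 300 samples with
# the training-cohort codeletion prevalence (172/692 ~ 24.9%), 150 genes on
# each of 1p and 19q carrying a one-copy-loss shift of -1 log2 unit in
# codeleted samples, 700 background genes, and residual noise sd 0.5.
# The transfer cohort adds a second batch with gene-wise offsets (sd 0.8),
# emulating a platform gap between two cohorts.

suppressPackageStartupMessages(library(codelcall))

main <- simulation_params(seed = 20190202)
cohort <- run_simulate(main, "results/data/cohort")
cat("main cohort:", ncol(cohort$expr), "samples,",
    sum(truth_labels(cohort) == "codeleted"), "codeleted\n")

transfer <- simulation_params(n_samples = 200, batch_shift_sd = 0.8,
                              n_batches = 2, seed = 20190203)
batch_cohort <- run_simulate(transfer, "results/data/cohort_two_batch")
cat("transfer cohort:", ncol(batch_cohort$expr), "samples in",
    nlevels(batch_cohort$batch), "batches\n")
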