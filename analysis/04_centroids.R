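#!/usr/bin/env Rscript
# Shrunken-centroid caller: cross-validated threshold curve, the selected
# sparse gene signature, and its composition.

suppressPackageStartupMessages(library(codelcall))

d <- read_dataset("results/data/cohort")
cv <- cv_threshold_curve(d, k = 10, seed = 20190202)
dir.create("results/pam", recursive = TRUE, showWarnings = FALSE)
write.table(cv$curve, "results/pam/cv_threshold_curve.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(cv)

model <- fit_nsc(d, delta = cv$best_delta)
write_model(model, "results/pam/model_nsc.json")
arm_frac <- mean(grepl("^G(1p|19q)_", model$selected_genes))
cat(sprintf("signature: %d genes, %.0f%% on 1p/19q\n",
            length(model$selected_genes), 100 * arm_frac))

pred <- predict_nsc(model, d$expr)
ev <- run_evaluate(pred, d, out_dir = "results/pam")
cat(sprintf("sens %.3f, spec %.3f, acc %.3f, AUC %.4f\n",
            ev$metrics$sensitivity, ev$metrics$specificity,
            ev$metrics$accuracy, ev$auc))
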