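#!/usr/bin/env Rscript
# PLS discriminant caller: 20% training split, component count chosen by
# stratified 10-fold CV on the training partition, evaluation on the held-out
# 80%.

suppressPackageStartupMessages(library(codelcall))

d <- read_dataset("results/data/cohort")
split <- holdout_split(d, train_frac = 0.2, seed = 20190202)
sel <- select_ncomp_cv(split$train, ncomp_grid = 1:15, k = 10,
                       seed = 20190202)
dir.create("results/plsda", recursive = TRUE, showWarnings = FALSE)
write.table(sel$table, "results/plsda/cv_ncomp_auc.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("selected ncomp = %d (CV AUC %.4f)\n", sel$best_ncomp,
            max(sel$table$mean_auc, na.rm = TRUE)))

model <- fit_plsda(split$train, ncomp = sel$best_ncomp)
write_model(model, "results/plsda/model_plsda.json")
pred <- predict_plsda(model, split$test$expr)
ev <- run_evaluate(pred, truth_labels(split$test), out_dir = "results/plsda")
cat(sprintf("held-out: sens %.3f, spec %.3f, acc %.3f, AUC %.4f\n",
            ev$metrics$sensitivity, ev$metrics$specificity,
            ev$metrics$accuracy, ev$auc))
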