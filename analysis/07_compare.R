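#!/usr/bin/env Rscript
# The five-method comparison on one fixed sample set: per-method
# sensitivity/specificity/accuracy/AUC, and the overlap of the
# predicted-codeleted sample sets.

suppressPackageStartupMessages(library(codelcall))

d <- read_dataset("results/data/cohort")
report <- run_compare(d, out_dir = "results/compare",
                      config = list(seed = 20190202))
print(report)
cat("samples called codeleted by all five methods:",
    report$overlap$all_methods, "\n")
cat("samples called codeleted by at least one method:",
    report$overlap$any_method, "\n")
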