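#!/usr/bin/env Rscript
# Consolidated report: rerun the recovery benchmark at the standard study
# conditions and aggregate with the composition worked example into one
# JSON document.
source("analysis/00_config.R")

bm <- run_benchmark(seed = SEED)
cat("benchmark: recall", bm$recall, ", precision", bm$precision,
    ",", bm$n_false_pav, "false calls, direction labels",
    ifelse(bm$direction_labels_correct, "correct", "NOT correct"), "\n")

report <- run_report(
  bins = bm$bins,
  composition = composition_reconcile(146e6, 117e6, 4e6),
  benchmark = bm,
  path = file.path(OUT, "report.json"))
cat("report written to", file.path(OUT, "report.json"), "\n")
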