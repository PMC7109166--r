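#!/usr/bin/env Rscript
# Diagnostic metrics recomputed from the study's published cross-
# classification tables (the one directly checkable published quantity: the
# raw per-sample data behind them is not public).
#
# 26-variant analysis: TP=37 FN=2 FP=7 TN=21
# 18-gene analysis:    TP=25 FN=14 FP=4 TN=24

library(mutcva)

dir.create("results", showWarnings = FALSE)

tables <- list(
  variants_26 = c(tp = 37, fn = 2, fp = 7, tn = 21),
  genes_18 = c(tp = 25, fn = 14, fp = 4, tn = 24))

rows <- lapply(names(tables), function(nm) {
  ct <- tables[[nm]]
  m <- diagnostic_metrics(ct["tp"], ct["fn"], ct["fp"], ct["tn"])
  data.frame(analysis = nm, t(ct),
             sensitivity = m$sensitivity, specificity = m$specificity,
             ppv = m$ppv, npv = m$npv)
})
out <- do.call(rbind, rows)
print(out, row.names = FALSE, digits = 3)
utils::write.table(format(out, digits = 4), "results/published_metrics.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
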