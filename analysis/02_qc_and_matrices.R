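#!/usr/bin/env Rscript
# Variant QC, matched-pair germline subtraction, and mutation matrices.
#
# Retention rules: depth >= 5 reads, support on both strands, population
# frequency <= 1%. Variants present in both members of a matched pair are
# presumed germline and removed from both. The surviving calls become the
# binary variants x samples incidence matrix (reduced to variants occurring
# at least 3 times, pooled over groups) and the genes x samples count matrix.

library(mutcva)

dir.create("results/matrices", showWarnings = FALSE, recursive = TRUE)

cohort <- cohort_calls(read_sample_sheet("results/data/samples.csv"),
                       read_variant_calls("results/data/calls.tsv", "tsv"))
cohort <- apply_qc_filters(cohort, filter_config())
cohort <- subtract_paired_germline(cohort)
cat(paste0(cohort$provenance, collapse = "\n"), "\n")

vm <- build_variant_matrix(cohort)
vm_red <- prevalence_filter(vm, 3)
gm <- build_gene_matrix(cohort)
write_matrix_tsv(vm, "results/matrices/variants_full.tsv")
write_matrix_tsv(vm_red, "results/matrices/variants_min3.tsv")
write_matrix_tsv(gm, "results/matrices/genes.tsv")

cat(sprintf("variant matrix: %d x %d; after >=3-occurrence reduction: %d x %d; gene matrix: %d x %d\n",
            nrow(vm$values), ncol(vm$values),
            nrow(vm_red$values), ncol(vm_red$values),
            nrow(gm$values), ncol(gm$values)))

st <- density_stats(vm, marker = "BRAF:c.1799T>A")
cat(sprintf("tumor mutation density: mean %.2f (range %d-%d)\n",
            st$amd_tumor, st$amd_range[1], st$amd_range[2]))
cat(sprintf("density by BRAF V600E status: carriers %.2f, non-carriers %.2f\n",
            st$amd_conditional["present"], st$amd_conditional["absent"]))
cat(sprintf("total events: %d tumor, %d tumor-free\n",
            st$tumor_total_events, st$normal_total_events))
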