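# Fixture builders and independent oracles shared across the suite.

# One-way ANOVA F via R's linear-model machinery; independent of the
# package's own arithmetic.
f_oracle <- function(x, g) {
  stats::anova(stats::lm(x ~ factor(g)))[["F value"]][1]
}

# Two-group LDA direction from MASS, used only as a cross-check.
lda_scores_oracle <- function(x, groups) {
  fit <- MASS::lda(t(x), grouping = factor(groups))
  drop(t(x) %*% fit$scaling[, 1])
}

make_samples <- function(n_tumor = 2, n_normal = 2, n_pairs = 0) {
  tumors <- data.frame(
    sample_id = sprintf("T%02d", seq_len(n_tumor)),
    patient_id = sprintf("PT%02d", seq_len(n_tumor)),
    status = "tumor",
    pair_id = c(if (n_pairs > 0) sprintf("P%02d", seq_len(n_pairs)),
                rep(NA_character_, n_tumor - n_pairs)),
    histology = "classical", stringsAsFactors = FALSE)
  normals <- data.frame(
    sample_id = sprintf("N%02d", seq_len(n_normal)),
    patient_id = sprintf("PT%02d", n_tumor + seq_len(n_normal)),
    status = "tumor_free",
    pair_id = c(if (n_pairs > 0) sprintf("P%02d", seq_len(n_pairs)),
                rep(NA_character_, n_normal - n_pairs)),
    histology = "none", stringsAsFactors = FALSE)
  if (n_pairs > 0) {
    normals$patient_id[seq_len(n_pairs)] <- tumors$patient_id[seq_len(n_pairs)]
  }
  rbind(tumors, normals)
}

make_call <- function(sample_id, gene = "BRAF", hgvs_c = "c.1799T>A",
                      depth = 100L, on_forward = TRUE, on_reverse = TRUE,
                      pop_af = 0, variant_class = "missense") {
  data.frame(sample_id = sample_id, gene = gene, hgvs_c = hgvs_c,
             depth = as.integer(depth), on_forward = on_forward,
             on_reverse = on_reverse, pop_af = pop_af,
             variant_class = variant_class, stringsAsFactors = FALSE)
}

make_cohort <- function(calls, n_tumor = 2, n_normal = 2, n_pairs = 0) {
  cohort_calls(make_samples(n_tumor, n_normal, n_pairs), calls)
}

# A random cohort whose QC evidence is a deterministic function of the
# variant key (identical in every carrier), so QC filtering and pair
# subtraction commute by construction: a pair-shared call passes or fails QC
# in both members together.
random_clean_cohort <- function(seed, n_tumor = 6, n_normal = 6, n_pairs = 4,
                                n_variants = 8) {
  set.seed(seed)
  samples <- make_samples(n_tumor, n_normal, n_pairs)
  keys <- data.frame(gene = sample(c("BRAF", "APC", "TSHR", "LPAR4"),
                                   n_variants, replace = TRUE),
                     hgvs_c = sprintf("c.%dA>G", 100 + seq_len(n_variants)))
  depth_by_key <- 5L + (seq_len(n_variants) * 7L) %% 50L
  rows <- list()
  for (s in samples$sample_id) {
    carried <- which(runif(n_variants) < 0.35)
    for (k in carried) {
      rows[[length(rows) + 1]] <- make_call(
        s, keys$gene[k], keys$hgvs_c[k],
        depth = depth_by_key[k], pop_af = 0)
    }
  }
  cohort_calls(samples, do.call(rbind, rows))
}

write_mini_vcf <- function(path, sample = "S1", dp = "4",
                           info_extra = "AF=0;SAF=2;SAR=2;GENE=BRAF;HGVSC=c.1799T>A") {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Population allele frequency">',
    '##INFO=<ID=SAF,Number=1,Type=Integer,Description="Alt reads forward">',
    '##INFO=<ID=SAR,Number=1,Type=Integer,Description="Alt reads reverse">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=HGVSC,Number=1,Type=String,Description="HGVS coding">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"),
    paste(c("7", "140453136", ".", "A", "T", "50", "PASS",
            paste0("DP=", dp, ";", info_extra), "GT", "0/1"), collapse = "\t"))
  writeLines(lines, path)
  path
}
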