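test_that("generation is bit-identical for a fixed template and seed", {
  t <- study_template(seed = 31)
  a <- generate_cohort(t)
  b <- generate_cohort(t)
  expect_identical(a$samples, b$samples)
  expect_identical(a$calls, b$calls)
  c2 <- generate_cohort(t, seed = 32)
  expect_false(identical(a$calls, c2$calls))
})

test_that("the study template encodes the cohort composition", {
  t <- study_template()
  expect_equal(c(t$n_tumor, t$n_normal, t$n_pairs), c(39L, 28L, 27L))
  # anchor prevalences
  keys <- variant_key(t$variants$gene, t$variants$hgvs_c)
  expect_equal(t$variants$p_tumor[keys == "BRAF:c.1799T>A"], 13 / 39)
  expect_equal(t$variants$p_normal[keys == "BRAF:c.1799T>A"], 0)
  expect_equal(t$variants$p_normal[keys == "LPAR4:c.137A>G"], 4 / 28)
  expect_equal(t$variants$p_tumor[keys == "LPAR4:c.137A>G"], 0)
  # 18 genes, sparse spectrum, tumor-free density about a third of tumors
  expect_equal(length(unique(t$variants$gene)), 18)
  dens <- expected_mutation_density(t)
  expect_gte(dens["tumor"], 2.0)
  expect_lte(dens["tumor"], 3.1)
  expect_lt(dens["normal"] / dens["tumor"], 0.4)

  # generated sample sheet: 27 pairs, 40 patients, histology spread
  co <- generate_cohort(t)
  expect_equal(length(unique(co$samples$patient_id)), 40)
  expect_equal(sum(co$samples$histology == "classical"), 24)
  expect_silent(validate_sample_sheet <- cohort_calls(co$samples, co$calls))
})

test_that("a perfectly separable template classifies the training set exactly", {
  vars <- data.frame(gene = "BRAF", hgvs_c = "c.1799T>A", p_tumor = 1,
                     p_normal = 0, variant_class = "missense",
                     stringsAsFactors = FALSE)
  t <- cohort_template(n_tumor = 10, n_normal = 10, n_pairs = 5,
                       variants = vars, seed = 5)
  rep <- run_pipeline(generate_cohort(t),
                      pipeline_config(min_count = 1, r_threshold = 0.1))
  expect_equal(rep$metrics$sensitivity, 1)
  expect_equal(rep$metrics$specificity, 1)
})

test_that("QC noise knobs reach the retention rules", {
  t <- study_template(seed = 17)
  t$qc_model$p_common_popaf <- 1
  co <- generate_cohort(t)
  expect_gt(nrow(co$calls), 0)
  expect_equal(nrow(apply_qc_filters(co)$calls), 0)  # everything common

  t$qc_model <- list(depth_mean = 642, depth_min = 1, p_single_strand = 1,
                     p_common_popaf = 0)
  co2 <- generate_cohort(t)
  expect_true(all(xor(co2$calls$on_forward, co2$calls$on_reverse)))
  expect_equal(nrow(apply_qc_filters(co2)$calls), 0)
})

test_that("pair-shared germline variants are injected symmetrically", {
  t <- study_template(seed = 23)
  t$germline_shared$p_pair <- 1
  co <- generate_cohort(t)
  keys <- variant_key(co$calls$gene, co$calls$hgvs_c)
  shared <- co$calls[keys == "AXIN1:c.2306A>G", ]
  # every one of the 27 pairs carries it in both members
  expect_equal(nrow(shared), 2 * 27)
  after <- subtract_paired_germline(co)
  keys_after <- variant_key(after$calls$gene, after$calls$hgvs_c)
  expect_false("AXIN1:c.2306A>G" %in% keys_after)
})

test_that("prevalence recovery stays within binomial sampling error", {
  t <- study_template(seed = 41)
  out <- prevalence_recovery_check(t, n_reps = 25)
  # impossible variants never occur
  expect_true(all(out$observed[out$p == 0] == 0))
  expect_false(any(out$flag[out$p == 0]))
  # the large-count anchors sit inside their 99% intervals at 25 reps
  anchors <- out[out$gene == "BRAF" & out$hgvs_c == "c.1799T>A" &
                   out$group == "tumor", ]
  expect_false(anchors$flag)
  # a single replicate gives wide intervals and no crash
  out1 <- prevalence_recovery_check(t, n_reps = 1)
  expect_equal(nrow(out1), 2 * nrow(t$variants))
})

test_that("rate heterogeneity and exclusivity groups shape the draws", {
  t <- study_template(seed = 51)
  t$rate_sigma <- 0.8
  expect_silent(co <- generate_cohort(t))
  expect_gt(nrow(co$calls), 0)

  vars <- data.frame(gene = c("BRAF", "NRAS"), hgvs_c = c("c.1", "c.2"),
                     p_tumor = c(1, 1), p_normal = 0,
                     variant_class = "missense", stringsAsFactors = FALSE)
  t2 <- cohort_template(n_tumor = 12, n_normal = 3, n_pairs = 0,
                        variants = vars,
                        exclusivity_groups = list(c("BRAF", "NRAS")), seed = 6)
  co2 <- generate_cohort(t2)
  per_sample <- table(co2$calls$sample_id)
  expect_true(all(per_sample <= 1))  # never both genes in one sample
})

test_that("templates survive a YAML round trip", {
  t <- study_template(seed = 61)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_template_yaml(t, path)
  t2 <- read_template_yaml(path)
  expect_equal(t2$n_tumor, t$n_tumor)
  expect_equal(t2$variants$p_tumor, t$variants$p_tumor)
  expect_identical(generate_cohort(t2)$calls, generate_cohort(t)$calls)
})
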