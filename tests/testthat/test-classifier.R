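make_fit <- function(r_values, f_values = NULL) {
  # minimal cva_fit stub for selection/risk arithmetic
  p <- length(r_values)
  ids <- sprintf("G%d:c.%d", seq_len(p), seq_len(p))
  if (is.null(f_values)) f_values <- abs(r_values) * 10
  structure(list(variable_ids = ids,
                 weights = stats::setNames(rep(1, p), ids),
                 coefficients = stats::setNames(rep(1, p), ids),
                 intercept = 0,
                 scores = numeric(),
                 f_ratios = stats::setNames(f_values, ids),
                 correlations = stats::setNames(r_values, ids),
                 group_means = c(tumor = 1, tumor_free = -1),
                 ridge_used = 0, positive = "tumor",
                 groups = character()),
            class = "cva_fit")
}

test_that("indicator selection thresholds |r| and tags direction", {
  fit <- make_fit(c(0.5, -0.3, 0.1))
  sel <- select_indicators(fit, 0.136)
  expect_equal(nrow(sel), 2)
  expect_setequal(sel$direction, c("RISK", "PROTECTIVE"))
  expect_equal(sel$direction[sel$r > 0], "RISK")
  expect_equal(sel$variable_id, sel$variable_id[order(-sel$f)])  # F-descending
  expect_equal(nrow(select_indicators(fit, 1.0)), 0)
})

test_that("F-sum risk score is a signed, capped, presence-weighted sum", {
  fit <- make_fit(c(0.8, -0.6), f_values = c(2, 3))
  sel <- select_indicators(fit, 0.1)
  # all-zero profile
  expect_equal(risk_score(c(0, 0), sel), 0)
  # one RISK and one PROTECTIVE carried: +2 - 3
  prof <- stats::setNames(c(1, 1), fit$variable_ids)
  expect_equal(risk_score(prof, sel), -1)
  expect_equal(risk_score(prof, sel, sign_mode = "unsigned"), 5)
  expect_equal(risk_score(prof, sel, sign_mode = "positive_only"), 2)
  # counts > 1 are presence, not multiplicity
  expect_equal(risk_score(stats::setNames(c(3, 0), fit$variable_ids), sel), 2)
  expect_error(risk_score(c(1, 1, 1), sel), "length")

  # a single carried RISK variable returns its own F
  fit2 <- make_fit(0.9, f_values = 60970 / 4489)
  sel2 <- select_indicators(fit2, 0.136)
  expect_equal(risk_score(stats::setNames(1, fit2$variable_ids), sel2),
               60970 / 4489)

  # infinite F enters at the cap
  fit3 <- make_fit(0.9, f_values = Inf)
  sel3 <- select_indicators(fit3, 0.1)
  expect_equal(risk_score(stats::setNames(1, fit3$variable_ids), sel3,
                          f_cap = 1e4), 1e4)
})

test_that("adding a zero-F variable never changes a risk score", {
  fit <- make_fit(c(0.8, -0.5, 0.4), f_values = c(5, 2, 0))
  sel <- select_indicators(fit, 0.1)
  sel_no_zero <- sel[sel$f > 0, , drop = FALSE]
  set.seed(3)
  for (i in 1:10) {
    prof <- stats::setNames(rbinom(3, 1, 0.5), fit$variable_ids)
    expect_equal(risk_score(prof, sel), risk_score(prof, sel_no_zero))
  }
})

test_that("diagnostic metrics satisfy the 2x2 identities exactly", {
  set.seed(21)
  for (i in 1:20) {
    ct <- as.list(rmultinom(1, 60, c(0.4, 0.1, 0.1, 0.4))[, 1])
    names(ct) <- c("tp", "fn", "fp", "tn")
    m <- diagnostic_metrics(ct$tp, ct$fn, ct$fp, ct$tn)
    if (ct$tp + ct$fn > 0) expect_equal(m$sensitivity, ct$tp / (ct$tp + ct$fn))
    if (ct$fp + ct$tn > 0) expect_equal(m$specificity, ct$tn / (ct$fp + ct$tn))
    if (ct$tp + ct$fp > 0) expect_equal(m$ppv, ct$tp / (ct$tp + ct$fp))
    if (ct$tn + ct$fn > 0) expect_equal(m$npv, ct$tn / (ct$tn + ct$fn))
    for (v in unlist(m)) if (!is.na(v)) expect_true(v >= 0 && v <= 1)
  }
})

test_that("classification uses the zero-profile cutoff with <= tumor-free", {
  # perfect single-variant separation: everyone classified correctly
  calls <- rbind(make_call("T01"), make_call("T02"))
  co <- make_cohort(calls, n_tumor = 2, n_normal = 2)
  m <- build_variant_matrix(co)
  fit <- fit_cva(m)
  rep <- classify(fit, m, r_threshold = 0.1)
  expect_equal(unname(rep$contingency), c(2L, 0L, 0L, 2L))
  expect_equal(rep$metrics$sensitivity, 1)
  expect_equal(rep$metrics$specificity, 1)
  # contingency margins equal the group sizes
  expect_equal(sum(rep$contingency[c("tp", "fn")]), 2)
  expect_equal(sum(rep$contingency[c("fp", "tn")]), 2)

  # mutation-free samples sit exactly at the cutoff and are called tumor-free
  zero_scores <- rep$scores$score[rep$scores$sample_id %in% c("N01", "N02")]
  expect_equal(zero_scores, rep(rep$cutoff, 2), tolerance = 1e-10)
  expect_equal(rep$scores$assignment[rep$scores$sample_id %in% c("N01", "N02")],
               rep("TUMOR_FREE", 2))
})

test_that("risk scores rank in the same direction as axis scores", {
  for (seed in c(2, 4, 6)) {
    co <- generate_cohort(study_template(seed = seed))
    m <- prevalence_filter(build_variant_matrix(subtract_paired_germline(
      apply_qc_filters(co))), 3)
    fit <- fit_cva(m)
    rep <- classify(fit, m, r_threshold = 0.136)
    expect_gt(sum(rep$selected$direction == "RISK"), 0)
    expect_gt(stats::cor(rep$scores$risk_score, rep$scores$score,
                         method = "spearman"), 0)
  }
})

test_that("a dominant tumor variant among balanced noise recovers the groups", {
  # one variant in 80% of tumors and no normals, plus sparse group-balanced
  # noise at hotspot-panel-like carriage rates: any noise a sample carries is
  # pure nuisance signal for the zero-mutation cutoff
  noise <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(gene = "NOISE", hgvs_c = sprintf("c.%d", i),
               p_tumor = 0.1, p_normal = 0.1, variant_class = "missense",
               stringsAsFactors = FALSE)
  }))
  vars <- rbind(
    data.frame(gene = "BRAF", hgvs_c = "c.1799T>A", p_tumor = 0.8,
               p_normal = 0, variant_class = "missense",
               stringsAsFactors = FALSE),
    noise)
  sens <- spec <- numeric(20)
  for (i in 1:20) {
    t <- cohort_template(n_tumor = 20, n_normal = 20, n_pairs = 0,
                         variants = vars, seed = 1000 + i)
    co <- generate_cohort(t)
    m <- build_variant_matrix(co)
    fit <- fit_cva(m)
    rep <- classify(fit, m, r_threshold = 0.2)
    sens[i] <- rep$metrics$sensitivity
    spec[i] <- rep$metrics$specificity
  }
  expect_gte(mean(sens), 0.75)
  expect_gte(mean(spec), 0.75)
})
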