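test_that("univariate F matches hand-derived ANOVA values", {
  g4 <- c("tumor", "tumor", "tumor_free", "tumor_free")
  # constant variable: no between-group variance
  expect_equal(univariate_f(c(1, 1, 1, 1), g4), 0)
  # hand ANOVA: SSB = 0.25, SSW = 0.5, df = (1, 2) -> F = 1
  expect_equal(univariate_f(c(1, 1, 1, 0), g4), 1.0)
  # perfect separator: SSW = 0, SSB > 0
  expect_identical(univariate_f(c(1, 1, 0, 0), g4), Inf)
  # a variant in 13/39 tumors and 0/28 normals: F = 60970/4489
  x <- c(rep(1, 13), rep(0, 26), rep(0, 28))
  g <- c(rep("tumor", 39), rep("tumor_free", 28))
  expect_equal(univariate_f(x, g), 60970 / 4489, tolerance = 1e-12)
  expect_equal(univariate_f(x, g), f_oracle(x, g), tolerance = 1e-12)

  expect_error(univariate_f(c(1, 0, 1), c("a", "a", "a")), "two nonempty")
})

test_that("univariate F equals the squared equal-variance t statistic", {
  set.seed(42)
  for (i in 1:10) {
    g <- c(rep("tumor", 8), rep("tumor_free", 7))
    x <- rnorm(15) + (g == "tumor") * runif(1, 0, 2)
    tt <- t.test(x[g == "tumor"], x[g == "tumor_free"], var.equal = TRUE)
    expect_equal(univariate_f(x, g), unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("univariate F agrees with the linear-model ANOVA oracle", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    n1 <- sample(2:(n - 2), 1)
    g <- c(rep("tumor", n1), rep("tumor_free", n - n1))
    x <- if (runif(1) < 0.5) rnorm(n) else rbinom(n, 1, runif(1, 0.2, 0.8))
    if (stats::sd(x) == 0) next  # lm() is numerically unreliable on a constant
    f_ref <- suppressWarnings(f_oracle(x, g))
    f_own <- univariate_f(x, g)
    if (is.finite(f_own) && is.finite(f_ref)) {
      expect_equal(f_own, f_ref, tolerance = 1e-10)
    }
  }
})

test_that("a single separating variable yields |r| = 1 with tumor scored high", {
  x <- matrix(c(1, 1, 0, 0), nrow = 1,
              dimnames = list("v", c("T1", "T2", "N1", "N2")))
  g <- c("tumor", "tumor", "tumor_free", "tumor_free")
  fit <- fit_cva(x, groups = g)
  expect_equal(abs(unname(fit$correlations)), 1, tolerance = 1e-12)
  expect_gt(fit$group_means["tumor"], fit$group_means["tumor_free"])
  expect_identical(unname(fit$f_ratios), Inf)
})

test_that("duplicated variables add no information to the fit", {
  set.seed(7)
  g <- c(rep("tumor", 6), rep("tumor_free", 6))
  row <- rbinom(12, 1, 0.5 + 0.3 * (g == "tumor"))
  x1 <- matrix(row, nrow = 1, dimnames = list("v1", paste0("s", 1:12)))
  x2 <- rbind(x1, v2 = row)
  fit1 <- fit_cva(x1, groups = g)
  fit2 <- fit_cva(x2, groups = g)
  expect_equal(unname(fit2$correlations["v1"]),
               unname(fit2$correlations["v2"]), tolerance = 1e-10)
  expect_equal(unname(fit2$scores), unname(fit1$scores), tolerance = 1e-4)
})

test_that("constant rows are handled: F = 0, r = 0, fit succeeds", {
  set.seed(8)
  g <- c(rep("tumor", 5), rep("tumor_free", 5))
  x <- rbind(sig = rbinom(10, 1, 0.5 + 0.4 * (g == "tumor")),
             flat = rep(1, 10))
  colnames(x) <- paste0("s", 1:10)
  fit <- fit_cva(x, groups = g)
  expect_equal(unname(fit$f_ratios["flat"]), 0)
  expect_equal(unname(fit$correlations["flat"]), 0)
  expect_true(is.finite(fit$weights["flat"]))
})

test_that("score convention holds: tumor high, unit pooled within-variance", {
  set.seed(9)
  for (i in 1:5) {
    g <- c(rep("tumor", 10), rep("tumor_free", 8))
    x <- matrix(rnorm(5 * 18, mean = rep((g == "tumor") * 0.8, each = 5)),
                nrow = 5)
    fit <- fit_cva(x, groups = g)
    expect_gt(fit$group_means["tumor"], fit$group_means["tumor_free"])
    s <- fit$scores
    ssw <- sum((s[g == "tumor"] - mean(s[g == "tumor"]))^2) +
      sum((s[g == "tumor_free"] - mean(s[g == "tumor_free"]))^2)
    expect_equal(ssw / (18 - 2), 1, tolerance = 1e-8)
    expect_equal(mean(s), 0, tolerance = 1e-10)
  }
})

test_that("scores match the generic two-group LDA projection up to affine map", {
  set.seed(10)
  for (i in 1:10) {
    n1 <- sample(6:10, 1); n2 <- sample(6:10, 1)
    g <- c(rep("tumor", n1), rep("tumor_free", n2))
    p <- sample(2:5, 1)
    x <- matrix(rnorm(p * (n1 + n2), mean = rep((g == "tumor"), each = p)),
                nrow = p)
    fit <- fit_cva(x, groups = g)
    ref <- lda_scores_oracle(x, g)
    expect_gt(abs(stats::cor(fit$scores, ref)), 0.9999)
  }
})

test_that("scores are invariant under variable rescaling as ridge vanishes", {
  set.seed(11)
  g <- c(rep("tumor", 8), rep("tumor_free", 8))
  x <- matrix(rnorm(4 * 16, mean = rep((g == "tumor") * 0.6, each = 4)),
              nrow = 4)
  x2 <- x
  x2[2, ] <- x2[2, ] * 10
  fit <- fit_cva(x, groups = g, ridge = 1e-12)
  fit2 <- fit_cva(x2, groups = g, ridge = 1e-12)
  expect_equal(unname(fit2$scores), unname(fit$scores), tolerance = 1e-6)
})

test_that("profile scoring is consistent with training scores and linear", {
  co <- generate_cohort(study_template(seed = 5))
  m <- prevalence_filter(build_variant_matrix(apply_qc_filters(co)), 3)
  fit <- fit_cva(m)
  # a training column reproduces its own score
  j <- 4
  prof <- stats::setNames(m$values[, j], rownames(m$values))
  expect_equal(score_profile(fit, prof), unname(fit$scores[j]),
               tolerance = 1e-10)
  # the tumor mean profile scores at the tumor mean score
  tumor_mean <- rowMeans(m$values[, m$labels == "tumor", drop = FALSE])
  expect_equal(score_profile(fit, tumor_mean),
               unname(fit$group_means["tumor"]), tolerance = 1e-10)
  expect_error(score_profile(fit, rep(0, nrow(m$values) + 1)), "length")
})

test_that("label permutation collapses the maximal F-ratio", {
  co <- generate_cohort(study_template(seed = 12))
  m <- prevalence_filter(build_variant_matrix(co), 3)
  labels <- unname(m$labels)
  obs_max <- max(apply(m$values, 1, univariate_f, labels = labels))
  set.seed(99)
  perm_max <- replicate(99, {
    max(apply(m$values, 1, univariate_f, labels = sample(labels)))
  })
  expect_lt(mean(perm_max >= obs_max), 0.05)
})
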