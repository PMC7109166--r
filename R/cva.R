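# Two-group canonical variates analysis (Fisher discriminant), from first
# principles.
#
# With two groups there is a single canonical variate: the linear combination
# w'x maximizing the ratio of between-group to within-group variance, i.e.
# w proportional to W^+ (mu_T - mu_N) where W is the pooled within-group
# covariance matrix. Sparse binary mutation data routinely make W singular
# (a variant absent from one group contributes no within-variance there), so
# W is ridge-stabilized: W + lambda I with lambda = 1e-6 * trace(W)/p by
# default; lambda is reported in the fit. Scores follow a fixed convention --
# tumor group high, pooled within-group variance 1, overall mean 0 -- because
# the absolute placement of the axis is otherwise arbitrary; only
# affine-invariant quantities (F-ratios, correlations, classifications) are
# comparable across implementations.

#' Univariate F-ratio (one-way ANOVA) for a single variable
#'
#' `F = [sum_g n_g (xbar_g - xbar)^2 / 1] / [SSW / (n - 2)]` with degrees of
#' freedom (1, n-2). A variable constant overall has no between-group
#' variance and returns 0; a perfect separator (within-group sum of squares 0,
#' between > 0) returns `Inf`.
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Group label per sample; exactly the two status levels, each
#'   nonempty.
#' @return A nonnegative scalar, possibly `Inf`.
#' @export
univariate_f <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2 || any(table(labels) == 0)) {
    stop("univariate_f requires exactly two nonempty groups")
  }
  n <- length(values)
  if (n < 3) stop("univariate_f requires n >= 3")
  grand <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    xg <- values[labels == g]
    ssb <- ssb + length(xg) * (mean(xg) - grand)^2
    ssw <- ssw + sum((xg - mean(xg))^2)
  }
  tol <- 1e-12 * max(1, sum((values - grand)^2))
  if (ssb <= tol) return(0)
  if (ssw <= tol) return(Inf)
  ssb / (ssw / (n - 2))
}

#' Fit a two-group canonical variates analysis
#'
#' Accepts a [mutation_matrix()] (variables in rows, samples in columns,
#' labels attached) or a plain numeric matrix with an explicit `groups`
#' vector. Returns the single canonical axis, per-sample scores under the
#' package's score convention, per-variable F-ratios and structure
#' correlations (Pearson r between each variable and the scores; 0 for a
#' constant variable).
#'
#' @param x A `mutation_matrix`, or a numeric matrix with variables in rows
#'   and samples in columns.
#' @param groups Group label per sample (required when `x` is a plain
#'   matrix); exactly two levels.
#' @param positive The group scored high on the axis (default `"tumor"`; for
#'   a plain matrix with other labels, the first label encountered).
#' @param ridge Ridge constant added to the diagonal of the pooled
#'   within-group covariance; default `1e-6 * trace(W)/p`.
#' @param standardize `"none"` (default) or `"unit_variance"` (scale each
#'   variable to unit overall variance before fitting).
#' @return A `cva_fit` with elements `variable_ids`, `weights` (raw
#'   discriminant direction), `coefficients` and `intercept` (the affine
#'   score map), `scores`, `f_ratios`, `correlations`, `group_means`,
#'   `ridge_used`, `positive`, `groups`.
#' @export
fit_cva <- function(x, groups = NULL, positive = NULL, ridge = NULL,
                    standardize = c("none", "unit_variance")) {
  standardize <- match.arg(standardize)
  if (inherits(x, "mutation_matrix")) {
    groups <- unname(x$labels)
    x <- x$values
    storage.mode(x) <- "double"
    if (is.null(positive)) positive <- "tumor"
  } else {
    stopifnot(is.matrix(x), !is.null(groups))
    groups <- as.character(groups)
    if (is.null(positive)) {
      positive <- if ("tumor" %in% groups) "tumor" else groups[1]
    }
  }
  if (nrow(x) < 1) stop("fit_cva requires at least one variable")
  lev <- unique(groups)
  if (length(lev) != 2 || !positive %in% lev) {
    stop("fit_cva requires exactly two groups including the positive one")
  }
  pos <- groups == positive
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop("fit_cva requires at least 2 samples per group")
  }
  n <- ncol(x)
  p <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("v", seq_len(p))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(n))

  if (standardize == "unit_variance") {
    sds <- apply(x, 1, stats::sd)
    sds[sds == 0] <- 1
    x <- x / sds
  }

  mu_pos <- rowMeans(x[, pos, drop = FALSE])
  mu_neg <- rowMeans(x[, !pos, drop = FALSE])
  d <- mu_pos - mu_neg
  xc <- x
  xc[, pos] <- xc[, pos, drop = FALSE] - mu_pos
  xc[, !pos] <- xc[, !pos, drop = FALSE] - mu_neg
  w_mat <- tcrossprod(xc) / (n - 2)
  if (is.null(ridge)) {
    tr <- sum(diag(w_mat))
    ridge <- if (tr > 0) 1e-6 * tr / p else 1e-6
  }
  w <- drop(solve(w_mat + diag(ridge, p), d))

  raw <- drop(crossprod(x, w))
  ssw_raw <- sum((raw[pos] - mean(raw[pos]))^2) +
    sum((raw[!pos] - mean(raw[!pos]))^2)
  s2 <- ssw_raw / (n - 2)
  scale_f <- if (s2 > 1e-24) {
    1 / sqrt(s2)
  } else if (stats::sd(raw) > 0) {
    # degenerate: perfect within-group collapse; fall back to total sd
    1 / stats::sd(raw)
  } else 1
  if (mean(raw[pos]) < mean(raw[!pos])) scale_f <- -scale_f
  coefficients <- w * scale_f
  intercept <- -mean(raw) * scale_f
  scores <- raw * scale_f + intercept
  names(scores) <- colnames(x)

  labels2 <- ifelse(pos, positive, setdiff(lev, positive))
  f_ratios <- apply(x, 1, univariate_f, labels = labels2)
  correlations <- apply(x, 1, function(row) {
    if (stats::sd(row) == 0 || stats::sd(scores) == 0) 0 else
      stats::cor(row, scores)
  })

  structure(list(
    variable_ids = rownames(x),
    weights = stats::setNames(w, rownames(x)),
    coefficients = stats::setNames(coefficients, rownames(x)),
    intercept = intercept,
    scores = scores,
    f_ratios = stats::setNames(f_ratios, rownames(x)),
    correlations = stats::setNames(correlations, rownames(x)),
    group_means = c(
      stats::setNames(mean(scores[pos]), positive),
      stats::setNames(mean(scores[!pos]), setdiff(lev, positive))),
    ridge_used = ridge,
    positive = positive,
    groups = stats::setNames(labels2, colnames(x))
  ), class = "cva_fit")
}

#' @export
print.cva_fit <- function(x, ...) {
  cat(sprintf("<cva_fit> %d variables, %d samples; group means %s=%.3f, %s=%.3f; ridge=%.3g\n",
              length(x$variable_ids), length(x$scores),
              names(x$group_means)[1], x$group_means[1],
              names(x$group_means)[2], x$group_means[2], x$ridge_used))
  invisible(x)
}

#' Score a new mutation profile on the fitted canonical axis
#'
#' Applies the same affine map as the training scores, so a profile equal to
#' a training sample's column reproduces that sample's score, and the
#' all-zero profile gives the zero-mutation score used as the classification
#' cutoff.
#'
#' @param fit A `cva_fit`.
#' @param profile Numeric vector over `fit$variable_ids` (0/1 or counts). If
#'   named, it is reordered to match; otherwise positional, and its length
#'   must match.
#' @return The profile's scalar position on the canonical axis.
#' @export
score_profile <- function(fit, profile) {
  stopifnot(inherits(fit, "cva_fit"))
  if (!is.null(names(profile))) {
    if (!setequal(names(profile), fit$variable_ids)) {
      stop("profile names do not match the fitted variable ids")
    }
    profile <- profile[fit$variable_ids]
  } else if (length(profile) != length(fit$variable_ids)) {
    stop("profile length ", length(profile), " does not match ",
         length(fit$variable_ids), " fitted variables")
  }
  sum(fit$coefficients * profile) + fit$intercept
}
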