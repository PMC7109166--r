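# Indicator selection, F-sum risk score, and resubstitution classification.
#
# Variables whose structure correlation with the canonical axis exceeds a
# data-derived threshold in absolute value are the indicators: positive
# correlation marks tumor (RISK), negative marks tumor-free tissue
# (PROTECTIVE). The risk score for a profile is the signed sum of F-ratios
# over the indicators it carries (PROTECTIVE entering negatively, so a
# benign-marker carrier is not scored high-risk); perfect separators whose F
# is infinite enter at a finite cap so they dominate but remain summable.
# Classification itself uses the canonical-axis score with the zero-mutation
# profile's score as cutoff: score <= cutoff is called tumor-free, above it
# malignant. Metrics are resubstitution (training-set) estimates, as fitted.

#' Select indicator variables by structure-correlation magnitude
#'
#' @param fit A [fit_cva()] result.
#' @param r_threshold Correlation magnitude threshold; variables with
#'   `|r| > r_threshold` are selected. Data-derived per matrix; no universal
#'   default.
#' @return Data frame (`variable_id`, `f`, `r`, `direction`) ordered by
#'   descending F (`Inf` first); zero rows is legal.
#' @export
select_indicators <- function(fit, r_threshold) {
  stopifnot(inherits(fit, "cva_fit"), length(r_threshold) == 1)
  keep <- abs(fit$correlations) > r_threshold
  out <- data.frame(
    variable_id = fit$variable_ids[keep],
    f = unname(fit$f_ratios[keep]),
    r = unname(fit$correlations[keep]),
    direction = ifelse(fit$correlations[keep] > 0, "RISK", "PROTECTIVE"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$f, out$variable_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' F-sum risk score of a mutation profile
#'
#' Signed sum over the selected indicators present in the profile: RISK
#' variables contribute `+F`, PROTECTIVE ones `-F` (configurable). Presence
#' is binary (`min(profile, 1)`); infinite F enters at `f_cap`.
#'
#' @param profile Numeric vector (0/1 or counts) named by variable id, or
#'   positional over `selected$variable_id`.
#' @param selected Selection data frame from [select_indicators()].
#' @param f_cap Finite stand-in for infinite F-ratios (default 1e4).
#' @param sign_mode `"signed"` (default), `"positive_only"` (drop PROTECTIVE
#'   terms) or `"unsigned"` (all terms positive).
#' @return Scalar risk score; 0 for an empty selection or all-zero profile.
#' @export
risk_score <- function(profile, selected, f_cap = 1e4,
                       sign_mode = c("signed", "positive_only", "unsigned")) {
  sign_mode <- match.arg(sign_mode)
  if (nrow(selected) == 0) return(0)
  if (!is.null(names(profile))) {
    missing <- setdiff(selected$variable_id, names(profile))
    if (length(missing) > 0) {
      stop("profile lacks selected variable(s): ",
           paste(missing, collapse = ", "))
    }
    present <- pmin(profile[selected$variable_id], 1)
  } else {
    if (length(profile) != nrow(selected)) {
      stop("profile length ", length(profile), " does not match ",
           nrow(selected), " selected variables")
    }
    present <- pmin(profile, 1)
  }
  f <- pmin(selected$f, f_cap)
  sgn <- switch(sign_mode,
    signed = ifelse(selected$direction == "RISK", 1, -1),
    positive_only = ifelse(selected$direction == "RISK", 1, 0),
    unsigned = rep(1, nrow(selected)))
  sum(sgn * f * present)
}

#' Diagnostic metrics from a 2x2 contingency table
#'
#' Tumor is the condition-positive class: TP tumors called malignant, FN
#' tumors called tumor-free, FP tumor-free called malignant, TN tumor-free
#' called tumor-free.
#'
#' @param tp,fn,fp,tn Nonnegative integer cell counts.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv` as fractions
#'   in \[0, 1\] (`NA` where the denominator is 0).
#' @export
diagnostic_metrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = frac(tp, tp + fn),
       specificity = frac(tn, fp + tn),
       ppv = frac(tp, tp + fp),
       npv = frac(tn, tn + fn))
}

#' Classify the training cohort by the zero-mutation score cutoff
#'
#' The cutoff is the canonical-axis score of the all-zero profile: a sample
#' scoring at or below it (carrying no net mutation signal) is called
#' TUMOR_FREE, above it MALIGNANT. Produces the full report: selected
#' indicators, per-sample axis and risk scores, assignments, 2x2 contingency
#' against the true labels, and diagnostic metrics.
#'
#' @param fit The [fit_cva()] result trained on `m`.
#' @param m The `mutation_matrix` the fit was trained on (labels required).
#' @param r_threshold Correlation threshold for [select_indicators()].
#' @param f_cap Cap for infinite F in the risk score (default 1e4).
#' @param sign_mode Risk-score sign convention (see [risk_score()]).
#' @return A `classification_report`.
#' @export
classify <- function(fit, m, r_threshold, f_cap = 1e4,
                     sign_mode = c("signed", "positive_only", "unsigned")) {
  sign_mode <- match.arg(sign_mode)
  stopifnot(inherits(fit, "cva_fit"), inherits(m, "mutation_matrix"))
  if (!identical(fit$variable_ids, rownames(m$values))) {
    stop("fit and matrix variables do not match; classify() is resubstitution")
  }
  if (length(m$labels) == 0) stop("matrix has no group labels")
  selected <- select_indicators(fit, r_threshold)
  cutoff <- score_profile(fit, rep(0, length(fit$variable_ids)))
  scores <- fit$scores[colnames(m$values)]
  assignment <- ifelse(scores > cutoff, "MALIGNANT", "TUMOR_FREE")
  truth <- unname(m$labels)
  risk <- vapply(seq_len(ncol(m$values)), function(j) {
    prof <- stats::setNames(m$values[, j], rownames(m$values))
    risk_score(prof, selected, f_cap = f_cap, sign_mode = sign_mode)
  }, numeric(1))
  tp <- sum(truth == "tumor" & assignment == "MALIGNANT")
  fn <- sum(truth == "tumor" & assignment == "TUMOR_FREE")
  fp <- sum(truth == "tumor_free" & assignment == "MALIGNANT")
  tn <- sum(truth == "tumor_free" & assignment == "TUMOR_FREE")
  structure(list(
    selected = selected,
    r_threshold = r_threshold,
    f_cap = f_cap,
    sign_mode = sign_mode,
    cutoff = cutoff,
    scores = data.frame(
      sample_id = colnames(m$values),
      score = unname(scores),
      risk_score = risk,
      assignment = unname(assignment),
      truth = truth,
      stringsAsFactors = FALSE),
    contingency = c(tp = tp, fn = fn, fp = fp, tn = tn),
    metrics = diagnostic_metrics(tp, fn, fp, tn)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d indicators (|r| > %g), cutoff %.4f\n",
              nrow(x$selected), x$r_threshold, x$cutoff))
  ct <- x$contingency
  cat(sprintf("contingency: TP=%d FN=%d FP=%d TN=%d\n",
              ct["tp"], ct["fn"], ct["fp"], ct["tn"]))
  m <- x$metrics
  cat(sprintf("sensitivity=%.3f specificity=%.3f ppv=%.3f npv=%.3f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv))
  invisible(x)
}
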