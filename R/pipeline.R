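# End-to-end pipeline: read -> QC filter -> pair subtraction -> matrix ->
# CVA -> classification report, with provenance at every stage.

#' Pipeline configuration
#'
#' @param filters A [filter_config()].
#' @param level Analysis level: `"variant"` (binary incidence matrix with the
#'   prevalence reduction) or `"gene"` (per-gene variant counts).
#' @param min_count Variant-level prevalence filter (default 3; pooled over
#'   both groups).
#' @param r_threshold Structure-correlation threshold for indicator
#'   selection; data-derived per matrix, hence required.
#' @param f_cap Finite stand-in for infinite F-ratios (default 1e4).
#' @param sign_mode Risk-score sign convention (see [risk_score()]).
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic; randomness lives in the generator).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(filters = filter_config(),
                            level = c("variant", "gene"),
                            min_count = 3, r_threshold,
                            f_cap = 1e4,
                            sign_mode = c("signed", "positive_only", "unsigned"),
                            seed = 1L) {
  level <- match.arg(level)
  sign_mode <- match.arg(sign_mode)
  stopifnot(inherits(filters, "filter_config"), min_count >= 1,
            is.numeric(r_threshold), length(r_threshold) == 1)
  structure(list(filters = filters, level = level,
                 min_count = as.integer(min_count),
                 r_threshold = r_threshold, f_cap = f_cap,
                 sign_mode = sign_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level keys `filters` (min_depth, require_both_strands,
#' max_pop_af, pair_subtraction), `level`, `min_count`, `classifier`
#' (r_threshold, f_cap, risk_sign_mode) and `seed`; all but
#' `classifier$r_threshold` optional.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  f <- raw$filters %||% list()
  cl <- raw$classifier %||% list()
  if (is.null(cl$r_threshold)) stop("config is missing classifier.r_threshold")
  pipeline_config(
    filters = filter_config(
      min_depth = f$min_depth %||% 5,
      require_both_strands = f$require_both_strands %||% TRUE,
      max_pop_af = f$max_pop_af %||% 0.01,
      pair_subtraction = f$pair_subtraction %||% TRUE),
    level = raw$level %||% "variant",
    min_count = raw$min_count %||% 3,
    r_threshold = cl$r_threshold,
    f_cap = cl$f_cap %||% 1e4,
    sign_mode = cl$risk_sign_mode %||% "signed",
    seed = raw$seed %||% 1L)
}

#' Run the full analysis pipeline on a cohort
#'
#' Applies QC retention rules, matched-pair germline subtraction (when
#' configured), builds the configured matrix (variant-level incidence with
#' prevalence reduction, or gene-level counts), fits the two-group canonical
#' variates analysis and produces the classification report. Every stage
#' appends to the cohort provenance, which is attached to the report. With an
#' empty (or emptied) call set the report is degenerate but valid: no
#' indicators, every sample scored at the cutoff and assigned TUMOR_FREE.
#'
#' @param cohort A `cohort_calls`.
#' @param config A [pipeline_config()].
#' @param out Optional output path prefix; when given, the JSON report (and
#'   score TSV) is written to `<out>.json` via [write_report()].
#' @return A `classification_report` with attributes `provenance`, `fit` and
#'   `matrix`.
#' @export
run_pipeline <- function(cohort, config, out = NULL) {
  stopifnot(inherits(cohort, "cohort_calls"),
            inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("qc_filters", apply_qc_filters(cohort, config$filters))
  if (config$filters$pair_subtraction) {
    cohort <- stage("pair_subtraction", subtract_paired_germline(cohort))
  }
  m <- stage("matrix", {
    if (config$level == "variant") {
      prevalence_filter(build_variant_matrix(cohort), config$min_count)
    } else {
      build_gene_matrix(cohort)
    }
  })
  cohort <- log_step(cohort, sprintf(
    "matrix: level=%s, %d x %d retained", config$level, nrow(m$values),
    ncol(m$values)))

  if (nrow(m$values) == 0) {
    # no informative variables left: everything scores at the cutoff
    report <- empty_report(m, config)
  } else {
    fit <- stage("fit_cva", fit_cva(m))
    report <- stage("classify",
                    classify(fit, m, r_threshold = config$r_threshold,
                             f_cap = config$f_cap,
                             sign_mode = config$sign_mode))
    attr(report, "fit") <- fit
  }
  cohort <- log_step(cohort, sprintf(
    "classify: r_threshold=%g, %d indicators, TP=%d FN=%d FP=%d TN=%d; seed=%d",
    config$r_threshold, nrow(report$selected),
    report$contingency["tp"], report$contingency["fn"],
    report$contingency["fp"], report$contingency["tn"], config$seed))
  attr(report, "provenance") <- cohort$provenance
  attr(report, "matrix") <- m
  if (!is.null(out)) {
    write_report(report, paste0(out, ".json"))
  }
  report
}

empty_report <- function(m, config) {
  n <- ncol(m$values)
  tn <- sum(m$labels == "tumor_free")
  fn <- sum(m$labels == "tumor")
  structure(list(
    selected = data.frame(variable_id = character(), f = numeric(),
                          r = numeric(), direction = character(),
                          stringsAsFactors = FALSE),
    r_threshold = config$r_threshold, f_cap = config$f_cap,
    sign_mode = config$sign_mode, cutoff = 0,
    scores = data.frame(sample_id = colnames(m$values),
                        score = rep(0, n), risk_score = rep(0, n),
                        assignment = rep("TUMOR_FREE", n),
                        truth = unname(m$labels), stringsAsFactors = FALSE),
    contingency = c(tp = 0L, fn = fn, fp = 0L, tn = tn),
    metrics = diagnostic_metrics(0, fn, 0, tn)
  ), class = "classification_report")
}

#' Run the pipeline from files on disk
#'
#' Thin wrapper: reads the sample sheet and call table, bundles them and
#' delegates to [run_pipeline()].
#'
#' @param sample_sheet Path to the sample sheet CSV.
#' @param calls Path to the variant calls (TSV dialect, whole cohort).
#' @param config A [pipeline_config()] or a YAML path for
#'   [read_pipeline_config()].
#' @param out Optional output path prefix (see [run_pipeline()]).
#' @return A `classification_report`.
#' @export
run_pipeline_files <- function(sample_sheet, calls, config, out = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cohort <- cohort_calls(read_sample_sheet(sample_sheet),
                         read_variant_calls(calls, dialect = "tsv"))
  run_pipeline(cohort, config, out = out)
}
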