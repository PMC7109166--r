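# Variant retention rules and matched-pair germline subtraction.
#
# The retention rules mirror a standard targeted-panel workflow: keep a call
# only when it is covered by at least `min_depth` reads, is supported on both
# sequencing strands, and is rare in the population (frequency <= max_pop_af;
# "more than 1%" is read strictly, so pop_af = 0.01 is retained). Pair
# subtraction then removes, within each matched tumor/tumor-free pair, any
# variant key present in both members -- a presumed shared germline event --
# from both members. The removal is per-pair, never cohort-wide: the same
# variant observed somatically in another patient is kept.

#' Filter configuration
#'
#' @param min_depth Minimum read depth to retain a call (default 5).
#' @param require_both_strands Require support on both strands (default TRUE).
#' @param max_pop_af Maximum population allele frequency retained
#'   (default 0.01; calls with `pop_af > max_pop_af` are removed).
#' @param pair_subtraction Whether the pipeline applies matched-pair germline
#'   subtraction after QC (default TRUE).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 5, require_both_strands = TRUE,
                          max_pop_af = 0.01, pair_subtraction = TRUE) {
  stopifnot(length(min_depth) == 1, min_depth >= 0,
            length(max_pop_af) == 1, max_pop_af >= 0, max_pop_af <= 1,
            is.logical(require_both_strands), is.logical(pair_subtraction))
  structure(list(min_depth = as.integer(min_depth),
                 require_both_strands = require_both_strands,
                 max_pop_af = max_pop_af,
                 pair_subtraction = pair_subtraction),
            class = "filter_config")
}

#' Apply depth / strand / population-frequency retention rules
#'
#' Retains calls with `depth >= min_depth`, support on both strands (when
#' required) and `pop_af <= max_pop_af`. Removal counts per rule are appended
#' to the cohort provenance. Idempotent; an empty result is legal.
#'
#' @param cohort A `cohort_calls`.
#' @param cfg A [filter_config()].
#' @return The filtered `cohort_calls`.
#' @export
apply_qc_filters <- function(cohort, cfg = filter_config()) {
  stopifnot(inherits(cohort, "cohort_calls"), inherits(cfg, "filter_config"))
  calls <- cohort$calls
  if (nrow(calls) == 0) {
    return(log_step(cohort, "qc_filters: 0 calls in, 0 removed"))
  }
  fail_depth <- calls$depth < cfg$min_depth
  fail_strand <- if (cfg$require_both_strands) {
    !(calls$on_forward & calls$on_reverse)
  } else rep(FALSE, nrow(calls))
  fail_af <- calls$pop_af > cfg$max_pop_af
  keep <- !(fail_depth | fail_strand | fail_af)
  cohort$calls <- calls[keep, , drop = FALSE]
  rownames(cohort$calls) <- NULL
  log_step(cohort, sprintf(
    "qc_filters: %d calls in, removed %d (depth < %d: %d; single-strand: %d; pop_af > %g: %d), %d retained",
    nrow(calls), sum(!keep), cfg$min_depth, sum(fail_depth),
    sum(fail_strand), cfg$max_pop_af, sum(fail_af), sum(keep)))
}

#' Remove pair-shared (presumed germline) variants from matched pairs
#'
#' For each matched tumor/tumor-free pair, any variant key present in both
#' members is removed from both. Unpaired samples are untouched. Removed keys
#' are logged per pair.
#'
#' @param cohort A `cohort_calls`.
#' @return The cohort with pair-shared variants removed.
#' @export
subtract_paired_germline <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_calls"))
  calls <- cohort$calls
  if (nrow(calls) == 0) {
    return(log_step(cohort, "pair_subtraction: 0 calls, nothing to do"))
  }
  samples <- cohort$samples
  keys <- variant_key(calls$gene, calls$hgvs_c)
  drop <- rep(FALSE, nrow(calls))
  logs <- character()
  for (pid in unique(stats::na.omit(samples$pair_id))) {
    members <- samples$sample_id[!is.na(samples$pair_id) & samples$pair_id == pid]
    in_t <- keys[calls$sample_id == members[1]]
    in_n <- keys[calls$sample_id == members[2]]
    shared <- intersect(in_t, in_n)
    if (length(shared) > 0) {
      drop <- drop | (calls$sample_id %in% members & keys %in% shared)
      logs <- c(logs, sprintf("pair_subtraction: pair %s removed %s",
                              pid, paste(shared, collapse = ",")))
    }
  }
  cohort$calls <- calls[!drop, , drop = FALSE]
  rownames(cohort$calls) <- NULL
  cohort <- log_step(cohort, sprintf(
    "pair_subtraction: %d calls in, %d removed as pair-shared, %d retained",
    nrow(calls), sum(drop), sum(!drop)))
  if (length(logs) > 0) cohort <- log_step(cohort, logs)
  cohort
}
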