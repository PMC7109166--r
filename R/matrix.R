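# Mutation matrices and descriptive mutation-density statistics.
#
# Two sibling containers are built from a filtered cohort: a binary
# variants x samples incidence matrix (entry 1 iff the sample carries at
# least one call of that variant key) and a genes x samples count matrix
# (number of DISTINCT variant keys of the gene in the sample). Row order is
# lexicographic in (gene, hgvs_c); column order is sample-sheet order and is
# the canonical sample order for every downstream stage, so repeated runs are
# reproducible byte-for-byte.

#' Construct a mutation matrix container
#'
#' @param values Integer matrix, variants (or genes) in rows, samples in
#'   columns, with dimnames.
#' @param kind `"variant_binary"` or `"gene_count"`.
#' @param labels Named character vector of per-sample status
#'   (`tumor`/`tumor_free`), names matching `colnames(values)`.
#' @return A `mutation_matrix`.
#' @export
mutation_matrix <- function(values, kind = c("variant_binary", "gene_count"),
                            labels) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  if (anyDuplicated(rownames(values))) stop("duplicate row ids")
  if (anyDuplicated(colnames(values))) stop("duplicate column ids")
  if (kind == "variant_binary" && nrow(values) > 0 &&
      !all(values %in% c(0L, 1L))) {
    stop("variant_binary values must be 0/1")
  }
  if (nrow(values) > 0 && any(values < 0)) stop("negative counts")
  labels <- labels[colnames(values)]
  if (anyNA(labels)) stop("labels missing for some columns")
  stopifnot(all(labels %in% STATUS_LEVELS))
  structure(list(values = values, kind = kind, labels = labels),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("<mutation_matrix kind=%s> %d x %d (%d tumor, %d tumor-free columns)\n",
              x$kind, nrow(x$values), ncol(x$values),
              sum(x$labels == "tumor"), sum(x$labels == "tumor_free")))
  invisible(x)
}

#' @export
dim.mutation_matrix <- function(x) dim(x$values)

cohort_status <- function(cohort) {
  stats::setNames(cohort$samples$status, cohort$samples$sample_id)
}

#' Build the binary variants x samples incidence matrix
#'
#' One row per distinct variant key appearing in at least one call; entry
#' (v, s) is 1 iff sample s has one or more calls of key v (duplicate calls
#' stay 1). Rows are sorted by (gene, hgvs_c); columns follow sample-sheet
#' order and include call-free samples as all-zero columns. An empty cohort
#' yields a 0-row matrix with all sample columns present.
#'
#' @param cohort A filtered `cohort_calls`.
#' @return A `mutation_matrix` of kind `variant_binary`.
#' @export
build_variant_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_calls"))
  samples <- cohort$samples$sample_id
  calls <- cohort$calls
  if (nrow(calls) == 0) {
    values <- matrix(0L, nrow = 0, ncol = length(samples),
                     dimnames = list(character(), samples))
    return(mutation_matrix(values, "variant_binary", cohort_status(cohort)))
  }
  uv <- unique(calls[, c("gene", "hgvs_c")])
  uv <- uv[order(uv$gene, uv$hgvs_c), , drop = FALSE]
  keys <- variant_key(uv$gene, uv$hgvs_c)
  values <- matrix(0L, nrow = length(keys), ncol = length(samples),
                   dimnames = list(keys, samples))
  values[cbind(match(variant_key(calls$gene, calls$hgvs_c), keys),
               match(calls$sample_id, samples))] <- 1L
  mutation_matrix(values, "variant_binary", cohort_status(cohort))
}

#' Drop rare variants by pooled occurrence count
#'
#' Retains rows whose sum across ALL columns (both groups pooled) is at least
#' `min_count`. The column set is unchanged. Monotone in `min_count`.
#'
#' @param m A `variant_binary` mutation matrix.
#' @param min_count Minimum pooled occurrence count (default 3).
#' @return The reduced `mutation_matrix`.
#' @export
prevalence_filter <- function(m, min_count = 3) {
  stopifnot(inherits(m, "mutation_matrix"), m$kind == "variant_binary",
            min_count >= 1)
  keep <- rowSums(m$values) >= min_count
  mutation_matrix(m$values[keep, , drop = FALSE], m$kind, m$labels)
}

#' Build the genes x samples variant-count matrix
#'
#' One row per gene with at least one retained call; entry (g, s) is the
#' number of distinct variant keys of gene g present in sample s (call
#' multiplicity is ignored). Columns follow sample-sheet order.
#'
#' @param cohort A filtered `cohort_calls`.
#' @return A `mutation_matrix` of kind `gene_count`.
#' @export
build_gene_matrix <- function(cohort) {
  vm <- build_variant_matrix(cohort)
  samples <- colnames(vm$values)
  if (nrow(vm$values) == 0) {
    values <- matrix(0L, nrow = 0, ncol = length(samples),
                     dimnames = list(character(), samples))
    return(mutation_matrix(values, "gene_count", vm$labels))
  }
  gene <- sub(":.*$", "", rownames(vm$values))
  values <- rowsum(vm$values, group = gene)
  values <- values[order(rownames(values)), , drop = FALSE]
  storage.mode(values) <- "integer"
  mutation_matrix(values, "gene_count", vm$labels)
}

#' Mutation-density descriptives over the tumor group
#'
#' Average mutation density (AMD) is the mean number of variants per tumor
#' sample, reported with its range. When a `marker` variant key is supplied,
#' the tumor columns are split by marker presence and the conditional means
#' reported -- e.g. mutation density in marker-positive vs marker-negative
#' tumors.
#'
#' @param m A `variant_binary` mutation matrix with labels.
#' @param marker Optional variant key (a `rownames(m$values)` entry).
#' @return A list with `amd_tumor`, `amd_range`, `tumor_total_events`,
#'   `normal_total_events` and, when `marker` is given, `amd_conditional`
#'   (named: `present`, `absent`).
#' @export
density_stats <- function(m, marker = NULL) {
  stopifnot(inherits(m, "mutation_matrix"), m$kind == "variant_binary")
  tumor_cols <- m$labels == "tumor"
  sums <- colSums(m$values)
  t_sums <- sums[tumor_cols]
  out <- list(
    amd_tumor = if (length(t_sums) > 0) mean(t_sums) else 0,
    amd_range = if (length(t_sums) > 0) c(min(t_sums), max(t_sums)) else c(0, 0),
    tumor_total_events = sum(t_sums),
    normal_total_events = sum(sums[!tumor_cols])
  )
  if (!is.null(marker)) {
    if (!marker %in% rownames(m$values)) {
      stop("marker variant '", marker, "' not found among matrix rows")
    }
    has <- m$values[marker, tumor_cols] > 0
    out$amd_conditional <- c(
      present = if (any(has)) mean(t_sums[has]) else NA_real_,
      absent = if (any(!has)) mean(t_sums[!has]) else NA_real_)
  }
  out
}

#' Export a mutation matrix as TSV (row and column headers)
#'
#' @param m A `mutation_matrix`.
#' @param path Destination path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(inherits(m, "mutation_matrix"))
  df <- data.frame(id = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
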