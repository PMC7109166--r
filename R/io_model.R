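# Domain containers and external-format I/O shared by every pipeline stage.
#
# A cohort is a pair of tables: a sample sheet (one row per tissue sample,
# tumor or tumor-free, optionally linked into matched pairs from the same
# patient) and a variant call table (one row per observed variant in one
# sample, with the QC evidence the retention rules need). Variant identity is
# the (gene, HGVS coding-DNA) token pair throughout -- the convention used by
# hotspot-panel reports -- and genomic coordinates are optional pass-through.

STATUS_LEVELS <- c("tumor", "tumor_free")
HISTOLOGY_LEVELS <- c("classical", "follicular", "encapsulated", "oncocytic",
                      "multifocal", "microcarcinoma", "none")
VARIANT_CLASSES <- c("missense", "nonsense", "frameshift_ins", "frameshift_del",
                     "inframe_del", "other")

CALL_COLUMNS <- c("sample_id", "gene", "hgvs_c", "chrom", "pos", "ref", "alt",
                  "depth", "on_forward", "on_reverse", "pop_af",
                  "variant_class", "cosmic_id")

#' Canonical variant identity token
#'
#' Variants are identified by gene symbol plus HGVS coding-DNA string (e.g.
#' `BRAF:c.1799T>A`); genomic coordinates are never part of the identity.
#'
#' @param gene HGNC gene symbol(s).
#' @param hgvs_c HGVS coding-DNA string(s).
#' @return Character vector of `gene:hgvs_c` keys.
#' @export
variant_key <- function(gene, hgvs_c) paste(gene, hgvs_c, sep = ":")

#' Bundle a sample sheet and a call table into a validated cohort
#'
#' @param samples Data frame as returned by [read_sample_sheet()].
#' @param calls Data frame as returned by [read_variant_calls()]; may have
#'   zero rows.
#' @param provenance Character vector of log lines carried along the pipeline.
#' @return An object of class `cohort_calls` with elements `samples`, `calls`
#'   and `provenance`.
#' @export
cohort_calls <- function(samples, calls, provenance = character()) {
  stopifnot(is.data.frame(samples), is.data.frame(calls))
  validate_sample_sheet(samples)
  calls <- validate_calls(calls)
  unknown <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(unknown) > 0) {
    stop("calls reference sample_id(s) absent from the sample sheet: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(samples = samples, calls = calls,
                 provenance = as.character(provenance)),
            class = "cohort_calls")
}

#' @export
print.cohort_calls <- function(x, ...) {
  n_t <- sum(x$samples$status == "tumor")
  n_n <- sum(x$samples$status == "tumor_free")
  cat(sprintf("<cohort_calls> %d samples (%d tumor, %d tumor-free), %d calls, %d distinct variants\n",
              nrow(x$samples), n_t, n_n, nrow(x$calls),
              length(unique(variant_key(x$calls$gene, x$calls$hgvs_c)))))
  if (length(x$provenance) > 0) {
    cat("provenance:\n")
    cat(paste0("  ", x$provenance, collapse = "\n"), "\n")
  }
  invisible(x)
}

log_step <- function(cohort, line) {
  cohort$provenance <- c(cohort$provenance, line)
  cohort
}

validate_sample_sheet <- function(samples) {
  req <- c("sample_id", "patient_id", "status", "pair_id", "histology")
  missing <- setdiff(req, names(samples))
  if (length(missing) > 0) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "))
  }
  bad_status <- setdiff(unique(samples$status), STATUS_LEVELS)
  if (length(bad_status) > 0) {
    stop("unknown status value(s): ", paste(bad_status, collapse = ", "))
  }
  paired <- samples[!is.na(samples$pair_id), , drop = FALSE]
  for (pid in unique(paired$pair_id)) {
    st <- paired$status[paired$pair_id == pid]
    if (!(length(st) == 2 && sum(st == "tumor") == 1 && sum(st == "tumor_free") == 1)) {
      stop("pair_id '", pid,
           "' must be shared by exactly one tumor and one tumor-free sample")
    }
  }
  invisible(samples)
}

validate_calls <- function(calls) {
  for (col in setdiff(CALL_COLUMNS, names(calls))) {
    calls[[col]] <- switch(col,
      pos = NA_integer_, depth = NA_integer_,
      on_forward = NA, on_reverse = NA, pop_af = NA_real_,
      NA_character_)
  }
  calls <- calls[, CALL_COLUMNS, drop = FALSE]
  if (nrow(calls) == 0) return(calls)
  if (any(!is.na(calls$depth) & calls$depth < 0)) stop("depth must be >= 0")
  bad_af <- !is.na(calls$pop_af) & (calls$pop_af < 0 | calls$pop_af > 1)
  if (any(bad_af)) {
    stop("pop_af outside [0, 1] in ", sum(bad_af), " call(s)")
  }
  calls
}

parse_status <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("tumor", "ptc", "cancer", "malignant")] <- "tumor"
  out[x %in% c("tumor_free", "tumor-free", "normal", "benign")] <- "tumor_free"
  if (anyNA(out)) {
    stop("unparseable status value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read a cohort sample sheet
#'
#' CSV with header `sample_id,patient_id,status,pair_id,histology`. `status`
#' is parsed case-insensitively; `tumor_free`, `normal` and `benign` are
#' synonyms. Empty `pair_id`/`histology` become `NA`/`"none"`.
#'
#' @param path Path to the CSV file.
#' @return Data frame with one validated row per sample.
#' @export
read_sample_sheet <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  req <- c("sample_id", "patient_id", "status", "pair_id", "histology")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- data.frame(
    sample_id = trimws(raw$sample_id),
    patient_id = trimws(raw$patient_id),
    status = parse_status(raw$status),
    pair_id = ifelse(trimws(raw$pair_id) == "", NA_character_, trimws(raw$pair_id)),
    histology = ifelse(trimws(raw$histology) == "", "none", trimws(raw$histology)),
    stringsAsFactors = FALSE
  )
  bad_hist <- setdiff(unique(out$histology), HISTOLOGY_LEVELS)
  if (length(bad_hist) > 0) {
    stop("unknown histology value(s): ", paste(bad_hist, collapse = ", "))
  }
  validate_sample_sheet(out)
  out
}

#' Write a cohort sample sheet
#'
#' @param samples Sample sheet data frame.
#' @param path Destination CSV path.
#' @export
write_sample_sheet <- function(samples, path) {
  validate_sample_sheet(samples)
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

parse_logical_col <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read per-sample variant calls
#'
#' Two dialects are supported. `tsv`: a single tab-delimited table holding the
#' whole cohort, header columns as in `CALL_COLUMNS` (`sample_id`, `gene`,
#' `hgvs_c`, `depth`, `on_forward`, `on_reverse`, `pop_af` required; the rest
#' optional pass-through). `vcf`: one single-sample VCF v4.x per file;
#' `sample_id` is taken from the VCF genotype column name, depth from
#' `DP`, strand presence from per-strand support counts (keys configurable,
#' default `SAF`/`SAR`, present on both strands when each count is > 0) and
#' the population allele frequency from a configurable INFO key.
#'
#' The reader applies no scientific filter: a `DP=4` record is returned with
#' depth 4. Structurally unparseable rows are skipped and their count logged
#' via `message()`; out-of-range values (negative depth, `pop_af` outside
#' \[0, 1\]) are an error. A missing population frequency is treated as 0
#' (hotspot variants are typically absent from population databases) and
#' logged.
#'
#' @param path Path to the calls file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param af_key,gene_key,hgvs_key,strand_fwd_key,strand_rev_key INFO keys for
#'   the vcf dialect.
#' @param class_key INFO key holding the variant class (vcf dialect).
#' @return Data frame of validated calls (columns `CALL_COLUMNS`).
#' @export
read_variant_calls <- function(path, dialect = c("tsv", "vcf"),
                               af_key = "AF", gene_key = "GENE",
                               hgvs_key = "HGVSC",
                               strand_fwd_key = "SAF", strand_rev_key = "SAR",
                               class_key = "VCLASS") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    read_calls_tsv(path)
  } else {
    read_calls_vcf(path, af_key, gene_key, hgvs_key,
                   strand_fwd_key, strand_rev_key, class_key)
  }
}

read_calls_tsv <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  req <- c("sample_id", "gene", "hgvs_c", "depth", "on_forward", "on_reverse",
           "pop_af")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    stop("variant call table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  n_in <- nrow(raw)
  calls <- data.frame(
    sample_id = raw$sample_id,
    gene = raw$gene,
    hgvs_c = raw$hgvs_c,
    chrom = if ("chrom" %in% names(raw)) raw$chrom else NA_character_,
    pos = if ("pos" %in% names(raw)) suppressWarnings(as.integer(raw$pos)) else NA_integer_,
    ref = if ("ref" %in% names(raw)) raw$ref else NA_character_,
    alt = if ("alt" %in% names(raw)) raw$alt else NA_character_,
    depth = suppressWarnings(as.integer(raw$depth)),
    on_forward = parse_logical_col(raw$on_forward),
    on_reverse = parse_logical_col(raw$on_reverse),
    pop_af = suppressWarnings(as.numeric(raw$pop_af)),
    variant_class = if ("variant_class" %in% names(raw)) raw$variant_class else NA_character_,
    cosmic_id = if ("cosmic_id" %in% names(raw)) raw$cosmic_id else NA_character_,
    stringsAsFactors = FALSE
  )
  # pop_af absent/blank: treat as rare (0) but keep it auditable
  n_af_missing <- sum(is.na(raw$pop_af))
  if (n_af_missing > 0) {
    message("read_variant_calls: ", n_af_missing,
            " call(s) with missing pop_af treated as 0")
    calls$pop_af[is.na(raw$pop_af)] <- 0
  }
  ok <- !is.na(calls$sample_id) & !is.na(calls$gene) & !is.na(calls$hgvs_c) &
    !is.na(calls$depth) & !is.na(calls$on_forward) & !is.na(calls$on_reverse) &
    !is.na(calls$pop_af)
  if (any(!ok)) {
    message("read_variant_calls: skipped ", sum(!ok),
            " unparseable record(s) out of ", n_in)
    calls <- calls[ok, , drop = FALSE]
    rownames(calls) <- NULL
  }
  validate_calls(calls)
}

read_calls_vcf <- function(path, af_key, gene_key, hgvs_key,
                           strand_fwd_key, strand_rev_key, class_key) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix[, , drop = FALSE], stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(validate_calls(data.frame()))
  gt_cols <- colnames(vcf@gt)
  if (is.null(gt_cols) || length(gt_cols) < 2) {
    stop("VCF has no sample column; required field(s): sample genotype column")
  }
  sample_id <- gt_cols[2]

  info1 <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else as.character(v)
  }
  depth <- suppressWarnings(as.integer(info1("DP")))
  if (all(is.na(depth))) {
    dp_gt <- tryCatch(vcfR::extract.gt(vcf, element = "DP"),
                      error = function(e) NULL)
    if (!is.null(dp_gt)) depth <- suppressWarnings(as.integer(dp_gt[, 1]))
  }
  if (all(is.na(depth))) stop("VCF is missing required field(s): DP")

  saf <- suppressWarnings(as.numeric(info1(strand_fwd_key)))
  sar <- suppressWarnings(as.numeric(info1(strand_rev_key)))
  if (all(is.na(saf)) || all(is.na(sar))) {
    warning("VCF lacks per-strand support fields (", strand_fwd_key, "/",
            strand_rev_key, "); assuming both strands present")
    on_forward <- rep(TRUE, nrow(fix))
    on_reverse <- rep(TRUE, nrow(fix))
  } else {
    on_forward <- !is.na(saf) & saf > 0
    on_reverse <- !is.na(sar) & sar > 0
  }

  pop_af <- suppressWarnings(as.numeric(info1(af_key)))
  n_af_missing <- sum(is.na(pop_af))
  if (n_af_missing > 0) {
    message("read_variant_calls: ", n_af_missing,
            " call(s) with missing ", af_key, " treated as pop_af 0")
    pop_af[is.na(pop_af)] <- 0
  }

  gene <- info1(gene_key)
  hgvs <- info1(hgvs_key)
  # Fall back to a coordinate token when the panel annotation keys are absent,
  # so the call still has a stable identity.
  fallback <- is.na(gene) | is.na(hgvs)
  gene[is.na(gene)] <- "unknown"
  hgvs[fallback & is.na(hgvs)] <- paste0("g.", fix$POS[fallback & is.na(hgvs)],
                                         fix$REF[fallback & is.na(hgvs)], ">",
                                         fix$ALT[fallback & is.na(hgvs)])

  vclass <- info1(class_key)
  calls <- data.frame(
    sample_id = sample_id, gene = gene, hgvs_c = hgvs,
    chrom = fix$CHROM, pos = suppressWarnings(as.integer(fix$POS)),
    ref = fix$REF, alt = fix$ALT,
    depth = depth, on_forward = on_forward, on_reverse = on_reverse,
    pop_af = pop_af,
    variant_class = ifelse(is.na(vclass), "other", vclass),
    cosmic_id = NA_character_,
    stringsAsFactors = FALSE
  )
  ok <- !is.na(calls$depth)
  if (any(!ok)) {
    message("read_variant_calls: skipped ", sum(!ok),
            " unparseable record(s) out of ", nrow(calls))
    calls <- calls[ok, , drop = FALSE]
    rownames(calls) <- NULL
  }
  validate_calls(calls)
}

#' Write a variant call table (tsv dialect)
#'
#' Round-trips bit-exactly through [read_variant_calls()] for all call fields.
#'
#' @param calls Call data frame.
#' @param path Destination TSV path.
#' @export
write_variant_calls <- function(calls, path) {
  calls <- validate_calls(calls)
  utils::write.table(calls, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a classification report to JSON (plus a per-sample score TSV)
#'
#' The JSON document holds the selected indicator variables with their F-ratio
#' and structure correlation, the correlation threshold, the zero-profile
#' score cutoff, the 2x2 contingency table, the diagnostic metrics, and the
#' per-sample score table. Key ordering is deterministic. A companion TSV of
#' per-sample scores (`<path minus .json>_scores.tsv`) is written alongside.
#'
#' @param report A `classification_report` from [classify()].
#' @param path Destination `.json` path.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  doc <- list(
    r_threshold = report$r_threshold,
    cutoff = report$cutoff,
    f_cap = report$f_cap,
    selected_variables = if (nrow(report$selected) == 0) list() else
      lapply(seq_len(nrow(report$selected)), function(i) {
        list(variable_id = report$selected$variable_id[i],
             f = unname(report$selected$f[i]),
             r = unname(report$selected$r[i]),
             direction = report$selected$direction[i])
      }),
    samples = lapply(seq_len(nrow(report$scores)), function(i) {
      list(sample_id = report$scores$sample_id[i],
           score = unname(report$scores$score[i]),
           risk_score = unname(report$scores$risk_score[i]),
           assignment = report$scores$assignment[i],
           truth = report$scores$truth[i])
    }),
    contingency = as.list(report$contingency),
    metrics = report$metrics
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  tsv <- sub("\\.json$", "", path)
  utils::write.table(
    report$scores[, c("sample_id", "score", "assignment", "truth")],
    paste0(tsv, "_scores.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a JSON classification report
#'
#' @param path Path written by [write_report()].
#' @return The parsed report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
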