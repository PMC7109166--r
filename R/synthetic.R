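# Synthetic cohort generation with the study's statistical structure.
#
# The template describes a two-group cohort (tumor / tumor-free, with matched
# pairs) and a sparse hotspot mutation spectrum: a handful of strongly
# group-skewed anchor variants over a background of singletons and
# doubletons. Samples carry each variant independently with its group
# prevalence (Bernoulli); matched pairs can additionally share germline
# variants injected into both members, exercising pair subtraction. Each call
# receives QC evidence (depth, strand support, population frequency) from a
# simple noise model so the retention rules can be exercised. Everything is
# reproducible from the template seed.

#' Construct a cohort template
#'
#' @param n_tumor,n_normal Group sizes.
#' @param n_pairs Number of matched tumor/tumor-free pairs
#'   (`<= min(n_tumor, n_normal)`).
#' @param variants Data frame with columns `gene`, `hgvs_c`, `p_tumor`,
#'   `p_normal`, `variant_class`: per-variant carriage prevalence in each
#'   group.
#' @param germline_shared Optional data frame (`gene`, `hgvs_c`, `p_pair`,
#'   `variant_class`): variants injected into BOTH members of a pair with
#'   probability `p_pair`.
#' @param qc_model List: `depth_mean` (Poisson mean read depth), `depth_min`
#'   (clamp), `p_single_strand` (probability a call is seen on one strand
#'   only), `p_common_popaf` (probability a call gets population frequency
#'   above 1%).
#' @param histology_counts Optional named integer vector distributing tumor
#'   samples over histology subtypes (must sum to `n_tumor`).
#' @param rate_sigma Lognormal sigma of an optional per-sample mutation-rate
#'   multiplier (mean 1); 0 (default) = homogeneous samples.
#' @param exclusivity_groups Optional list of gene-symbol vectors; within a
#'   sample, at most one carried variant per listed group is kept (mutual
#'   exclusivity), deterministic given the draws.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `cohort_template`.
#' @export
cohort_template <- function(n_tumor, n_normal, n_pairs, variants,
                            germline_shared = NULL,
                            qc_model = list(depth_mean = 642, depth_min = 1,
                                            p_single_strand = 0,
                                            p_common_popaf = 0),
                            histology_counts = NULL,
                            rate_sigma = 0, exclusivity_groups = NULL,
                            seed = 1) {
  stopifnot(n_tumor >= 1, n_normal >= 1, n_pairs >= 0,
            n_pairs <= min(n_tumor, n_normal),
            is.data.frame(variants),
            all(c("gene", "hgvs_c", "p_tumor", "p_normal", "variant_class")
                %in% names(variants)),
            all(variants$p_tumor >= 0 & variants$p_tumor <= 1),
            all(variants$p_normal >= 0 & variants$p_normal <= 1))
  if (anyDuplicated(variant_key(variants$gene, variants$hgvs_c))) {
    stop("duplicate variant keys in template")
  }
  if (!is.null(germline_shared)) {
    stopifnot(all(c("gene", "hgvs_c", "p_pair") %in% names(germline_shared)),
              all(germline_shared$p_pair >= 0 & germline_shared$p_pair <= 1))
    if (is.null(germline_shared$variant_class)) {
      germline_shared$variant_class <- "missense"
    }
  }
  if (!is.null(histology_counts)) {
    stopifnot(sum(histology_counts) == n_tumor,
              all(names(histology_counts) %in% HISTOLOGY_LEVELS))
  }
  for (key in c("depth_mean", "depth_min", "p_single_strand", "p_common_popaf")) {
    if (is.null(qc_model[[key]])) stop("qc_model is missing '", key, "'")
  }
  structure(list(n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 n_pairs = as.integer(n_pairs),
                 variants = variants, germline_shared = germline_shared,
                 qc_model = qc_model, histology_counts = histology_counts,
                 rate_sigma = rate_sigma,
                 exclusivity_groups = exclusivity_groups,
                 seed = as.integer(seed)),
            class = "cohort_template")
}

#' Template calibrated to the thyroid study's printed statistics
#'
#' 39 tumor and 28 tumor-free samples with 27 matched pairs (40 patients);
#' anchor variants at their reported occurrence counts -- the BRAF V600E
#' token in 13/39 tumors and no normals, the TSHR c.1373T>C and APC
#' c.636_637insAA tokens in 4/39 tumors each, the benign-indicator LPAR4
#' c.137A>G in 4/28 normals -- plus eight further reported indicator tokens at
#' 3/39, a benign IDH1 token at 3/28, and a background of singleton/doubleton
#' variants across the remaining genes. Background HGVS tokens are synthetic
#' stand-ins (the study's full per-variant table is not public); they are
#' tuned so the analytic expected tumor mutation count is 100/39 = 2.56 and
#' the tumor-free density about a third of that. One pair-shared germline
#' AXIN1 variant exercises pair subtraction. The default QC model is clean
#' (deep both-strand coverage, no common-population calls), emulating the
#' post-QC dataset the analysis starts from.
#'
#' @param seed Integer seed stored in the template.
#' @return A `cohort_template`.
#' @export
study_template <- function(seed = 1) {
  v <- function(gene, hgvs, pt, pn, cls = "missense") {
    data.frame(gene = gene, hgvs_c = hgvs, p_tumor = pt, p_normal = pn,
               variant_class = cls, stringsAsFactors = FALSE)
  }
  syn_tokens <- function(gene, n, offset) {
    # deterministic synthetic coding tokens, unique within gene
    vapply(seq_len(n), function(i) sprintf("c.%dA>G", offset + 101 * i),
           character(1))
  }
  anchors <- rbind(
    v("BRAF", "c.1799T>A", 13 / 39, 0),
    v("TSHR", "c.1373T>C", 4 / 39, 0),
    v("APC", "c.636_637insAA", 4 / 39, 0, "frameshift_ins"),
    v("LPAR4", "c.137A>G", 0, 4 / 28))
  named_mid <- rbind(
    v("C16orf3", "c.169A>G", 3 / 39, 0),
    v("SMAD4", "c.964T>A", 3 / 39, 0),
    v("APC", "c.4666_4667insA", 3 / 39, 0, "frameshift_ins"),
    v("TSHR", "c.1963A>G", 3 / 39, 0),
    v("APC", "c.866C>A", 3 / 39, 0),
    v("C16orf3", "c.178G>A", 3 / 39, 0),
    v("DICER1", "c.5174G>A", 3 / 39, 0),
    v("TSHR", "c.1397A>T", 3 / 39, 0),
    v("IDH1", "c.352C>A", 0, 3 / 28))
  dbl_genes <- c("APC", "APC", "APC", "BRAF", "BRAF", "BRAF", "AXIN1", "AXIN1",
                 "PIK3CA", "PIK3CA", "CTNNB1", "EIF1AX", "PTEN", "TP53",
                 "MET", "HRAS")
  sgl_genes <- c(rep("BRAF", 6), rep("APC", 6), "AXIN1", "AXIN1", "PIK3CA",
                 "PIK3CA", "NRAS", "NRAS", "TP53", "TP53", "MET", "CTNNB1",
                 "SMAD4")
  bg_tumor <- do.call(rbind, lapply(seq_along(dbl_genes), function(i) {
    v(dbl_genes[i], sprintf("c.%dC>T", 1000 + 13 * i), 2 / 39, 0)
  }))
  bg_tumor2 <- do.call(rbind, lapply(seq_along(sgl_genes), function(i) {
    v(sgl_genes[i], sprintf("c.%dG>A", 2000 + 17 * i), 1 / 39, 0)
  }))
  nrm_dbl <- c("GNAS", "GNAS", "AXIN1", "C16orf3")
  nrm_sgl <- c("EIF1AX", "PTEN")
  bg_normal <- rbind(
    do.call(rbind, lapply(seq_along(nrm_dbl), function(i) {
      v(nrm_dbl[i], sprintf("c.%dT>C", 3000 + 19 * i), 0, 2 / 28)
    })),
    do.call(rbind, lapply(seq_along(nrm_sgl), function(i) {
      v(nrm_sgl[i], sprintf("c.%dA>C", 4000 + 23 * i), 0, 1 / 28)
    })),
    do.call(rbind, lapply(1:5, function(i) {
      v("LPAR4", sprintf("c.%dG>T", 500 + 29 * i), 0, 1 / 28)
    })))
  variants <- rbind(anchors, named_mid, bg_tumor, bg_tumor2, bg_normal)
  cohort_template(
    n_tumor = 39, n_normal = 28, n_pairs = 27,
    variants = variants,
    germline_shared = data.frame(gene = "AXIN1", hgvs_c = "c.2306A>G",
                                 p_pair = 0.15, variant_class = "missense",
                                 stringsAsFactors = FALSE),
    histology_counts = c(classical = 24, follicular = 4, encapsulated = 3,
                         oncocytic = 4, multifocal = 1, microcarcinoma = 3),
    seed = seed)
}

#' Analytic expected mutation counts per sample under a template
#'
#' Sum of carriage prevalences per group (germline pair-shared variants are
#' excluded: they are removed by pair subtraction and do not count as somatic
#' density).
#'
#' @param t A `cohort_template`.
#' @return Named vector `c(tumor = ..., normal = ...)`.
#' @export
expected_mutation_density <- function(t) {
  stopifnot(inherits(t, "cohort_template"))
  c(tumor = sum(t$variants$p_tumor), normal = sum(t$variants$p_normal))
}

template_sample_sheet <- function(t) {
  n_extra_t <- t$n_tumor - t$n_pairs
  n_extra_n <- t$n_normal - t$n_pairs
  tumors <- data.frame(
    sample_id = sprintf("T%02d", seq_len(t$n_tumor)),
    patient_id = sprintf("PT%02d", c(seq_len(t$n_pairs),
                                     t$n_pairs + seq_len(n_extra_t))),
    status = "tumor",
    pair_id = c(sprintf("P%02d", seq_len(t$n_pairs)),
                rep(NA_character_, n_extra_t)),
    stringsAsFactors = FALSE)
  normals <- data.frame(
    sample_id = sprintf("N%02d", seq_len(t$n_normal)),
    patient_id = sprintf("PT%02d", c(seq_len(t$n_pairs),
                                     t$n_pairs + n_extra_t + seq_len(n_extra_n))),
    status = "tumor_free",
    pair_id = c(sprintf("P%02d", seq_len(t$n_pairs)),
                rep(NA_character_, n_extra_n)),
    stringsAsFactors = FALSE)
  hist <- rep("none", t$n_tumor)
  if (!is.null(t$histology_counts)) {
    hist <- rep(names(t$histology_counts), t$histology_counts)
  }
  tumors$histology <- hist
  normals$histology <- "none"
  rbind(tumors, normals)
}

#' Generate a synthetic cohort from a template
#'
#' Each sample carries each template variant independently with its group
#' prevalence (optionally modulated by a per-sample lognormal rate
#' multiplier); paired samples additionally share germline variants with
#' probability `p_pair`, injected into both members. Each call receives depth
#' (clamped Poisson), strand support and population frequency from the
#' template's QC model. Identical `(template, seed)` gives bit-identical
#' output.
#'
#' @param t A `cohort_template`.
#' @param seed Seed override; defaults to `t$seed`.
#' @return A `cohort_calls`.
#' @export
generate_cohort <- function(t, seed = t$seed) {
  stopifnot(inherits(t, "cohort_template"))
  samples <- template_sample_sheet(t)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  nv <- nrow(t$variants)
  rows <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    p <- if (samples$status[i] == "tumor") t$variants$p_tumor else
      t$variants$p_normal
    if (t$rate_sigma > 0) {
      mult <- exp(stats::rnorm(1, -t$rate_sigma^2 / 2, t$rate_sigma))
      p <- pmin(1, p * mult)
    }
    carried <- which(stats::runif(nv) < p)
    if (!is.null(t$exclusivity_groups) && length(carried) > 1) {
      for (grp in t$exclusivity_groups) {
        in_grp <- carried[t$variants$gene[carried] %in% grp]
        if (length(in_grp) > 1) carried <- setdiff(carried, in_grp[-1])
      }
    }
    if (length(carried) > 0) {
      rows[[i]] <- data.frame(sample_id = samples$sample_id[i],
                              gene = t$variants$gene[carried],
                              hgvs_c = t$variants$hgvs_c[carried],
                              variant_class = t$variants$variant_class[carried],
                              stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  if (!is.null(t$germline_shared) && t$n_pairs > 0) {
    shared_rows <- list()
    for (pid in sprintf("P%02d", seq_len(t$n_pairs))) {
      members <- samples$sample_id[!is.na(samples$pair_id) &
                                     samples$pair_id == pid]
      hit <- stats::runif(nrow(t$germline_shared)) < t$germline_shared$p_pair
      if (any(hit)) {
        shared_rows[[pid]] <- data.frame(
          sample_id = rep(members, each = sum(hit)),
          gene = rep(t$germline_shared$gene[hit], 2),
          hgvs_c = rep(t$germline_shared$hgvs_c[hit], 2),
          variant_class = rep(t$germline_shared$variant_class[hit], 2),
          stringsAsFactors = FALSE)
      }
    }
    calls <- rbind(calls, do.call(rbind, shared_rows))
  }
  if (is.null(calls)) {
    calls <- data.frame(sample_id = character(), gene = character(),
                        hgvs_c = character(), variant_class = character(),
                        stringsAsFactors = FALSE)
  }
  calls <- unique(calls)
  rownames(calls) <- NULL

  n_calls <- nrow(calls)
  qc <- t$qc_model
  calls$depth <- pmax(stats::rpois(n_calls, qc$depth_mean),
                      as.integer(qc$depth_min))
  single <- stats::runif(n_calls) < qc$p_single_strand
  fwd_only <- stats::runif(n_calls) < 0.5
  calls$on_forward <- !single | fwd_only
  calls$on_reverse <- !single | !fwd_only
  common <- stats::runif(n_calls) < qc$p_common_popaf
  calls$pop_af <- ifelse(common, stats::runif(n_calls, 0.011, 0.2), 0)

  cohort_calls(samples, calls,
               provenance = sprintf(
                 "generate_cohort: %d samples, %d calls, seed %d",
                 nrow(samples), n_calls, seed))
}

#' Check generator prevalence recovery against binomial sampling error
#'
#' Generates `n_reps` cohorts (seeds `t$seed + 1 .. t$seed + n_reps`), counts
#' per-variant carriage in each group, and compares the pooled observed
#' fraction with the generating prevalence via a 99% binomial interval.
#'
#' @param t A `cohort_template`.
#' @param n_reps Number of replicate cohorts (>= 1).
#' @return Data frame: `gene`, `hgvs_c`, `group`, `p`, `observed`, `lower`,
#'   `upper`, `flag` (TRUE when observed falls outside the interval).
#' @export
prevalence_recovery_check <- function(t, n_reps) {
  stopifnot(inherits(t, "cohort_template"), n_reps >= 1)
  keys <- variant_key(t$variants$gene, t$variants$hgvs_c)
  counts <- matrix(0L, nrow = length(keys), ncol = 2,
                   dimnames = list(keys, c("tumor", "tumor_free")))
  for (rep in seq_len(n_reps)) {
    co <- generate_cohort(t, seed = t$seed + rep)
    ck <- variant_key(co$calls$gene, co$calls$hgvs_c)
    st <- cohort_status(co)[co$calls$sample_id]
    for (g in c("tumor", "tumor_free")) {
      tab <- table(factor(ck[st == g], levels = keys))
      counts[, g] <- counts[, g] + as.integer(tab)
    }
  }
  out <- do.call(rbind, lapply(c("tumor", "tumor_free"), function(g) {
    n_g <- if (g == "tumor") t$n_tumor else t$n_normal
    size <- n_g * n_reps
    p <- if (g == "tumor") t$variants$p_tumor else t$variants$p_normal
    lo <- stats::qbinom(0.005, size, p)
    hi <- stats::qbinom(0.995, size, p)
    data.frame(gene = t$variants$gene, hgvs_c = t$variants$hgvs_c, group = g,
               p = p, observed = counts[, g] / size,
               lower = lo / size, upper = hi / size,
               flag = counts[, g] < lo | counts[, g] > hi,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Serialize / read a cohort template as YAML
#'
#' @param t A `cohort_template`.
#' @param path Destination (or source) YAML path.
#' @export
write_template_yaml <- function(t, path) {
  stopifnot(inherits(t, "cohort_template"))
  x <- unclass(t)
  if (!is.null(x$histology_counts)) {
    x$histology_counts <- as.list(x$histology_counts)  # yaml map keeps names
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_template_yaml
#' @export
read_template_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort_template(
    n_tumor = raw$n_tumor, n_normal = raw$n_normal, n_pairs = raw$n_pairs,
    variants = as.data.frame(raw$variants, stringsAsFactors = FALSE),
    germline_shared = if (is.null(raw$germline_shared)) NULL else
      as.data.frame(raw$germline_shared, stringsAsFactors = FALSE),
    qc_model = raw$qc_model,
    histology_counts = if (is.null(raw$histology_counts)) NULL else
      unlist(raw$histology_counts),
    rate_sigma = raw$rate_sigma %||% 0,
    exclusivity_groups = raw$exclusivity_groups,
    seed = raw$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
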