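#' Default tissue category set
#'
#' The nine-tissue panel the atlas analyses assume by default.
#' @export
DEFAULT_TISSUES <- c("leaf", "root", "anther", "carpel", "flower_bud",
                     "seed", "stem", "early_fruit", "late_fruit")

#' Construct an expression atlas
#'
#' @param values Genes x samples matrix of TPM values (non-negative), with
#'   gene ids as rownames and sample ids as colnames.
#' @param meta Data frame with one row per sample: `sample_id`, `tissue`,
#'   `batch` and optionally `genotype`.
#' @param tissues Allowed tissue category set (default the nine-tissue panel).
#' @return Object of class `expr_atlas` with elements `values`, `meta`.
#' @export
expr_atlas <- function(values, meta, tissues = DEFAULT_TISSUES) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("TPM values must be non-negative")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  stopifnot(all(c("sample_id", "tissue", "batch") %in% names(meta)))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id))) stop("metadata missing for some samples")
  bad <- !(meta$tissue %in% tissues)
  if (any(bad)) stop("unknown tissue label(s): ",
                     paste(unique(meta$tissue[bad]), collapse = ", "))
  structure(list(values = values, meta = meta, tissues = tissues),
            class = "expr_atlas")
}

#' @export
print.expr_atlas <- function(x, ...) {
  cat("expr_atlas:", nrow(x$values), "genes x", ncol(x$values), "samples;",
      length(unique(x$meta$tissue)), "tissue(s),",
      length(unique(x$meta$batch)), "batch(es)\n")
  invisible(x)
}

#' Read an expression matrix and metadata from TSV
#'
#' @param matrix_path TSV with genes in rows (first column `gene_id`) and one
#'   column per sample.
#' @param meta_path TSV with columns `sample_id`, `tissue`, `batch`
#'   (optionally `genotype`).
#' @param tissues Allowed tissue set.
#' @return An [expr_atlas()].
#' @export
read_expression <- function(matrix_path, meta_path, tissues = DEFAULT_TISSUES) {
  df <- read.table(matrix_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  meta <- read_tsv(meta_path)
  expr_atlas(values, meta, tissues = tissues)
}

#' Write an atlas to TSV (matrix + metadata)
#'
#' @param atlas An [expr_atlas()].
#' @param matrix_path,meta_path Output paths.
#' @export
write_expression <- function(atlas, matrix_path, meta_path) {
  df <- data.frame(gene_id = rownames(atlas$values), atlas$values,
                   check.names = FALSE)
  write_tsv(df, matrix_path)
  write_tsv(atlas$meta, meta_path)
  invisible(matrix_path)
}

#' Expressed-gene masks at TPM > 1
#'
#' Genes are classed by whether they exceed TPM 1 in at least one sample
#' (`expressed_anywhere`), in every sample (`expressed_everywhere`, the
#' candidate set for housekeeping calls) or never (`never_expressed`,
#' retained in atlas outputs but excluded from housekeeping identification).
#' The threshold is strict (TPM exactly 1 does not count as expressed).
#'
#' @param atlas An [expr_atlas()].
#' @return List of three character vectors of gene ids.
#' @export
expressed_gene_mask <- function(atlas) {
  any_expr <- rowSums(atlas$values > 1) > 0
  all_expr <- rowSums(atlas$values > 1) == ncol(atlas$values)
  list(expressed_anywhere = rownames(atlas$values)[any_expr],
       expressed_everywhere = rownames(atlas$values)[all_expr],
       never_expressed = rownames(atlas$values)[!any_expr])
}

#' Log-transform an atlas
#'
#' Elementwise `log2(TPM + eps)`; entries with TPM <= 1 are flagged as
#' low-expression (they are zeroed on the specificity scale downstream).
#'
#' @param atlas An [expr_atlas()].
#' @param eps Pseudo-TPM added before the log (default 0.01).
#' @return Object of class `log_matrix`: `values` (log2 scale), `low_flag`
#'   (logical matrix, TPM <= 1), `eps`, `meta`, `tissues`.
#' @export
log_transform <- function(atlas, eps = 0.01) {
  stopifnot(eps > 0)
  if (any(atlas$values < 0)) stop("negative TPM")
  structure(list(values = log2(atlas$values + eps),
                 low_flag = atlas$values <= 1,
                 eps = eps, meta = atlas$meta, tissues = atlas$tissues),
            class = "log_matrix")
}

#' Batch adjustment of a log matrix
#'
#' `tissue_stratified_centering` removes, per gene, each batch's mean
#' deviation from its samples' tissue means (i.e. the batch effect estimated
#' after stripping tissue structure) — a simple additive stand-in for
#' surrogate-variable style correction with a pluggable interface. `none` is
#' the identity; `plugin` substitutes an externally corrected matrix.
#' A batch whose samples all come from a single tissue is confounded with
#' tissue and is skipped with a warning.
#'
#' @param lm A [log_transform()] result.
#' @param method One of `"tissue_stratified_centering"`, `"none"`, `"plugin"`.
#' @param plugin_values Corrected matrix (same shape) when `method = "plugin"`.
#' @return A `log_matrix` with adjusted `values`.
#' @export
batch_adjust <- function(lm, method = c("tissue_stratified_centering",
                                        "none", "plugin"),
                         plugin_values = NULL) {
  method <- match.arg(method)
  if (method == "none") return(lm)
  if (method == "plugin") {
    stopifnot(identical(dim(plugin_values), dim(lm$values)))
    lm$values <- plugin_values
    return(lm)
  }
  v <- lm$values
  tissue <- lm$meta$tissue
  batch <- as.character(lm$meta$batch)
  # per-gene tissue means over all samples
  tmeans <- vapply(unique(tissue), function(tt)
    rowMeans(v[, tissue == tt, drop = FALSE]), numeric(nrow(v)))
  colnames(tmeans) <- unique(tissue)
  resid <- v - tmeans[, tissue, drop = FALSE]
  offset <- matrix(0, nrow(v), ncol(v))
  for (b in unique(batch)) {
    sel <- batch == b
    if (length(unique(tissue[sel])) < 2L && length(unique(batch)) > 1L) {
      warning("batch '", b, "' confounded with a single tissue; not centered")
      next
    }
    offset[, sel] <- rowMeans(resid[, sel, drop = FALSE])
  }
  # re-centre within tissue so per-gene tissue grand means are preserved
  for (tt in unique(tissue)) {
    sel <- tissue == tt
    offset[, sel] <- offset[, sel, drop = FALSE] -
      rowMeans(offset[, sel, drop = FALSE])
  }
  lm$values <- v - offset
  lm
}

#' Tissue-mean expression profile
#'
#' The default `"threshold_log2"` scale operationalises the low-expression
#' rule: TPM values at or below 1 are set to 0, then `log2(x + 1)` is averaged
#' per tissue — the scale on which the tau index is computed. Applied to a
#' batch-adjusted `log_matrix`, the corrected values are mapped back to the
#' TPM scale (`2^v - eps`) before thresholding, so specificity is judged on
#' corrected expression (the same matrix the differential tests use).
#' `"raw_tpm"` averages TPM directly; `"adjusted_log2"` averages the adjusted
#' log values without the zeroing rule.
#'
#' @param x An [expr_atlas()] or a (typically batch-adjusted) `log_matrix`.
#' @param scale Aggregation scale (`raw_tpm` requires an `expr_atlas`).
#' @return Object of class `tissue_profile`: `means` (genes x tissues),
#'   `n_samples` (per tissue), `scale`.
#' @export
tissue_means <- function(x, scale = c("threshold_log2", "raw_tpm",
                                      "adjusted_log2")) {
  scale <- match.arg(scale)
  if (scale == "adjusted_log2") {
    stopifnot(inherits(x, "log_matrix"))
    v <- x$values
  } else {
    stopifnot(inherits(x, c("expr_atlas", "log_matrix")))
    v <- if (inherits(x, "log_matrix")) pmax(2^x$values - x$eps, 0) else x$values
    if (scale == "raw_tpm" && !inherits(x, "expr_atlas"))
      stop("raw_tpm aggregation needs an expr_atlas")
    if (scale == "threshold_log2") {
      v[v <= 1] <- 0
      v <- log2(v + 1)
    }
  }
  tissue <- x$meta$tissue
  tabs <- table(tissue)
  present <- names(tabs)[tabs > 0]
  means <- vapply(present, function(tt)
    rowMeans(v[, tissue == tt, drop = FALSE]), numeric(nrow(v)))
  rownames(means) <- rownames(v)
  structure(list(means = means, n_samples = as.integer(tabs[present]),
                 scale = scale), class = "tissue_profile")
}

#' Sample-sample similarity matrix
#'
#' @param lm A `log_matrix` (or anything with a `values` matrix).
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric samples x samples correlation matrix with unit diagonal.
#' @export
sample_similarity <- function(lm, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(ncol(lm$values) >= 2L)
  cor(lm$values, method = method)
}

#' Concordance between two atlas representations
#'
#' Compares the sample-sample similarity structure of two representations of
#' the same samples (e.g. TPM-based vs count-based): Fisher-z summarised
#' correlation of matched off-diagonal similarity entries, plus the Adjusted
#' Rand Index between average-linkage partitions at each cut level k.
#'
#' @param lmA,lmB Two `log_matrix` objects over the same samples.
#' @param k_range Integer vector of cut levels; values outside `[2, n-1]` are
#'   skipped.
#' @return List `fisher_z_pearson`, `fisher_z_spearman`, `ari_by_k` (named
#'   numeric vector).
#' @export
representation_concordance <- function(lmA, lmB, k_range = 2:10) {
  stopifnot(identical(colnames(lmA$values), colnames(lmB$values)))
  n <- ncol(lmA$values)
  out <- list()
  for (m in c("pearson", "spearman")) {
    sA <- sample_similarity(lmA, m); sB <- sample_similarity(lmB, m)
    out[[paste0("fisher_z_", m)]] <- concordance(sA, sB, method = "pearson")
  }
  dA <- as.dist(1 - sample_similarity(lmA, "pearson"))
  dB <- as.dist(1 - sample_similarity(lmB, "pearson"))
  tA <- hclust_average(dA); tB <- hclust_average(dB)
  ks <- k_range[k_range >= 2 & k_range <= n - 1]
  out$ari_by_k <- setNames(
    vapply(ks, function(k) ari(cut_partition(tA, k), cut_partition(tB, k)),
           numeric(1)),
    as.character(ks))
  out
}

#' @importFrom stats as.dist
NULL
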