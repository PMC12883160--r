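#' Tau tissue-specificity index
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)` over N tissue means `x >= 0`;
#' 0 for uniform expression, 1 for single-tissue expression. Undefined (NA)
#' when all tissue means are 0.
#'
#' @param x Numeric vector of tissue means (length >= 2, non-negative).
#' @return Tau in \[0, 1\], or `NA` when `max(x) == 0`.
#' @export
tau <- function(x) {
  stopifnot(length(x) >= 2L, all(x >= 0))
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

#' Tau table for a tissue profile
#'
#' @param profile A [tissue_means()] result.
#' @return Data frame: `gene_id`, `tau` (NA when undefined), `argmax_tissue`.
#' @export
tau_table <- function(profile) {
  mm <- profile$means
  mx <- apply(mm, 1, max)
  taus <- ifelse(mx == 0, NA_real_,
                 rowSums(1 - mm / pmax(mx, .Machine$double.xmin)) /
                   (ncol(mm) - 1))
  arg <- colnames(mm)[max.col(mm, ties.method = "first")]
  arg[mx == 0] <- NA_character_
  data.frame(gene_id = rownames(mm), tau = taus, argmax_tissue = arg,
             stringsAsFactors = FALSE)
}

#' Call tissue-specific genes
#'
#' For each gene, the candidate tissue is the argmax of its tissue means; the
#' candidate is tested against every other tissue on per-sample adjusted log2
#' values. A gene passes the differential-expression criterion when, in all
#' contrasts, the signed log2 fold change toward the candidate tissue is at
#' least `lfc_min` and the BH-adjusted p-value is at most `padj_max` (BH
#' applied per contrast family across genes sharing the candidate tissue).
#' The final call combines the DE criterion with the tau threshold; the
#' default combination is the conjunction, with union available.
#'
#' @param lm Batch-adjusted `log_matrix` (per-sample values used for testing).
#' @param profile [tissue_means()] result on the specificity scale (tau and
#'   candidate-tissue source).
#' @param lfc_min Minimum signed log2 fold change toward the candidate tissue.
#' @param padj_max Maximum BH-adjusted p-value, enforced in every contrast.
#' @param tau_min Tau threshold.
#' @param test `"welch"` (default) or `"moderated"` (empirical-Bayes shrunk).
#' @param combine `"intersection"` (DE AND tau, default) or `"union"`.
#' @return Data frame of class `ts_calls`: `gene_id`, `tissue`, `tau`,
#'   `log2fc_min` (worst contrast), `padj_worst` (largest adjusted p),
#'   `passes_de`, `passes_tau`, `is_TS`.
#' @export
call_ts <- function(lm, profile, lfc_min = 2, padj_max = 0.01, tau_min = 0.85,
                    test = c("welch", "moderated"),
                    combine = c("intersection", "union")) {
  test <- match.arg(test); combine <- match.arg(combine)
  tt <- tau_table(profile)
  tissue <- lm$meta$tissue
  counts <- table(tissue)
  testable <- names(counts)[counts >= 2L]
  skipped <- setdiff(colnames(profile$means), testable)
  if (length(skipped))
    warning("tissue(s) with < 2 samples cannot be TS targets: ",
            paste(skipped, collapse = ", "))
  v <- lm$values
  genes <- rownames(v)
  out <- data.frame(gene_id = genes, tissue = tt$argmax_tissue,
                    tau = tt$tau, log2fc_min = NA_real_, padj_worst = NA_real_,
                    passes_de = FALSE, passes_tau = !is.na(tt$tau) & tt$tau >= tau_min,
                    stringsAsFactors = FALSE)
  others_all <- intersect(colnames(profile$means), unique(tissue))
  for (target in testable) {
    idx <- which(tt$argmax_tissue == target)
    if (!length(idx)) next
    X <- v[idx, tissue == target, drop = FALSE]
    others <- setdiff(others_all, target)
    lfc <- padj <- matrix(NA_real_, length(idx), length(others),
                          dimnames = list(NULL, others))
    for (oth in others) {
      if (counts[[oth]] < 2L) next
      Y <- v[idx, tissue == oth, drop = FALSE]
      res <- if (test == "welch") .row_welch(X, Y) else moderated_t(X, Y)
      lfc[, oth] <- rowMeans(X) - rowMeans(Y)
      padj[, oth] <- bh_adjust(res$p_value)
    }
    ok <- complete.cases(lfc) & complete.cases(padj)
    pass <- ok & apply(lfc >= lfc_min, 1, all) & apply(padj <= padj_max, 1, all)
    out$log2fc_min[idx] <- apply(lfc, 1, min)
    out$padj_worst[idx] <- apply(padj, 1, max)
    out$passes_de[idx] <- pass
  }
  out$is_TS <- if (combine == "intersection")
    out$passes_de & out$passes_tau else out$passes_de | out$passes_tau
  class(out) <- c("ts_calls", "data.frame")
  out
}

#' @export
print.ts_calls <- function(x, ...) {
  cat("ts_calls:", nrow(x), "genes;", sum(x$is_TS), "tissue-specific",
      sprintf("(DE-only %d, tau-only %d)\n",
              sum(x$passes_de & !x$passes_tau),
              sum(x$passes_tau & !x$passes_de)))
  invisible(x)
}
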