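#' Call housekeeping genes
#'
#' Candidates are the genes expressed above TPM 1 in every sample. A candidate
#' is a housekeeping gene when its batch-adjusted log2 value exceeds, in every
#' sample, that sample's median across all genes (configurable to a single
#' global median), and its stability score is at most `cv_max`. Stability is
#' the coefficient of variation of the adjusted log2 values across all samples
#' (standard deviation available as an alternative), computed on the
#' low-expression-zeroed scale (TPM <= 1 treated as 0 before the transform —
#' immaterial for everywhere-expressed candidates, applied for consistency).
#' Results are sorted by the stability score ascending (most stable first).
#'
#' @param lm Batch-adjusted `log_matrix`.
#' @param mask Result of [expressed_gene_mask()] computed on the same atlas.
#' @param cv_max Maximum stability score (default 0.1 for CV).
#' @param median_mode `"per_sample"` (default) or `"global"`.
#' @param stability `"cv"` (default) or `"sd"`.
#' @param profile Optional [tissue_means()] result; when given, tau is
#'   reported per gene.
#' @return Data frame of class `hk_calls`: `gene_id`,
#'   `exceeds_median_everywhere`, `stability`, `mean_log2`, `tau`, `is_HK`,
#'   sorted by `stability`.
#' @export
call_hk <- function(lm, mask, cv_max = 0.1,
                    median_mode = c("per_sample", "global"),
                    stability = c("cv", "sd"), profile = NULL) {
  median_mode <- match.arg(median_mode)
  stability <- match.arg(stability)
  if (ncol(lm$values) < 2L) stop("need at least 2 samples")
  cand <- mask$expressed_everywhere
  v <- lm$values
  # zero rule: entries flagged low (TPM <= 1) treated as 0 on the log scale
  vz <- v
  vz[lm$low_flag] <- 0
  bar <- if (median_mode == "per_sample")
    apply(v, 2, median) else rep(median(v), ncol(v))
  vc <- v[cand, , drop = FALSE]
  exceeds <- rowSums(sweep(vc, 2, bar, ">")) == ncol(v)
  mu <- rowMeans(vz[cand, , drop = FALSE])
  sdv <- apply(vz[cand, , drop = FALSE], 1, sd)
  score <- if (stability == "cv") ifelse(mu == 0, NA_real_, sdv / mu) else sdv
  is_hk <- exceeds & !is.na(score) & score <= cv_max
  taus <- if (!is.null(profile)) {
    tt <- tau_table(profile)
    tt$tau[match(cand, tt$gene_id)]
  } else NA_real_
  out <- data.frame(gene_id = cand, exceeds_median_everywhere = exceeds,
                    stability = score, mean_log2 = mu, tau = taus,
                    is_HK = is_hk, stringsAsFactors = FALSE)
  out <- out[order(out$stability), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hk_calls", "data.frame")
  out
}

#' @export
print.hk_calls <- function(x, ...) {
  cat("hk_calls:", nrow(x), "everywhere-expressed candidates;",
      sum(x$is_HK), "housekeeping\n")
  invisible(x)
}
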