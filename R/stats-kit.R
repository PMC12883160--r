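# Statistical primitives shared by all stages. Standard procedures are
# delegated to base R / mclust; only behaviour the pipeline needs at
# degenerate inputs is layered on top.

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order (step-up, capped at 1).
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' Welch's two-sample t-test
#'
#' Computed from the closed form with Satterthwaite degrees of freedom so that
#' degenerate inputs are defined: zero variance in both groups with equal
#' means gives p = 1; zero variance with unequal means gives the limiting
#' p = 0 (statistic +/- Inf).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p_value` (two-sided).
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1))
    return(list(statistic = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p_value = 0))
  }
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = stat, df = df, p_value = 2 * pt(-abs(stat), df))
}

#' Moderated two-sample t-test with empirical-Bayes variance shrinkage
#'
#' Per-gene variances are shrunk toward a pooled prior (the mean of the
#' per-gene pooled variances) with `prior_df` prior degrees of freedom,
#' then an equal-variance t-statistic is formed with `prior_df + n1 + n2 - 2`
#' degrees of freedom. Operates row-wise on matrices so one call covers a
#' whole contrast family.
#'
#' @param X,Y Matrices (genes x samples) for the two groups.
#' @param prior_df Prior degrees of freedom for the shrinkage (default 4).
#' @return Data frame with `statistic`, `df`, `p_value` per row.
#' @export
moderated_t <- function(X, Y, prior_df = 4) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y),
            ncol(X) >= 2L, ncol(Y) >= 2L)
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  dfe <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dfe
  s2_prior <- mean(s2)
  s2_post <- (prior_df * s2_prior + dfe * s2) / (prior_df + dfe)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  stat <- (m1 - m2) / se
  df <- prior_df + dfe
  data.frame(statistic = stat, df = df, p_value = 2 * pt(-abs(stat), df))
}

# Row-wise Welch test for contrast families (vectorised form of welch_t).
.row_welch <- function(X, Y) {
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- ifelse(se2 == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
                 (m1 - m2) / sqrt(se2))
  df <- ifelse(se2 == 0, n1 + n2 - 2,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- ifelse(se2 == 0, ifelse(m1 == m2, 1, 0), 2 * pt(-abs(stat), df))
  data.frame(statistic = stat, df = df, p_value = p)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the combined sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' corrections. All values tied across both samples gives p = 1.
#'
#' @param x,y Numeric vectors (each length >= 1).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic` (Mann-Whitney U for `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  ties <- any(duplicated(pooled))
  use_exact <- !ties && length(pooled) <= 12L
  res <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                      exact = use_exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Chi-square goodness-of-fit test
#'
#' @param observed Vector of category counts (>= 2 categories, total > 0).
#' @param expected_proportions Expected proportions summing to 1; every
#'   expected count must be positive.
#' @return List with `statistic`, `df`, `p_value` (upper tail).
#' @export
chi_square_gof <- function(observed, expected_proportions) {
  stopifnot(length(observed) >= 2L,
            length(observed) == length(expected_proportions),
            sum(observed) > 0)
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  if (any(expected_proportions <= 0))
    stop("expected count of zero: statistic undefined")
  res <- suppressWarnings(chisq.test(observed, p = expected_proportions))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Fisher-z concordance between two similarity matrices
#'
#' Correlates the matched off-diagonal upper-triangle entries of two
#' sample-by-sample similarity matrices and reports the correlation summarised
#' through the Fisher z transform (for a single matrix pair this is the plain
#' correlation of the matched entries).
#'
#' @param simA,simB Square symmetric similarity matrices of identical shape.
#' @param method Correlation method for the matched entries.
#' @return Concordance in (-1, 1).
#' @export
concordance <- function(simA, simB, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(identical(dim(simA), dim(simB)), nrow(simA) >= 3L)
  ut <- upper.tri(simA)
  a <- simA[ut]; b <- simB[ut]
  if (sd(a) == 0 || sd(b) == 0)
    stop("constant similarity matrix: correlation undefined")
  r <- cor(a, b, method = method)
  tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))))
}

#' Adjusted Rand Index between two partitions
#'
#' @param a,b Cluster label vectors over the same elements.
#' @return ARI in \[-1, 1\]; 1 iff the partitions are identical up to label
#'   permutation.
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  mclust::adjustedRandIndex(a, b)
}

#' Average-linkage hierarchical clustering
#'
#' @param d A `dist` object.
#' @return An `hclust` tree (UPGMA / average linkage).
#' @export
hclust_average <- function(d) hclust(d, method = "average")

#' Cut an average-linkage tree into k clusters
#'
#' @param tree An `hclust` object.
#' @param k Number of clusters.
#' @return Integer cluster labels.
#' @export
cut_partition <- function(tree, k) cutree(tree, k = k)
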