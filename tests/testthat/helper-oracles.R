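# Independent oracles and fixture builders shared across the suite.

# Brute-force per-base labelling of a genome annotation: every base gets
# exactly one of exon/intron/intergenic, exon winning over intron.
per_base_partition <- function(ann) {
  out <- matrix(0, nrow = length(ann$chrom_lengths), ncol = 3,
                dimnames = list(names(ann$chrom_lengths),
                                c("exon", "intron", "intergenic")))
  for (ch in names(ann$chrom_lengths)) {
    lab <- rep("intergenic", ann$chrom_lengths[[ch]])
    e <- ann$exons[ann$exons$chrom == ch, ]
    g <- ann$genes[ann$genes$chrom == ch, ]
    for (i in seq_len(nrow(e))) lab[(e$start[i] + 1):e$end[i]] <- "exon"
    for (i in seq_len(nrow(g))) {
      span <- (g$start[i] + 1):g$end[i]
      lab[span][lab[span] != "exon"] <- "intron"
    }
    out[ch, ] <- c(sum(lab == "exon"), sum(lab == "intron"),
                   sum(lab == "intergenic"))
  }
  out
}

# Brute-force shared-base count between [s1,e1) and a set of regions.
per_base_overlap <- function(s1, e1, regions) {
  if (s1 == e1) return(0)
  covered <- rep(FALSE, e1 - s1)
  for (i in seq_len(nrow(regions))) {
    lo <- max(s1, regions$start[i]); hi <- min(e1, regions$end[i])
    if (lo < hi) covered[(lo - s1 + 1):(hi - s1)] <- TRUE
  }
  sum(covered)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# assignments of the pooled ranks (no ties assumed).
enum_wilcox_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r_obs <- sum(rank(pooled)[seq_len(m)])
  u_obs <- r_obs - m * (m + 1) / 2
  subsets <- utils::combn(m + n, m)
  us <- apply(subsets, 2, function(ix) sum(ix) - m * (m + 1) / 2)
  p_less <- mean(us <= u_obs); p_greater <- mean(us >= u_obs)
  min(1, 2 * min(p_less, p_greater))
}

# Adjusted Rand Index from the contingency table (permutation-model formula).
ari_contingency <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

# Small deterministic annotation: 1000-bp chromosome, one gene [100,400)
# with exons [100,200) and [300,400).
toy_annotation <- function() {
  genome_annotation(c(chr1 = 1000),
                    list(gene_model("gA", "chr1", "+", 100, 400,
                                    c(100, 300), c(200, 400))))
}

# Random small genome with possibly-overlapping genes, for oracle testing.
random_annotation <- function(max_len = 10000) {
  len <- sample(2000:max_len, 1)
  n_genes <- sample(0:5, 1)
  genes <- list()
  for (i in seq_len(n_genes)) {
    glen <- sample(100:800, 1)
    start <- sample(0:(len - glen), 1)
    k <- sample(1:3, 1)
    cuts <- sort(sample(seq(start + 10, start + glen - 10, by = 10),
                        2 * k - 2))
    bounds <- c(start, cuts, start + glen)
    es <- bounds[seq(1, 2 * k - 1, by = 2)]
    ee <- bounds[seq(2, 2 * k, by = 2)]
    genes[[i]] <- gene_model(paste0("rg", i), "chrR", sample(c("+", "-"), 1),
                             start, start + glen, es, ee)
  }
  genome_annotation(c(chrR = len), genes)
}

# Down-scaled synthetic study used by unit tests that exercise run_all.
small_config <- function(seed = 5) {
  synthetic_config(
    seed = seed, n_chrom = 2L, chrom_len = 8e5, n_genes = 300L,
    n_ts = 20L, n_hk = 20L, n_sv_genic = 20L,
    n_sv_occupancy = 5L, n_sv_complex = 5L, n_sv_depleted = 4L,
    n_sv_te_background = 4L, n_sv_ins = 8L, n_sv_tier3 = 6L,
    samples_per_tissue = 4L,
    n_map_synteny = 150L, n_map_og1to1 = 30L, n_map_ogbest = 20L)
}

# The default-condition run used by the acceptance checks; computed once.
.run_cache <- new.env(parent = emptyenv())
get_default_run <- function() {
  if (is.null(.run_cache$report)) {
    dir <- file.path(tempdir(), "vescatlas_default_run")
    .run_cache$report <- run_all(synthetic_config(seed = 101), out_dir = dir)
    .run_cache$dir <- dir
  }
  .run_cache
}
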