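# Structural-variant analytics: multi-caller merging, confidence tiering,
# TE-content classification, genic-overlap enrichment, promoter-window gene
# association and SV-expression association.

#' Merge SV calls across callers
#'
#' Calls cluster when they share chromosome and (by default) SV type and their
#' start positions chain within `max_distance` (single linkage within type).
#' The representative call is the assembly-based caller's member when present
#' (the merged set is assembly-anchored), otherwise the longest member;
#' support is the union of member callers.
#'
#' @param calls An [sv_calls()] data frame pooled over callers.
#' @param max_distance Maximum start-position gap within a cluster (bp).
#' @param same_type Require identical `sv_type` within a cluster.
#' @param assembly_caller Name of the assembly-based caller.
#' @return Data frame of class `merged_svs`: representative `chrom`, `pos`,
#'   `end`, `sv_type`, `length`, `id`, plus `support` (list column of caller
#'   names) and `n_members`.
#' @export
merge_svs <- function(calls, max_distance = 1000, same_type = TRUE,
                      assembly_caller = "svim_asm") {
  stopifnot(inherits(calls, "data.frame"), nrow(calls) > 0)
  key <- if (same_type) paste(calls$chrom, calls$sv_type) else calls$chrom
  out <- list()
  for (k in unique(key)) {
    grp <- calls[key == k, , drop = FALSE]
    grp <- grp[order(grp$pos, grp$caller, grp$id), , drop = FALSE]
    gap <- c(Inf, diff(grp$pos))
    cl <- cumsum(gap > max_distance)
    for (ci in unique(cl)) {
      mem <- grp[cl == ci, , drop = FALSE]
      asm <- mem[mem$caller == assembly_caller, , drop = FALSE]
      rep_row <- if (nrow(asm)) asm[order(-asm$length, asm$id)[1], ]
                 else mem[order(-mem$length, mem$id)[1], ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = rep_row$chrom, pos = rep_row$pos, end = rep_row$end,
        sv_type = rep_row$sv_type, length = rep_row$length, id = rep_row$id,
        n_members = nrow(mem), stringsAsFactors = FALSE)
      out[[length(out)]]$support <- list(sort(unique(mem$caller)))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$sv_type, res$id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("merged_svs", "data.frame")
  res
}

#' Assign confidence tiers to merged SVs
#'
#' Tier 1: supported by the assembly-based, short-read and long-read callers.
#' Tier 2: insertions over 500 bp supported by the assembly-based and
#' long-read callers (short-read methods are insufficiently sensitive for
#' large insertions) that are not tier 1. Everything else is tier 3; a merged
#' call lacking assembly support is tier 3 with a warning, since the merged
#' set is assembly-anchored. Tiers 1 and 2 form the high-confidence set used
#' downstream.
#'
#' @param msv A [merge_svs()] result.
#' @param assembly_caller,short_read_caller,long_read_caller Caller roles.
#' @param tier2_min_length Minimum insertion length for tier 2 (bp; strict >).
#' @return `msv` with an integer `tier` column.
#' @export
classify_tier <- function(msv, assembly_caller = "svim_asm",
                          short_read_caller = "manta",
                          long_read_caller = "sniffles",
                          tier2_min_length = 500) {
  sup <- msv$support
  has <- function(caller) vapply(sup, function(s) caller %in% s, logical(1))
  a <- has(assembly_caller); s <- has(short_read_caller); l <- has(long_read_caller)
  if (any(!a))
    warning(sum(!a), " merged call(s) without assembly support assigned tier 3")
  tier1 <- a & s & l
  tier2 <- !tier1 & a & l & msv$sv_type == "INS" & msv$length > tier2_min_length
  msv$tier <- ifelse(!a, 3L, ifelse(tier1, 1L, ifelse(tier2, 2L, 3L)))
  msv
}

#' High-confidence subset (tiers 1 and 2)
#'
#' @param msv A tiered [classify_tier()] result.
#' @return The rows with tier 1 or 2.
#' @export
high_confidence <- function(msv) {
  stopifnot("tier" %in% names(msv))
  msv[msv$tier %in% c(1L, 2L), , drop = FALSE]
}

#' Classify a TE proportion against the genomic background
#'
#' Under random placement, the TE proportion of a length-`l` region is
#' approximately `N(p, p(1-p)/l)` where `p` is the genome-wide background TE
#' proportion. The observed proportion is converted to a standard-normal
#' statistic; upper-tail significance marks TE-derived regions, lower-tail
#' significance TE-depleted ones, at `alpha/2` per tail.
#'
#' @param p_hat Observed TE proportion(s) of the region(s).
#' @param l Region length(s), bp.
#' @param p Background TE proportion, strictly inside (0, 1).
#' @param alpha Total two-sided significance level (default 0.05).
#' @return Data frame with `z` and `category` in
#'   `{TE_derived, TE_depleted, background}` (vectorised).
#' @export
classify_te_proportion <- function(p_hat, l, p, alpha = 0.05) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1), all(l > 0))
  if (p <= 0 || p >= 1) stop("background proportion must be inside (0, 1)")
  z <- (p_hat - p) / sqrt(p * (1 - p) / l)
  upper <- pnorm(z, lower.tail = FALSE)
  lower <- pnorm(z)
  category <- ifelse(upper < alpha / 2, "TE_derived",
                     ifelse(lower < alpha / 2, "TE_depleted", "background"))
  data.frame(z = z, category = category, stringsAsFactors = FALSE)
}

#' Classify SV regions by TE content
#'
#' Each region's TE proportion is tested against the genomic background with
#' [classify_te_proportion()]. TE-derived regions in which a single TE family
#' accounts for more than `occupancy_threshold` (of the region's TE-covered
#' bases by default, or of the region length) are occupancy-type; the
#' remaining TE-derived regions are TE-complex.
#'
#' @param regions Data frame with `chrom`, `start`, `end` (0-based half-open;
#'   every region at least 50 bp) and optionally `id`.
#' @param te TE track data frame: `chrom`, `start`, `end`, `family_id`.
#' @param p Genome-wide background TE proportion (0 < p < 1).
#' @param alpha Total two-sided significance level.
#' @param occupancy_threshold Dominant-family fraction above which a
#'   TE-derived region is occupancy-type.
#' @param denominator `"te_bases"` (dominant family over the region's
#'   TE-covered bases, default) or `"region_length"`.
#' @param chrom_lengths Optional named vector; regions outside their
#'   chromosome raise an error.
#' @return Data frame of class `te_content`: `id`, `l`, `te_bases`, `p_hat`,
#'   `z`, `category` in `{TE_derived_occupancy, TE_derived_complex,
#'   TE_depleted, background}`, `dominant_family`, `dominant_fraction`.
#' @export
classify_te_content <- function(regions, te, p, alpha = 0.05,
                                occupancy_threshold = 0.8,
                                denominator = c("te_bases", "region_length"),
                                chrom_lengths = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(nrow(regions) > 0, all(regions$end - regions$start >= 50))
  if (!is.null(chrom_lengths)) {
    bad <- regions$start < 0 | regions$end > chrom_lengths[regions$chrom]
    if (any(bad)) stop("region outside chromosome bounds")
  }
  if (is.null(regions$id)) regions$id <- paste0("region", seq_len(nrow(regions)))
  l <- regions$end - regions$start
  rg <- .as_granges(regions$chrom, regions$start, regions$end)
  te_bases <- numeric(nrow(regions))
  dom_family <- rep(NA_character_, nrow(regions))
  dom_bases <- numeric(nrow(regions))
  if (nrow(te)) {
    tg <- .as_granges(te$chrom, te$start, te$end)
    hits <- GenomicRanges::findOverlaps(rg, tg)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::pintersect(rg[qi], tg[si])
      w <- GenomicRanges::width(ov)
      fam <- te$family_id[si]
      # total TE bases via flattened union (overlapping TEs not double-counted)
      for (i in unique(qi)) {
        sel <- qi == i
        ir <- IRanges::reduce(IRanges::ranges(ov[sel]))
        te_bases[i] <- sum(IRanges::width(ir))
        per_fam <- tapply(w[sel], fam[sel], sum)
        j <- order(-per_fam, names(per_fam))[1]
        dom_family[i] <- names(per_fam)[j]
        dom_bases[i] <- per_fam[[j]]
      }
    }
  }
  p_hat <- te_bases / l
  cls <- classify_te_proportion(p_hat, l, p, alpha = alpha)
  denom <- if (denominator == "te_bases") te_bases else l
  dom_frac <- ifelse(denom > 0, dom_bases / denom, 0)
  category <- cls$category
  derived <- category == "TE_derived"
  category[derived] <- ifelse(dom_frac[derived] > occupancy_threshold,
                              "TE_derived_occupancy", "TE_derived_complex")
  out <- data.frame(id = regions$id, l = l, te_bases = te_bases,
                    p_hat = p_hat, z = cls$z, category = category,
                    dominant_family = dom_family,
                    dominant_fraction = dom_frac, stringsAsFactors = FALSE)
  class(out) <- c("te_content", "data.frame")
  out
}

#' Base-pair overlap enrichment of SVs in genic features
#'
#' The SV footprint (insertions, which have no reference footprint, are
#' excluded) is flattened so overlapping or adjacent SVs never double-count a
#' base, then intersected at base resolution with the exon / intron /
#' intergenic partition of the genome. Observed base counts are compared with
#' the genomic category proportions by a chi-square goodness-of-fit test.
#'
#' @param svs Data frame of SVs with `chrom`, `pos`, `end`, `sv_type`
#'   (typically the high-confidence merged set).
#' @param ann A [genome_annotation()].
#' @return List of class `overlap_enrichment`: `observed` (named base counts),
#'   `expected_proportions`, `expected`, `statistic`, `df`, `p_value`.
#' @export
overlap_enrichment <- function(svs, ann) {
  span <- svs[svs$sv_type != "INS" & svs$end > svs$pos, , drop = FALSE]
  if (!nrow(span)) stop("no SV bases to test (footprint is empty)")
  fp <- GenomicRanges::reduce(.as_granges(span$chrom, span$pos, span$end))
  part <- partition_genome(ann)
  obs <- setNames(numeric(3), colnames(part$counts))
  for (ch in unique(as.character(GenomicRanges::seqnames(fp)))) {
    fp_ch <- IRanges::ranges(fp[GenomicRanges::seqnames(fp) == ch])
    e <- ann$exons[ann$exons$chrom == ch, ]
    g <- ann$genes[ann$genes$chrom == ch, ]
    er <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    gr <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    intr <- BiocGenerics::setdiff(gr, er)
    exon_bp <- sum(IRanges::width(BiocGenerics::intersect(fp_ch, er)))
    intron_bp <- sum(IRanges::width(BiocGenerics::intersect(fp_ch, intr)))
    obs["exon"] <- obs["exon"] + exon_bp
    obs["intron"] <- obs["intron"] + intron_bp
    obs["intergenic"] <- obs["intergenic"] +
      sum(IRanges::width(fp_ch)) - exon_bp - intron_bp
  }
  gof <- chi_square_gof(obs, part$proportions)
  structure(list(observed = obs, expected_proportions = part$proportions,
                 expected = part$proportions * sum(obs),
                 statistic = gof$statistic, df = gof$df,
                 p_value = gof$p_value),
            class = "overlap_enrichment")
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat("SV base-pair overlap enrichment (chi-square GOF, df =", x$df, ")\n")
  print(rbind(observed = x$observed, expected = round(x$expected, 1)))
  cat("X-squared =", format(x$statistic), ", p =", format(x$p_value), "\n")
  invisible(x)
}

#' Associate SVs with genes via span and promoter window
#'
#' A gene harbors an SV when any part of the SV overlaps the gene span or its
#' promoter window — `promoter_bp` upstream of the span on the gene's strand
#' (`+`: `[start - promoter_bp, start)`; `-`: `[end, end + promoter_bp)`),
#' clipped to the chromosome. Insertions are treated as 1-bp breakpoints.
#' Each link is sub-labelled by the overlapped feature: `exon`, `intron`,
#' `promoter`, or `spanning` when more than one feature is touched.
#'
#' @param svs Data frame with `chrom`, `pos`, `end`, `sv_type`, `id`.
#' @param ann A [genome_annotation()].
#' @param promoter_bp Promoter window size (default 2000 bp).
#' @return Data frame of class `gene_sv_links`: `gene_id`, `sv_id`, `region`,
#'   `harbored` (always TRUE for emitted rows).
#' @export
link_genes <- function(svs, ann, promoter_bp = 2000) {
  if (!nrow(svs) || !nrow(ann$genes))
    return(structure(data.frame(gene_id = character(), sv_id = character(),
                                region = character(), harbored = logical()),
                     class = c("gene_sv_links", "data.frame")))
  g <- ann$genes
  prom_start <- ifelse(g$strand == "+", pmax(g$start - promoter_bp, 0), g$end)
  prom_end <- ifelse(g$strand == "+", g$start,
                     pmin(g$end + promoter_bp, ann$chrom_lengths[g$chrom]))
  ext_start <- pmin(g$start, prom_start)
  ext_end <- pmax(g$end, prom_end)
  s_start <- svs$pos
  s_end <- ifelse(svs$sv_type == "INS" | svs$end == svs$pos,
                  svs$pos + 1L, svs$end)
  sv_gr <- .as_granges(svs$chrom, s_start, s_end)
  gene_gr <- .as_granges(g$chrom, ext_start, ext_end)
  hits <- GenomicRanges::findOverlaps(sv_gr, gene_gr)
  if (!length(hits))
    return(structure(data.frame(gene_id = character(), sv_id = character(),
                                region = character(), harbored = logical()),
                     class = c("gene_sv_links", "data.frame")))
  qi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  region <- character(length(qi))
  for (k in seq_along(qi)) {
    i <- qi[k]; j <- gi[k]
    ex <- ann$exons[ann$exons$gene_id == g$gene_id[j], , drop = FALSE]
    gm <- gene_model(g$gene_id[j], g$chrom[j], g$strand[j], g$start[j],
                     g$end[j], ex$start, ex$end)
    intr <- gene_introns(gm)
    touches <- c(
      exon = overlap_bases(s_start[i], s_end[i], ex) > 0,
      intron = overlap_bases(s_start[i], s_end[i], intr) > 0,
      promoter = overlap_bases(s_start[i], s_end[i],
                               data.frame(start = prom_start[j],
                                          end = prom_end[j])) > 0)
    region[k] <- if (sum(touches) > 1L) "spanning" else names(which(touches))[1]
  }
  out <- data.frame(gene_id = g$gene_id[gi], sv_id = svs$id[qi],
                    region = region, harbored = TRUE, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$sv_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_sv_links", "data.frame")
  out
}

#' SV-expression association tests
#'
#' Compares SV-harboring genes against the remaining genes by two-tailed
#' Wilcoxon rank-sum tests: on mean adjusted log2 expression, on tau (when a
#' tissue profile is supplied), on |log2FC| between genotypes (when a
#' fold-change table is supplied), and stratified by SV region label with BH
#' adjustment across the region family.
#'
#' @param links A [link_genes()] result.
#' @param lm Batch-adjusted `log_matrix` over all genes.
#' @param profile Optional [tissue_means()] result for the tau comparison.
#' @param lfc_table Optional data frame `gene_id`, `log2fc` (genotype
#'   contrast) for the |log2FC| comparison.
#' @return List of class `sv_assoc` with elements `expression`, `tau`,
#'   `lfc`, `by_region` (data frame with BH-adjusted p per region).
#' @export
expression_association <- function(links, lm, profile = NULL,
                                   lfc_table = NULL) {
  genes <- rownames(lm$values)
  sv_genes <- intersect(unique(links$gene_id), genes)
  non_sv <- setdiff(genes, sv_genes)
  if (length(sv_genes) < 2L || length(non_sv) < 2L)
    stop("need at least 2 genes per group")
  mean_expr <- rowMeans(lm$values)
  two_group <- function(a, b) {
    w <- wilcoxon_rank_sum(a, b)
    list(n_sv = length(a), n_other = length(b),
         median_sv = median(a), median_other = median(b),
         direction = if (median(a) < median(b)) "SV_lower"
                     else if (median(a) > median(b)) "SV_higher" else "equal",
         statistic = w$statistic, p_value = w$p_value)
  }
  out <- list(expression = two_group(mean_expr[sv_genes], mean_expr[non_sv]))
  if (!is.null(profile)) {
    tt <- tau_table(profile)
    taus <- setNames(tt$tau, tt$gene_id)
    a <- taus[sv_genes]; b <- taus[non_sv]
    out$tau <- two_group(a[!is.na(a)], b[!is.na(b)])
  }
  if (!is.null(lfc_table)) {
    lfc <- setNames(abs(lfc_table$log2fc), lfc_table$gene_id)
    a <- lfc[intersect(sv_genes, names(lfc))]
    b <- lfc[intersect(non_sv, names(lfc))]
    out$lfc <- two_group(a, b)
  }
  regions <- sort(unique(links$region))
  if (length(regions)) {
    rows <- lapply(regions, function(r) {
      gsel <- intersect(unique(links$gene_id[links$region == r]), genes)
      if (length(gsel) < 2L) return(NULL)
      tg <- two_group(mean_expr[gsel], mean_expr[non_sv])
      data.frame(region = r, n = length(gsel), median_sv = tg$median_sv,
                 median_other = tg$median_other, p_value = tg$p_value,
                 stringsAsFactors = FALSE)
    })
    br <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (!is.null(br)) br$p_adj <- bh_adjust(br$p_value)
    out$by_region <- br
  }
  class(out) <- "sv_assoc"
  out
}

#' @export
print.sv_assoc <- function(x, ...) {
  e <- x$expression
  cat(sprintf("SV-expression association: %d SV genes vs %d others\n",
              e$n_sv, e$n_other))
  cat(sprintf("  log2 TPM: median %.3f vs %.3f (%s), Wilcoxon p = %.3g\n",
              e$median_sv, e$median_other, e$direction, e$p_value))
  if (!is.null(x$tau))
    cat(sprintf("  tau:      median %.3f vs %.3f, p = %.3g\n",
                x$tau$median_sv, x$tau$median_other, x$tau$p_value))
  if (!is.null(x$lfc))
    cat(sprintf("  |log2FC|: median %.3f vs %.3f, p = %.3g\n",
                x$lfc$median_sv, x$lfc$median_other, x$lfc$p_value))
  invisible(x)
}
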