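# Deterministic, seeded generator of every pipeline input with exported
# ground truth: toy genome annotation, TE landscape, per-caller SV VCFs,
# multi-tissue TPM matrix with planted TS/HK/SV-effect genes and batch
# offsets, id-mapping evidence tables, and a truth JSON.

#' Synthetic-data configuration
#'
#' Defaults define the package's standard study conditions: a 10-Mb toy
#' genome (5 x 2 Mb) carrying 2,000 genes; a TE landscape at 30% background
#' proportion; a nine-tissue atlas with 6 samples per tissue from 3 studies
#' (batches) with additive per-gene batch offsets (sd 1 on the log2 scale);
#' 100 planted tissue-specific genes at +4 log2 in one tissue, 100 planted
#' housekeeping genes (high mean, sd 0.2); and a planted -1 log2 expression
#' effect on genes harboring high-confidence SVs. Caller support is drawn
#' per SV with role-specific sensitivities (assembly 1.0, long-read 0.9,
#' short-read 0.85, dropping to 0.1 for insertions over 500 bp).
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param ... Overrides for any default listed above (see source for names).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chrom = 5L, chrom_len = 2e6,
    n_genes = 2000L, exons_per_gene = 3L,
    gene_len = c(1000, 2000), gene_gap = c(600, 1200),
    # TE landscape
    te_p = 0.3, te_families = 20L, te_len = c(100, 500),
    # SVs
    n_sv_genic = 120L, sv_genic_len = c(500, 2000),
    n_sv_occupancy = 20L, n_sv_complex = 20L, n_sv_depleted = 15L,
    n_sv_te_background = 15L, sv_te_len = c(800, 3000),
    n_sv_ins = 40L, sv_ins_len = c(600, 3000),
    n_sv_tier3 = 30L, sv_tier3_len = c(500, 2000),
    sens_assembly = 1.0, sens_long = 0.9, sens_short = 0.85,
    sens_short_big_ins = 0.1, caller_jitter = 100,
    # expression
    tissues = DEFAULT_TISSUES, samples_per_tissue = 6L, n_batches = 3L,
    batch_sd = 1, noise_sd = 0.5, tissue_effect_sd = 1,
    baseline_mean = 3, baseline_sd = 2,
    n_ts = 100L, ts_log2fc = 4, ts_baseline = -1,
    n_hk = 100L, hk_sd = 0.2, hk_mean = 6,
    sv_expression_effect = -1,
    lfc_null_sd = 0.3, lfc_sv_mean = -1, lfc_sv_sd = 0.5,
    # id mapping
    n_map_synteny = 1500L, n_map_og1to1 = 200L, n_map_ogbest = 150L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "synthetic_config")
}

# Segment a gene span into an alternating exon/intron chain (k exons).
.make_exons <- function(start, end, k) {
  n_seg <- 2L * k - 1L
  L <- end - start
  w <- runif(n_seg, 0.5, 1.5)
  lens <- floor(L * w / sum(w))
  lens[1] <- lens[1] + (L - sum(lens))
  bounds <- start + c(0, cumsum(lens))
  odd <- seq(1L, n_seg, by = 2L)
  list(starts = bounds[odd], ends = bounds[odd + 1L])
}

.place_genes <- function(cfg) {
  per_chrom <- rep(cfg$n_genes %/% cfg$n_chrom, cfg$n_chrom)
  per_chrom[seq_len(cfg$n_genes %% cfg$n_chrom)] <-
    per_chrom[seq_len(cfg$n_genes %% cfg$n_chrom)] + 1L
  worst <- max(per_chrom) * (cfg$gene_gap[2] + cfg$gene_len[2])
  if (worst > 0.75 * cfg$chrom_len)
    stop("infeasible placement: too many genes for genome size")
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  models <- vector("list", cfg$n_genes)
  gi <- 0L
  last_end <- setNames(numeric(cfg$n_chrom), chroms)
  for (ci in seq_len(cfg$n_chrom)) {
    cursor <- 0
    for (j in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      gap <- round(runif(1, cfg$gene_gap[1], cfg$gene_gap[2]))
      len <- round(runif(1, cfg$gene_len[1], cfg$gene_len[2]))
      start <- cursor + gap
      ex <- .make_exons(start, start + len, cfg$exons_per_gene)
      models[[gi]] <- gene_model(sprintf("g%04d", gi), chroms[ci],
                                 sample(c("+", "-"), 1), start, start + len,
                                 ex$starts, ex$ends)
      cursor <- start + len
    }
    last_end[ci] <- cursor
  }
  list(ann = genome_annotation(setNames(rep(cfg$chrom_len, cfg$n_chrom),
                                        chroms), models),
       last_end = last_end)
}

# Background TE process: alternating gap/TE intervals tuned so expected TE
# density equals te_p; family weights are skewed (common vs rare families).
.background_tes <- function(cfg, chrom) {
  mean_len <- mean(cfg$te_len)
  mean_gap <- mean_len * (1 - cfg$te_p) / cfg$te_p
  half <- 0.8 * mean_gap
  n_draw <- ceiling(cfg$chrom_len / (cfg$te_len[1] + mean_gap - half)) + 10L
  lens <- round(runif(n_draw, cfg$te_len[1], cfg$te_len[2]))
  gaps <- round(runif(n_draw, mean_gap - half, mean_gap + half))
  ends <- cumsum(lens + gaps)
  starts <- ends - lens
  keep <- ends <= cfg$chrom_len
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             family_id = paste0("fam", sample.int(cfg$te_families,
                                                  sum(keep), replace = TRUE,
                                                  prob = 1 / seq_len(cfg$te_families))),
             stringsAsFactors = FALSE)
}

.te_class_label <- function(family_id) {
  idx <- as.integer(sub("fam", "", family_id))
  c(rep("LTR/Gypsy", 8), rep("LTR/Copia", 6), rep("DNA/MULE-MuDR", 4),
    rep("LINE/L1", 2))[idx]
}

#' Generate a full synthetic input set with ground truth
#'
#' Emits, under `out_dir`: `genome.gff3`, `te.out` (RepeatMasker layout),
#' `svim_asm.vcf` / `manta.vcf` / `sniffles.vcf`, `tpm.tsv`, `metadata.tsv`,
#' `genotype_lfc.tsv`, `anchors.tsv`, `orthogroups.tsv`, `distances.tsv`,
#' and `truth.json`. The same seed yields byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the ground truth and the file paths.
#' @export
generate_synthetic <- function(config = synthetic_config(), out_dir) {
  cfg <- config
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## genome ------------------------------------------------------------
  placed <- .place_genes(cfg)
  ann <- placed$ann
  genes <- ann$genes
  n_genes <- nrow(genes)

  ## gene roles ---------------------------------------------------------
  ids <- genes$gene_id
  ts_genes <- sort(sample(ids, cfg$n_ts))
  hk_genes <- sort(sample(setdiff(ids, ts_genes), cfg$n_hk))
  ts_tissue <- setNames(sample(cfg$tissues, cfg$n_ts, replace = TRUE), ts_genes)

  ## SV placement --------------------------------------------------------
  # genic deletions: non-adjacent plain genes so distinct SVs never merge
  plain <- setdiff(ids, c(ts_genes, hk_genes))
  plain_idx <- sort(match(plain, ids))
  sel <- integer(0); last <- -3L
  for (i in plain_idx) {
    if (i - last >= 3L) { sel <- c(sel, i); last <- i }
  }
  if (length(sel) < cfg$n_sv_genic)
    stop("infeasible placement: not enough non-adjacent genes for genic SVs")
  genic_idx <- sort(sample(sel, cfg$n_sv_genic))
  sv <- list()
  for (i in genic_idx) {
    glen <- genes$end[i] - genes$start[i]
    len <- round(runif(1, cfg$sv_genic_len[1], min(cfg$sv_genic_len[2], glen)))
    in_promoter <- runif(1) < 0.25
    if (in_promoter) {
      anchor <- if (genes$strand[i] == "+") genes$start[i] - len - 50
                else genes$end[i] + 50
      start <- max(0, anchor)
    } else {
      start <- genes$start[i] +
        round(runif(1, 0, max(0, glen - len)))
    }
    sv[[length(sv) + 1L]] <- data.frame(
      chrom = genes$chrom[i], pos = start, end = start + len, sv_type = "DEL",
      length = len, te_class = "background_genic", forced_tier3 = FALSE,
      stringsAsFactors = FALSE)
  }
  # intergenic SVs in the tail beyond the last gene of each chromosome
  tail_specs <- data.frame(
    te_class = c(rep("occupancy", cfg$n_sv_occupancy),
                 rep("complex", cfg$n_sv_complex),
                 rep("depleted", cfg$n_sv_depleted),
                 rep("background", cfg$n_sv_te_background),
                 rep("ins", cfg$n_sv_ins),
                 rep("tier3", cfg$n_sv_tier3)),
    stringsAsFactors = FALSE)
  tail_specs <- tail_specs[sample.int(nrow(tail_specs)), , drop = FALSE]
  chroms <- names(ann$chrom_lengths)
  cursor <- placed$last_end + 5000
  ci <- 0L
  for (k in seq_len(nrow(tail_specs))) {
    cls <- tail_specs$te_class[k]
    len <- switch(cls,
      ins = round(runif(1, cfg$sv_ins_len[1], cfg$sv_ins_len[2])),
      tier3 = round(runif(1, cfg$sv_tier3_len[1], cfg$sv_tier3_len[2])),
      round(runif(1, cfg$sv_te_len[1], cfg$sv_te_len[2])))
    ci <- ci %% length(chroms) + 1L
    start <- cursor[ci]
    is_ins <- cls == "ins"
    endp <- if (is_ins) start else start + len
    if (max(start, endp) + 1000 > cfg$chrom_len)
      stop("infeasible placement: SV tail exceeds chromosome")
    cursor[ci] <- start + (if (is_ins) 0 else len) + 3000
    sv[[length(sv) + 1L]] <- data.frame(
      chrom = chroms[ci], pos = start, end = endp,
      sv_type = if (is_ins) "INS" else "DEL", length = len,
      te_class = if (is_ins) NA_character_ else
        if (cls == "tier3") "background" else cls,
      forced_tier3 = cls == "tier3", stringsAsFactors = FALSE)
  }
  if (!length(sv))
    sv <- list(data.frame(chrom = character(), pos = numeric(),
                          end = numeric(), sv_type = character(),
                          length = numeric(), te_class = character(),
                          forced_tier3 = logical(), stringsAsFactors = FALSE))
  sv <- do.call(rbind, sv)
  sv$id <- sprintf("sv%04d", seq_len(nrow(sv)))

  ## TE landscape --------------------------------------------------------
  te <- do.call(rbind, lapply(chroms, function(ch) .background_tes(cfg, ch)))
  planted <- sv[!is.na(sv$te_class) &
                  sv$te_class %in% c("occupancy", "complex", "depleted"), ]
  if (nrow(planted)) {
    rg <- .as_granges(planted$chrom, planted$pos, planted$end)
    tg <- .as_granges(te$chrom, te$start, te$end)
    drop <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(tg, rg)))
    if (length(drop)) te <- te[-drop, , drop = FALSE]
    extra <- list()
    for (k in seq_len(nrow(planted))) {
      l <- planted$end[k] - planted$pos[k]
      off <- planted$pos[k] + round(0.02 * l)
      cov <- round(0.9 * l)
      if (planted$te_class[k] == "occupancy") {
        fam <- paste0("fam", sample.int(cfg$te_families, 1))
        extra[[length(extra) + 1L]] <- data.frame(
          chrom = planted$chrom[k], start = off, end = off + cov,
          family_id = fam, stringsAsFactors = FALSE)
      } else if (planted$te_class[k] == "complex") {
        fams <- paste0("fam", sample.int(cfg$te_families, 3))
        piece <- floor(cov / 3)
        extra[[length(extra) + 1L]] <- data.frame(
          chrom = planted$chrom[k],
          start = off + (0:2) * piece, end = off + (1:3) * piece,
          family_id = fams, stringsAsFactors = FALSE)
      } # depleted: leave empty
    }
    te <- rbind(te, do.call(rbind, extra))
  }
  te <- te[order(te$chrom, te$start), , drop = FALSE]
  rownames(te) <- NULL
  te$class_label <- .te_class_label(te$family_id)
  te_p_realized <- sum(te$end - te$start) / sum(ann$chrom_lengths)

  ## caller support ------------------------------------------------------
  n_sv <- nrow(sv)
  long_hit <- runif(n_sv) < cfg$sens_long
  short_sens <- ifelse(sv$sv_type == "INS" & sv$length > 500,
                       cfg$sens_short_big_ins, cfg$sens_short)
  short_hit <- runif(n_sv) < short_sens
  long_hit[sv$forced_tier3] <- FALSE
  short_hit[sv$forced_tier3] <- FALSE
  sv$support <- mapply(function(l, s) {
    sort(c("svim_asm", if (s) "manta", if (l) "sniffles"))
  }, long_hit, short_hit, SIMPLIFY = FALSE)
  sv$tier <- ifelse(long_hit & short_hit, 1L,
                    ifelse(long_hit & sv$sv_type == "INS" & sv$length > 500,
                           2L, 3L))

  ## per-caller VCFs (mapping-based callers jittered) ---------------------
  mk_calls <- function(caller, keep, jitter) {
    d <- sv[keep, c("chrom", "pos", "end", "sv_type", "length", "id")]
    if (jitter > 0 && nrow(d)) {
      dj <- round(runif(nrow(d), -jitter, jitter))
      d$pos <- pmax(0L, d$pos + dj)
      d$end <- ifelse(d$sv_type == "INS", d$pos, d$pos + d$length)
    }
    d$caller <- rep(caller, nrow(d))
    d$id <- if (nrow(d)) paste0(caller, "_", d$id) else character(0)
    sv_calls(d)
  }
  calls_asm <- mk_calls("svim_asm", rep(TRUE, n_sv), 0)
  calls_short <- mk_calls("manta", short_hit, cfg$caller_jitter)
  calls_long <- mk_calls("sniffles", long_hit, cfg$caller_jitter)

  ## SV-gene links and expression effects --------------------------------
  hc <- sv[sv$tier %in% c(1L, 2L), , drop = FALSE]
  links <- link_genes(hc, ann)
  sv_effect_genes <- sort(unique(links$gene_id))

  ## expression ----------------------------------------------------------
  tissues <- cfg$tissues
  n_t <- length(tissues)
  samples <- expand.grid(rep = seq_len(cfg$samples_per_tissue),
                         tissue = tissues, stringsAsFactors = FALSE)
  samples$batch <- paste0("study", ((samples$rep - 1L) %% cfg$n_batches) + 1L)
  samples$sample_id <- sprintf("%s_%s_r%d", samples$tissue, samples$batch,
                               samples$rep)
  n_s <- nrow(samples)
  baseline <- rnorm(n_genes, cfg$baseline_mean, cfg$baseline_sd)
  noise_sd <- rep(cfg$noise_sd, n_genes)
  tis_eff <- matrix(rnorm(n_genes * n_t, 0, cfg$tissue_effect_sd),
                    n_genes, n_t, dimnames = list(ids, tissues))
  i_ts <- match(ts_genes, ids); i_hk <- match(hk_genes, ids)
  baseline[i_ts] <- cfg$ts_baseline
  tis_eff[i_ts, ] <- 0
  tis_eff[cbind(i_ts, match(ts_tissue, tissues))] <- cfg$ts_log2fc
  baseline[i_hk] <- cfg$hk_mean
  tis_eff[i_hk, ] <- 0
  noise_sd[i_hk] <- cfg$hk_sd
  sv_eff <- rep(0, n_genes)
  sv_eff[match(sv_effect_genes, ids)] <- cfg$sv_expression_effect
  batches <- paste0("study", seq_len(cfg$n_batches))
  batch_off <- matrix(rnorm(n_genes * cfg$n_batches, 0, cfg$batch_sd),
                      n_genes, cfg$n_batches, dimnames = list(ids, batches))
  log2tpm <- matrix(baseline + sv_eff, n_genes, n_s) +
    tis_eff[, samples$tissue] + batch_off[, samples$batch] +
    matrix(rnorm(n_genes * n_s), n_genes, n_s) * noise_sd
  tpm <- 2^log2tpm
  dimnames(tpm) <- list(ids, samples$sample_id)
  meta <- data.frame(sample_id = samples$sample_id, tissue = samples$tissue,
                     batch = samples$batch, genotype = "H4",
                     stringsAsFactors = FALSE)

  ## genotype fold-change table ------------------------------------------
  lfc <- rnorm(n_genes, 0, cfg$lfc_null_sd)
  i_sv <- match(sv_effect_genes, ids)
  lfc[i_sv] <- rnorm(length(i_sv), cfg$lfc_sv_mean, cfg$lfc_sv_sd)
  lfc_table <- data.frame(gene_id = ids, log2fc = lfc,
                          stringsAsFactors = FALSE)

  ## id-mapping evidence --------------------------------------------------
  n_map <- cfg$n_map_synteny + cfg$n_map_og1to1 + cfg$n_map_ogbest
  if (n_map + 1 > n_genes)
    stop("id-mapping counts exceed gene count")
  idB <- ids
  idA <- sub("^g", "v4_", ids)
  i1 <- seq_len(cfg$n_map_synteny)
  i2 <- cfg$n_map_synteny + seq_len(cfg$n_map_og1to1)
  i3 <- cfg$n_map_synteny + cfg$n_map_og1to1 + seq_len(cfg$n_map_ogbest)
  i4 <- setdiff(seq_len(n_genes), c(i1, i2, i3))
  anchors <- data.frame(idA = idA[i1], idB = idB[i1],
                        block = paste0("blk", (i1 - 1) %/% 50 + 1),
                        stringsAsFactors = FALSE)
  og <- rbind(
    data.frame(gene_id = idA[c(i1, i2)], version = "A",
               orthogroup = paste0("OG", c(i1, i2)), stringsAsFactors = FALSE),
    data.frame(gene_id = idB[c(i1, i2)], version = "B",
               orthogroup = paste0("OG", c(i1, i2)), stringsAsFactors = FALSE),
    # tier-3 groups: one A gene with two candidate B genes
    data.frame(gene_id = idA[i3], version = "A",
               orthogroup = paste0("OGm", i3), stringsAsFactors = FALSE),
    data.frame(gene_id = idB[i3], version = "B",
               orthogroup = paste0("OGm", i3), stringsAsFactors = FALSE),
    data.frame(gene_id = paste0(idB[i3], "_alt"), version = "B",
               orthogroup = paste0("OGm", i3), stringsAsFactors = FALSE),
    # version-A genes with an orthogroup but no version-B partner: unmapped
    data.frame(gene_id = idA[i4], version = "A",
               orthogroup = paste0("OGa", i4), stringsAsFactors = FALSE))
  distances <- data.frame(
    idA = rep(idA[i3], 2L),
    idB = c(idB[i3], paste0(idB[i3], "_alt")),
    distance = c(round(runif(length(i3), 0.01, 0.2), 4),
                 round(runif(length(i3), 0.3, 0.9), 4)),
    stringsAsFactors = FALSE)
  idmap_truth <- data.frame(
    idA = idA[c(i1, i2, i3, i4)],
    expected_idB = c(idB[i1], idB[i2], idB[i3], rep(NA_character_,
                                                    length(i4))),
    expected_confidence = c(rep("synteny_1to1", length(i1)),
                            rep("orthogroup_1to1", length(i2)),
                            rep("orthogroup_best", length(i3)),
                            rep("unmapped", length(i4))),
    stringsAsFactors = FALSE)

  ## write ----------------------------------------------------------------
  paths <- list(
    gff3 = file.path(out_dir, "genome.gff3"),
    te = file.path(out_dir, "te.out"),
    vcf_asm = file.path(out_dir, "svim_asm.vcf"),
    vcf_short = file.path(out_dir, "manta.vcf"),
    vcf_long = file.path(out_dir, "sniffles.vcf"),
    tpm = file.path(out_dir, "tpm.tsv"),
    meta = file.path(out_dir, "metadata.tsv"),
    lfc = file.path(out_dir, "genotype_lfc.tsv"),
    anchors = file.path(out_dir, "anchors.tsv"),
    orthogroups = file.path(out_dir, "orthogroups.tsv"),
    distances = file.path(out_dir, "distances.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_gff3(ann, paths$gff3)
  write_repeatmasker_out(te, paths$te)
  write_vcf_svs(calls_asm, paths$vcf_asm, ann$chrom_lengths)
  write_vcf_svs(calls_short, paths$vcf_short, ann$chrom_lengths)
  write_vcf_svs(calls_long, paths$vcf_long, ann$chrom_lengths)
  tpm_df <- data.frame(gene_id = ids, signif(tpm, 10), check.names = FALSE)
  write_tsv(tpm_df, paths$tpm)
  write_tsv(meta, paths$meta)
  write_tsv(lfc_table, paths$lfc)
  write_tsv(anchors, paths$anchors)
  write_tsv(og, paths$orthogroups)
  write_tsv(distances, paths$distances)

  sv_out <- sv
  sv_out$support <- vapply(sv_out$support, paste, character(1), collapse = ",")
  truth <- list(
    seed = cfg$seed,
    tissues = tissues,
    te_p_configured = cfg$te_p,
    te_p_realized = te_p_realized,
    ts_genes = as.list(ts_tissue),
    hk_genes = hk_genes,
    sv = sv_out[, c("id", "chrom", "pos", "end", "sv_type", "length",
                    "support", "tier", "te_class")],
    sv_effect_genes = sv_effect_genes,
    sv_expression_effect = cfg$sv_expression_effect,
    batch_sd = cfg$batch_sd,
    idmap = idmap_truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(truth = truth, paths = paths, config = cfg))
}
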