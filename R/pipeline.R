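# End-to-end orchestration on the synthetic fixture: generate inputs, read
# them back through the package's own readers, run every analysis stage in
# dependency order, and emit a machine-readable run report.

#' Run the full pipeline on a synthetic fixture
#'
#' Generates the synthetic input set for `config`, reads every file back
#' through the package readers (so the run also exercises round-trip
#' integrity), and executes the stages in dependency order: ingest ->
#' expressed-gene filter -> log transform -> batch adjustment -> tissue
#' means -> tau/TS calling -> HK calling -> SV merge/tier -> TE-content
#' classification -> overlap enrichment -> gene linking -> expression
#' association -> id mapping. Stage groups can be switched off. Results and
#' a JSON run report are written under `out_dir`.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Working directory for generated inputs and outputs.
#' @param stages Character subset of `c("expression", "sv", "idmap")`.
#' @param params Optional overrides: `eps`, `lfc_min`, `padj_max`, `tau_min`,
#'   `cv_max`, `alpha`, `promoter_bp`, `max_distance`.
#' @return List of class `run_report` (also written as `report.json`).
#' @export
run_all <- function(config = synthetic_config(), out_dir = tempfile("atlasrun"),
                    stages = c("expression", "sv", "idmap"),
                    params = list()) {
  stopifnot(all(stages %in% c("expression", "sv", "idmap")))
  pp <- list(eps = 0.01, lfc_min = 2, padj_max = 0.01, tau_min = 0.85,
             cv_max = 0.1, alpha = 0.05, promoter_bp = 2000,
             max_distance = 1000)
  pp[names(params)] <- params
  # locale-independent name ordering for report list fields
  csort <- function(x) sort(x, method = "radix")
  count_list <- function(x) {
    tb <- table(x)
    as.list(tb)[csort(names(tb))]
  }
  gen <- generate_synthetic(config, out_dir)
  paths <- gen$paths
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  report <- list(seed = config$seed, stages = stages,
                 params = pp[csort(names(pp))])

  ann <- read_gff3(paths$gff3)
  report$genome <- list(n_chrom = length(ann$chrom_lengths),
                        genome_bp = unname(sum(ann$chrom_lengths)),
                        n_genes = nrow(ann$genes))
  part <- partition_genome(ann)
  report$genome$partition <- as.list(signif(part$proportions, 10))

  lm_adj <- NULL; profile <- NULL; atlas <- NULL
  if ("expression" %in% stages) {
    atlas <- read_expression(paths$tpm, paths$meta, tissues = truth$tissues)
    mask <- expressed_gene_mask(atlas)
    lm <- log_transform(atlas, eps = pp$eps)
    lm_adj <- batch_adjust(lm)
    profile <- tissue_means(lm_adj)
    ts <- call_ts(lm_adj, profile, lfc_min = pp$lfc_min,
                  padj_max = pp$padj_max, tau_min = pp$tau_min)
    hk <- call_hk(lm_adj, mask, cv_max = pp$cv_max, profile = profile)
    stopifnot(!any(ts$gene_id[ts$is_TS] %in% hk$gene_id[hk$is_HK]))
    write_tsv(ts, file.path(out_dir, "ts_calls.tsv"))
    write_tsv(hk, file.path(out_dir, "hk_calls.tsv"))
    called_ts <- ts$gene_id[ts$is_TS]
    true_ts <- names(truth$ts_genes)
    called_hk <- hk$gene_id[hk$is_HK]
    sim <- sample_similarity(lm_adj)
    partn <- cut_partition(hclust_average(as.dist(1 - sim)),
                           length(truth$tissues))
    report$expression <- list(
      n_samples = ncol(atlas$values),
      n_expressed_anywhere = length(mask$expressed_anywhere),
      n_expressed_everywhere = length(mask$expressed_everywhere),
      n_never_expressed = length(mask$never_expressed),
      n_ts_called = length(called_ts),
      ts_sensitivity = signif(mean(true_ts %in% called_ts), 10),
      ts_fdp = signif(if (length(called_ts))
        mean(!(called_ts %in% true_ts)) else 0, 10),
      n_hk_called = length(called_hk),
      hk_sensitivity = signif(mean(truth$hk_genes %in% called_hk), 10),
      hk_tau_max = signif(max(hk$tau[hk$is_HK], na.rm = TRUE), 10),
      tissue_ari = signif(ari(partn, atlas$meta$tissue), 10))
  }

  if ("sv" %in% stages) {
    calls <- rbind(read_vcf_svs(paths$vcf_asm, "svim_asm"),
                   read_vcf_svs(paths$vcf_short, "manta"),
                   read_vcf_svs(paths$vcf_long, "sniffles"))
    merged <- classify_tier(merge_svs(calls, max_distance = pp$max_distance))
    hc <- high_confidence(merged)
    te <- read_repeatmasker_out(paths$te)
    p_bg <- sum(te$end - te$start) / sum(ann$chrom_lengths)
    dels <- hc[hc$sv_type != "INS", , drop = FALSE]
    tec <- classify_te_content(
      data.frame(chrom = dels$chrom, start = dels$pos, end = dels$end,
                 id = dels$id), te, p = p_bg, alpha = pp$alpha,
      chrom_lengths = ann$chrom_lengths)
    enr <- overlap_enrichment(hc, ann)
    links <- link_genes(hc, ann, promoter_bp = pp$promoter_bp)
    write_tsv(data.frame(merged[, c("chrom", "pos", "end", "sv_type",
                                    "length", "id", "tier")],
                         support = vapply(merged$support, paste, character(1),
                                          collapse = ",")),
              file.path(out_dir, "merged_svs.tsv"))
    write_tsv(tec, file.path(out_dir, "te_content.tsv"))
    write_tsv(links, file.path(out_dir, "gene_sv_links.tsv"))
    report$sv <- list(
      n_input_calls = nrow(calls),
      n_merged = nrow(merged),
      n_tier1 = sum(merged$tier == 1L),
      n_tier2 = sum(merged$tier == 2L),
      n_tier3 = sum(merged$tier == 3L),
      n_high_confidence = nrow(hc),
      tier_match_truth = identical(
        sort(truth$sv$id[truth$sv$tier %in% c(1, 2)]),
        sort(sub("^svim_asm_", "", hc$id))),
      te_background_p = signif(p_bg, 10),
      te_categories = count_list(tec$category),
      enrichment = list(observed = as.list(enr$observed),
                        statistic = signif(enr$statistic, 10),
                        df = enr$df,
                        p_value = signif(enr$p_value, 10)),
      n_sv_genes = length(unique(links$gene_id)))
    if (!is.null(lm_adj)) {
      lfc_table <- read_tsv(paths$lfc)
      assoc <- expression_association(links, lm_adj, profile = profile,
                                      lfc_table = lfc_table)
      report$sv$association <- list(
        expression_p = signif(assoc$expression$p_value, 10),
        expression_direction = assoc$expression$direction,
        tau_p = signif(assoc$tau$p_value, 10),
        lfc_p = signif(assoc$lfc$p_value, 10),
        by_region = lapply(split(assoc$by_region,
                                 assoc$by_region$region)[csort(unique(assoc$by_region$region))],
                           function(r)
          list(n = r$n, p_adj = signif(r$p_adj, 10))))
    }
  }

  if ("idmap" %in% stages) {
    ev <- mapping_evidence(read_tsv(paths$anchors),
                           read_tsv(paths$orthogroups),
                           read_tsv(paths$distances))
    mapping <- reconcile(ev)
    write_tsv(mapping, file.path(out_dir, "id_mapping.tsv"))
    tr <- truth$idmap
    m <- mapping[match(tr$idA, mapping$idA), ]
    report$idmap <- list(
      n_genes = nrow(mapping),
      confidence_counts = count_list(mapping$confidence),
      accuracy = signif(mean(m$confidence == tr$expected_confidence &
                               (is.na(tr$expected_idB) |
                                  m$idB == tr$expected_idB), na.rm = TRUE), 10))
  }

  report$versions <- list(package = "vescatlas",
                          version = as.character(utils::packageVersion("vescatlas")))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("vescatlas run report (seed", x$seed, ")\n")
  if (!is.null(x$expression))
    cat(sprintf("  expression: %d TS (sens %.3f, FDP %.3f), %d HK (sens %.3f), tissue ARI %.3f\n",
                x$expression$n_ts_called, x$expression$ts_sensitivity,
                x$expression$ts_fdp, x$expression$n_hk_called,
                x$expression$hk_sensitivity, x$expression$tissue_ari))
  if (!is.null(x$sv))
    cat(sprintf("  sv: %d merged (tier1 %d, tier2 %d, tier3 %d); enrichment X2 = %.1f, p = %.3g\n",
                x$sv$n_merged, x$sv$n_tier1, x$sv$n_tier2, x$sv$n_tier3,
                x$sv$enrichment$statistic, x$sv$enrichment$p_value))
  if (!is.null(x$idmap))
    cat(sprintf("  idmap: %d genes, accuracy %.3f\n",
                x$idmap$n_genes, x$idmap$accuracy))
  invisible(x)
}
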