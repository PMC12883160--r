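make_calls <- function(...) {
  sv_calls(do.call(rbind, lapply(list(...), as.data.frame)))
}

test_that("merging chains same-type calls within 1 kb and keeps types apart", {
  calls <- make_calls(
    list(chrom = "chr1", pos = 1000, end = 2000, sv_type = "DEL",
         length = 1000, caller = "svim_asm", id = "a1"),
    list(chrom = "chr1", pos = 1500, end = 2600, sv_type = "DEL",
         length = 1100, caller = "sniffles", id = "s1"),
    list(chrom = "chr1", pos = 1400, end = 1400, sv_type = "INS",
         length = 700, caller = "svim_asm", id = "a2"),
    list(chrom = "chr1", pos = 3000, end = 3900, sv_type = "DEL",
         length = 900, caller = "manta", id = "m1"))
  m <- merge_svs(calls)
  expect_equal(nrow(m), 3)  # DEL cluster, lone INS, distant DEL
  del <- m[m$sv_type == "DEL" & m$pos == 1000, ]
  expect_equal(del$id, "a1")               # assembly member is representative
  expect_equal(del$support[[1]], c("sniffles", "svim_asm"))
  expect_equal(del$n_members, 2)
  # the 3000-start DEL is > 1000 bp from the 1500-start member: own cluster
  expect_equal(m$id[m$pos == 3000], "m1")
  expect_equal(m$id[m$sv_type == "INS"], "a2")
})

test_that("single linkage chains across intermediate members", {
  calls <- make_calls(
    list(chrom = "chr1", pos = 0, end = 100, sv_type = "DEL",
         length = 100, caller = "manta", id = "m1"),
    list(chrom = "chr1", pos = 900, end = 1000, sv_type = "DEL",
         length = 100, caller = "sniffles", id = "s1"),
    list(chrom = "chr1", pos = 1800, end = 1900, sv_type = "DEL",
         length = 100, caller = "svim_asm", id = "a1"))
  m <- merge_svs(calls)
  expect_equal(nrow(m), 1)  # 0 and 1800 linked through 900
  expect_equal(m$support[[1]], c("manta", "sniffles", "svim_asm"))
  # without the bridge the ends split
  m2 <- merge_svs(calls[-2, ])
  expect_equal(nrow(m2), 2)
})

test_that("merging is invariant to input row order", {
  set.seed(15)
  calls <- make_calls(
    list(chrom = "chr2", pos = 100, end = 700, sv_type = "DEL",
         length = 600, caller = "svim_asm", id = "a1"),
    list(chrom = "chr2", pos = 450, end = 1000, sv_type = "DEL",
         length = 550, caller = "manta", id = "m1"),
    list(chrom = "chr1", pos = 100, end = 700, sv_type = "DEL",
         length = 600, caller = "sniffles", id = "s1"),
    list(chrom = "chr2", pos = 5000, end = 5000, sv_type = "INS",
         length = 900, caller = "sniffles", id = "s2"))
  ref <- merge_svs(calls)
  for (i in 1:10) {
    perm <- calls[sample(nrow(calls)), , drop = FALSE]
    expect_equal(merge_svs(sv_calls(perm)), ref, ignore_attr = TRUE)
  }
})

test_that("tier assignment matches the exhaustive support truth table", {
  callers <- c("svim_asm", "manta", "sniffles")
  supports <- unlist(lapply(1:3, function(k)
    combn(callers, k, simplify = FALSE)), recursive = FALSE)
  grid <- expand.grid(si = seq_along(supports), type = c("DEL", "INS"),
                      len = c(300, 501, 5000), stringsAsFactors = FALSE)
  msv <- data.frame(chrom = "chr1",
                    pos = seq_len(nrow(grid)) * 10000,
                    sv_type = grid$type, length = grid$len,
                    id = paste0("v", seq_len(nrow(grid))),
                    stringsAsFactors = FALSE)
  msv$end <- ifelse(msv$sv_type == "INS", msv$pos, msv$pos + msv$length)
  msv$support <- supports[grid$si]
  has <- function(w) vapply(msv$support, function(s) w %in% s, logical(1))
  expect_obj <- suppressWarnings(classify_tier(msv))
  expected <- ifelse(
    has("svim_asm") & has("manta") & has("sniffles"), 1L,
    ifelse(has("svim_asm") & has("sniffles") &
             msv$sv_type == "INS" & msv$length > 500, 2L, 3L))
  expect_equal(expect_obj$tier, expected)
  # a 500-bp insertion with assembly + long-read support is NOT tier 2
  at500 <- suppressWarnings(classify_tier(data.frame(
    chrom = "chr1", pos = 1, end = 1, sv_type = "INS", length = 500,
    id = "x", support = I(list(c("svim_asm", "sniffles"))))))
  expect_equal(at500$tier, 3L)
  # missing assembly support warns and never escapes tier 3
  expect_warning(t3 <- classify_tier(data.frame(
    chrom = "chr1", pos = 1, end = 1, sv_type = "INS", length = 900,
    id = "y", support = I(list(c("manta", "sniffles"))))), "assembly")
  expect_equal(t3$tier, 3L)
  expect_equal(high_confidence(expect_obj)$tier,
               expected[expected != 3L])
})

test_that("TE proportion z matches hand computation and tails are symmetric", {
  # l = 600, p = 0.3: se = sqrt(0.3 * 0.7 / 600)
  se <- sqrt(0.3 * 0.7 / 600)
  got <- classify_te_proportion(c(0.3 + 5 * se, 0.3 - 5 * se, 0.3),
                                600, 0.3)
  expect_equal(got$z, c(5, -5, 0), tolerance = 1e-12)
  expect_equal(got$category, c("TE_derived", "TE_depleted", "background"))
  # hand value: p_hat = 0.9, l = 500, p = 0.3 -> z = 0.6 / sqrt(0.21/500)
  z <- classify_te_proportion(0.9, 500, 0.3)$z
  expect_equal(z, 0.6 / sqrt(0.21 / 500), tolerance = 1e-12)
  expect_equal(z, 29.277, tolerance = 1e-3)
  # boundary: z exactly at qnorm(0.975) is not significant (strict <)
  at_crit <- classify_te_proportion(0.3 + qnorm(0.975) * se, 600, 0.3)
  expect_equal(at_crit$category, "background")
  expect_error(classify_te_proportion(0.5, 100, 0), "inside")
})

test_that("TE content splits derived regions by dominant-family occupancy", {
  te <- data.frame(
    chrom = "chr1",
    start = c(100, 400, 1000, 1300, 1450),
    end   = c(400, 550, 1300, 1450, 1600),
    family_id = c("famA", "famA", "famA", "famB", "famC"))
  regions <- data.frame(chrom = "chr1",
                        start = c(100, 1000, 5000, 8000),
                        end = c(600, 1600, 5500, 8500),
                        id = c("occ", "cpx", "empty", "half"))
  # give "half" a background-level TE fraction
  te <- rbind(te, data.frame(chrom = "chr1", start = 8000, end = 8150,
                             family_id = "famD"))
  tc <- classify_te_content(regions, te, p = 0.3)
  row <- function(i) tc[tc$id == i, ]
  # occ: 450/500 TE bases, all famA -> occupancy (dominant fraction 1)
  expect_equal(row("occ")$te_bases, 450)
  expect_equal(row("occ")$p_hat, 0.9)
  expect_equal(row("occ")$category, "TE_derived_occupancy")
  expect_equal(row("occ")$dominant_fraction, 1)
  # cpx: 600/600 TE bases, famA 300/600 = 0.5 of TE bases -> complex
  expect_equal(row("cpx")$te_bases, 600)
  expect_equal(row("cpx")$dominant_family, "famA")
  expect_equal(row("cpx")$dominant_fraction, 0.5)
  expect_equal(row("cpx")$category, "TE_derived_complex")
  # empty: 0 TE bases in 500 bp -> depleted at p = 0.3
  expect_equal(row("empty")$category, "TE_depleted")
  # half: 150/500 = 0.3 exactly -> background
  expect_equal(row("half")$p_hat, 0.3)
  expect_equal(row("half")$category, "background")
  # region_length denominator flips cpx's dominant fraction base
  tc2 <- classify_te_content(regions, te, p = 0.3,
                             denominator = "region_length")
  expect_equal(tc2$dominant_fraction[tc2$id == "occ"], 0.9)
  # overlapping TE copies are not double counted in te_bases
  te_ov <- data.frame(chrom = "chr1", start = c(100, 200), end = c(350, 450),
                      family_id = c("famA", "famB"))
  tc3 <- classify_te_content(data.frame(chrom = "chr1", start = 100,
                                        end = 500, id = "ov"),
                             te_ov, p = 0.3)
  expect_equal(tc3$te_bases, 350)
  expect_error(
    classify_te_content(data.frame(chrom = "chr1", start = 100, end = 700),
                        te, p = 0.3, chrom_lengths = c(chr1 = 650)),
    "bounds")
})

test_that("overlap enrichment matches the closed-form toy and excludes INS", {
  # genome 1000 bp: exon 200, intron 100, intergenic 700 (toy annotation)
  ann <- toy_annotation()
  svs <- data.frame(chrom = "chr1",
                    pos = c(150, 250, 500, 20),
                    end = c(170, 280, 600, 20),
                    sv_type = c("DEL", "DEL", "DEL", "INS"),
                    id = paste0("v", 1:4))
  en <- overlap_enrichment(svs, ann)
  expect_equal(en$observed, c(exon = 20, intron = 30, intergenic = 100))
  expect_equal(en$df, 2)
  props <- c(0.2, 0.1, 0.7)
  x2 <- sum((en$observed - 150 * props)^2 / (150 * props))
  expect_equal(en$statistic, x2)
  expect_equal(en$p_value, exp(-x2 / 2))
  # duplicated/overlapping SVs do not double-count bases
  svs2 <- rbind(svs, data.frame(chrom = "chr1", pos = 150, end = 170,
                                sv_type = "DEL", id = "dup"))
  expect_equal(overlap_enrichment(svs2, ann)$observed, en$observed)
  # fragmenting one SV into adjacent pieces leaves the result unchanged
  svs3 <- svs
  svs3 <- rbind(svs3[-3, ],
                data.frame(chrom = "chr1", pos = c(500, 530), end = c(530, 600),
                           sv_type = "DEL", id = c("v3a", "v3b")))
  expect_equal(overlap_enrichment(svs3, ann)$observed, en$observed)
  expect_error(overlap_enrichment(svs[4, ], ann), "footprint")
})

test_that("gene linking honours strand-aware promoter windows", {
  ann <- genome_annotation(c(chr1 = 20000), list(
    gene_model("gplus", "chr1", "+", 5000, 8000, c(5000, 7000),
               c(6000, 8000)),
    gene_model("gminus", "chr1", "-", 12000, 15000, 12000, 15000)))
  svs <- data.frame(
    chrom = "chr1",
    pos = c(3500, 2500, 8100, 15500, 11500, 5500, 6200, 5900),
    end = c(3600, 2600, 8200, 15600, 11600, 5600, 6300, 6100),
    sv_type = "DEL",
    id = c("prom_plus", "too_far", "down_plus", "prom_minus", "up_minus",
           "exonic", "intronic", "span"))
  svs$length <- svs$end - svs$pos
  links <- link_genes(svs, ann)
  lk <- function(sv) links[links$sv_id == sv, ]
  # + strand: [3000, 5000) is promoter; 2 kb downstream of the end is not
  expect_equal(lk("prom_plus")$gene_id, "gplus")
  expect_equal(lk("prom_plus")$region, "promoter")
  expect_equal(nrow(lk("too_far")), 0)
  expect_equal(nrow(lk("down_plus")), 0)
  # - strand: promoter is [15000, 17000), not [10000, 12000)
  expect_equal(lk("prom_minus")$gene_id, "gminus")
  expect_equal(lk("prom_minus")$region, "promoter")
  expect_equal(nrow(lk("up_minus")), 0)
  expect_equal(lk("exonic")$region, "exon")
  expect_equal(lk("intronic")$region, "intron")
  expect_equal(lk("span")$region, "spanning")  # crosses exon/intron boundary
})

test_that("insertions link as 1-bp breakpoints and clipping respects bounds", {
  ann <- genome_annotation(c(chr1 = 10000), list(
    gene_model("g1", "chr1", "+", 500, 1500, 500, 1500)))
  svs <- data.frame(chrom = "chr1", pos = c(499, 1500, 100),
                    end = c(499, 1500, 100), sv_type = "INS",
                    length = c(800, 800, 800), id = c("in_prom", "past", "edge"))
  links <- link_genes(svs, ann)
  # promoter clipped to [0, 500): breakpoints 499 and 100 fall inside,
  # 1500 is past the gene end (half-open) and 2 kb downstream is not linked
  expect_equal(sort(links$sv_id), c("edge", "in_prom"))
  expect_true(all(links$region == "promoter"))
})

test_that("expression association flags planted downregulation and not null", {
  set.seed(16)
  n <- 60
  v <- matrix(2^rnorm(n * 6, 5, 0.3), n, 6,
              dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
  sv_genes <- paste0("g", 1:15)
  v[sv_genes, ] <- v[sv_genes, ] / 4   # planted 2-fold-squared reduction
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     tissue = rep(c("leaf", "root"), each = 3), batch = "b1")
  lm <- batch_adjust(log_transform(expr_atlas(v, meta)))
  links <- data.frame(gene_id = sv_genes, sv_id = paste0("sv", 1:15),
                      region = rep(c("exon", "promoter", "intron"), 5),
                      harbored = TRUE)
  assoc <- expression_association(links, lm, profile = tissue_means(lm))
  expect_lt(assoc$expression$p_value, 0.001)
  expect_equal(assoc$expression$direction, "SV_lower")
  expect_equal(assoc$expression$n_sv, 15)
  expect_equal(assoc$by_region$p_adj, bh_adjust(assoc$by_region$p_value))
  # identical groups: no signal
  links_null <- data.frame(gene_id = paste0("g", seq(16, 60, by = 3)),
                           sv_id = "x", region = "exon", harbored = TRUE)
  set.seed(17)
  lm_null <- lm
  lm_null$values[] <- matrix(rnorm(n * 6, 5, 0.3), n, 6)
  assoc_null <- expression_association(links_null, lm_null)
  expect_gt(assoc_null$expression$p_value, 0.01)
  # degenerate: all genes share one value -> p = 1
  lm_const <- lm
  lm_const$values[] <- 5
  assoc_const <- expression_association(links, lm_const)
  expect_equal(assoc_const$expression$p_value, 1)
})
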