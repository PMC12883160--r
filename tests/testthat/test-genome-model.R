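test_that("GFF3 coordinates convert to 0-based half-open and introns derive", {
  ann <- toy_annotation()
  tmp <- tempfile(fileext = ".gff3")
  write_gff3(ann, tmp)
  rt <- read_gff3(tmp)
  expect_equal(rt$chrom_lengths, c(chr1 = 1000))
  expect_equal(rt$genes$start, 100)
  expect_equal(rt$genes$end, 400)
  expect_equal(rt$exons$start, c(100, 300))
  expect_equal(rt$exons$end, c(200, 400))
  gm <- gene_model("gA", "chr1", "+", 100, 400, c(100, 300), c(200, 400))
  expect_equal(gene_introns(gm), data.frame(start = 200, end = 300),
               ignore_attr = TRUE)
  # single exon covering the span: no intron bases
  gm2 <- gene_model("gB", "chr1", "+", 0, 100, 0, 100)
  expect_equal(nrow(gene_introns(gm2)), 0)
})

test_that("GFF3 write/read round-trips a multi-gene annotation", {
  set.seed(11)
  ann <- random_annotation()
  while (nrow(ann$genes) < 2) ann <- random_annotation()
  tmp <- tempfile(fileext = ".gff3")
  write_gff3(ann, tmp)
  rt <- read_gff3(tmp)
  o <- order(rt$genes$gene_id)
  expect_equal(rt$chrom_lengths, ann$chrom_lengths)
  expect_equal(rt$genes[o, ], ann$genes[order(ann$genes$gene_id), ],
               ignore_attr = TRUE)
  expect_equal(rt$exons[order(rt$exons$gene_id, rt$exons$start), ],
               ann$exons[order(ann$exons$gene_id, ann$exons$start), ],
               ignore_attr = TRUE)
})

test_that("longest-transcript exon chain is selected for multi-isoform loci", {
  tmp <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 1000",
    "chr1\tx\tgene\t101\t500\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t101\t500\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tx\texon\t101\t150\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\tx\tmRNA\t101\t500\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\tx\texon\t101\t300\t.\t+\t.\tID=e2;Parent=t2",
    "chr1\tx\texon\t401\t500\t.\t+\t.\tID=e3;Parent=t2"), tmp)
  ann <- read_gff3(tmp)
  expect_equal(ann$exons$start, c(100, 400))  # t2 has the longer chain
  expect_equal(ann$exons$end, c(300, 500))
})

test_that("gene_model rejects malformed exon chains", {
  expect_error(gene_model("g", "c", "+", 10, 5, 10, 12), "start < end")
  expect_error(gene_model("g", "c", "+", 0, 100, c(0, 40), c(50, 100)),
               "overlapping")
  expect_error(gene_model("g", "c", "+", 10, 100, 0, 50), "outside")
})

test_that("genome partition matches the toy example and handles precedence", {
  part <- partition_genome(toy_annotation())
  expect_equal(part$counts["chr1", ], c(exon = 200, intron = 100,
                                        intergenic = 700))
  expect_equal(sum(part$proportions), 1)
  # annotation with no genes: everything intergenic
  empty <- genome_annotation(c(chr1 = 500), list())
  expect_equal(partition_genome(empty)$counts["chr1", "intergenic"], 500)
  # exon of one gene covering the intron of an overlapping gene counts exon
  ov <- genome_annotation(c(chr1 = 1000), list(
    gene_model("a", "chr1", "+", 100, 400, c(100, 300), c(200, 400)),
    gene_model("b", "chr1", "-", 150, 350, 150, 350)))
  expect_equal(partition_genome(ov)$counts["chr1", ],
               per_base_partition(ov)["chr1", ])
  expect_equal(unname(partition_genome(ov)$counts["chr1", "exon"]), 300)
})

test_that("genome partition equals per-base labelling on random genomes", {
  set.seed(42)
  for (i in 1:25) {
    ann <- random_annotation(6000)
    expect_equal(partition_genome(ann)$counts, per_base_partition(ann))
  }
})

test_that("overlap_bases is exact, half-open, symmetric-bounded and additive", {
  expect_equal(overlap_bases(100, 250, data.frame(start = 0, end = 150)), 50)
  expect_equal(overlap_bases(0, 100, data.frame(start = 100, end = 200)), 0)
  expect_equal(overlap_bases(10, 20, data.frame(start = 0, end = 1000)), 10)
  expect_equal(overlap_bases(5, 5, data.frame(start = 0, end = 10)), 0)
  expect_equal(overlap_bases(0, 10, data.frame(start = integer(),
                                               end = integer())), 0)
  set.seed(7)
  for (i in 1:50) {
    s <- sample(0:500, 1); e <- s + sample(0:300, 1)
    regions <- data.frame(start = sample(0:600, 5))
    regions$end <- regions$start + sample(1:200, 5)
    got <- overlap_bases(s, e, regions)
    expect_equal(got, per_base_overlap(s, e, regions))
    expect_gte(got, 0)
    expect_lte(got, e - s)
  }
})

test_that("RepeatMasker .out round-trips with 1-based closed conversion", {
  te <- data.frame(chrom = "chr1", start = 999, end = 1299,
                   family_id = "rnd-1_family-5", class_label = "LTR/Gypsy")
  tmp <- tempfile(fileext = ".out")
  write_repeatmasker_out(te, tmp)
  rt <- read_repeatmasker_out(tmp)
  expect_equal(rt$start, 999)
  expect_equal(rt$end, 1299)
  expect_equal(rt$end - rt$start, 300)
  expect_equal(rt$family_id, "rnd-1_family-5")
  # raw 1-based closed row 1000..1299 spans 300 bases
  raw <- readLines(tmp)[4]
  expect_match(raw, " 1000 1299 ")
})

test_that("VCF SV reader applies coordinate conventions and filters", {
  tmp <- tempfile(fileext = ".vcf")
  svs <- sv_calls(data.frame(
    chrom = c("chr1", "chr1", "chr1"), pos = c(100, 500, 40),
    end = c(200, 500, 60), sv_type = c("DEL", "INS", "DEL"),
    length = c(100, 800, 20), caller = "svim_asm",
    id = c("d1", "i1", "tiny")))
  write_vcf_svs(svs, tmp, c(chr1 = 10000))
  rt <- read_vcf_svs(tmp, "svim_asm")
  expect_equal(nrow(rt), 2)  # 20-bp call dropped by the 50-bp floor
  del <- rt[rt$sv_type == "DEL", ]
  expect_equal(del$pos, 100); expect_equal(del$end, 200)
  expect_equal(del$length, 100)
  ins <- rt[rt$sv_type == "INS", ]
  expect_equal(ins$pos, 500); expect_equal(ins$end, 500)
  expect_equal(ins$length, 800)
})

test_that("VCF records without SVTYPE are skipped with a warning", {
  tmp <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\ta\tN\t<DEL>\t.\tPASS\tSVLEN=-100;END=200",
    "chr1\t901\tb\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-100;END=1000"), tmp)
  expect_warning(rt <- read_vcf_svs(tmp, "x"), "SVTYPE")
  expect_equal(nrow(rt), 1)
  expect_equal(rt$pos, 900)
})
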