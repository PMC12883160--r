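#' @import methods
#' @importFrom stats median sd var cor cutree hclust dist rnorm runif rbinom
#'   pnorm pt p.adjust wilcox.test chisq.test setNames quantile complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# All internal coordinates are 0-based half-open [start, end); conversion to
# and from 1-based closed conventions happens only in the readers/writers.

#' Construct a gene model
#'
#' A gene model is a gene span plus a disjoint, sorted exon chain (the longest
#' transcript's exons), all in 0-based half-open coordinates.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end Gene span, 0-based half-open.
#' @param exon_starts,exon_ends Integer vectors of exon coordinates
#'   (0-based half-open), sorted, non-overlapping, contained in the span.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, exon_starts, exon_ends) {
  stopifnot(length(gene_id) == 1L, nzchar(gene_id), strand %in% c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (start >= end) stop("gene span must satisfy start < end: ", gene_id)
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) < 1L)
    stop("exon coordinate vectors must be non-empty and equal length: ", gene_id)
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  if (any(exon_starts >= exon_ends)) stop("empty exon in gene ", gene_id)
  if (any(exon_starts[-1] < exon_ends[-length(exon_ends)]))
    stop("overlapping exons in gene ", gene_id)
  if (exon_starts[1] < start || exon_ends[length(exon_ends)] > end)
    stop("exon outside gene span in gene ", gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = start, end = end,
                 exon_starts = exon_starts, exon_ends = exon_ends),
            class = "gene_model")
}

#' Intron intervals of a gene model
#'
#' @param gm A [gene_model()].
#' @return Data frame with columns `start`, `end` (0-based half-open); zero
#'   rows when the exon chain covers the whole span.
#' @export
gene_introns <- function(gm) {
  k <- length(gm$exon_starts)
  pieces <- list(
    data.frame(start = gm$start, end = gm$exon_starts[1]),
    if (k > 1L) data.frame(start = gm$exon_ends[-k], end = gm$exon_starts[-1]),
    data.frame(start = gm$exon_ends[k], end = gm$end)
  )
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  out[out$start < out$end, , drop = FALSE]
}

#' Construct a genome annotation
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param genes List of [gene_model()] objects.
#' @return An object of class `genome_annotation` with elements
#'   `chrom_lengths`, `genes` (data frame), `exons` (data frame).
#' @export
genome_annotation <- function(chrom_lengths, genes) {
  stopifnot(!is.null(names(chrom_lengths)), all(nzchar(names(chrom_lengths))))
  chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  gdf <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = g$start, end = g$end, stringsAsFactors = FALSE)))
  edf <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = g$exon_starts, end = g$exon_ends,
               stringsAsFactors = FALSE)))
  if (is.null(gdf)) {
    gdf <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer())
    edf <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer())
  } else {
    if (anyDuplicated(gdf$gene_id)) stop("duplicate gene ids in annotation")
    bad <- !(gdf$chrom %in% names(chrom_lengths)) |
      gdf$end > chrom_lengths[gdf$chrom] | gdf$start < 0
    if (any(bad)) stop("gene span outside chromosome: ",
                       paste(gdf$gene_id[bad], collapse = ", "))
  }
  structure(list(chrom_lengths = chrom_lengths, genes = gdf, exons = edf),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp,",
      nrow(x$genes), "gene(s)\n")
  invisible(x)
}

.as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

.gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Read a GFF3 file into a genome annotation
#'
#' Coordinates are converted from GFF3's 1-based closed convention to 0-based
#' half-open. For multi-transcript loci the exon chain of the transcript with
#' the largest summed exon length is kept (ties broken by transcript id).
#' Chromosome lengths come from `##sequence-region` pragmas when present,
#' otherwise from the maximal feature end per chromosome.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon features.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  df <- as.data.frame(gr)
  # chromosome lengths from pragmas
  lines <- readLines(path)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  chrom_lengths <- NULL
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "\\s+")
    chrom_lengths <- setNames(
      vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
      vapply(parts, function(p) p[2], character(1)))
  }
  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), ]
  exons <- df[df$type == "exon", ]
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1]] else NA_character_, character(1))
  mrnas$parent <- first_parent(mrnas$Parent)
  exons$parent <- first_parent(exons$Parent)
  models <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    tx <- mrnas[!is.na(mrnas$parent) & mrnas$parent == gid, ]
    if (nrow(tx) == 0L) {
      ex <- exons[!is.na(exons$parent) & exons$parent == gid, ]
    } else {
      exlen <- vapply(tx$ID, function(tid) {
        e <- exons[exons$parent == tid, ]
        sum(e$end - e$start + 1)
      }, numeric(1))
      best <- tx$ID[order(-exlen, tx$ID)][1]
      ex <- exons[exons$parent == best, ]
    }
    if (nrow(ex) == 0L)  # exonless gene: treat whole span as one exon
      ex <- genes[i, , drop = FALSE]
    gene_model(gid, as.character(genes$seqnames[i]),
               as.character(genes$strand[i]),
               genes$start[i] - 1L, genes$end[i],
               ex$start - 1L, ex$end)
  })
  if (is.null(chrom_lengths)) {
    mx <- tapply(df$end, as.character(df$seqnames), max)
    chrom_lengths <- setNames(as.numeric(mx), names(mx))
  }
  genome_annotation(chrom_lengths, models)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_gff3()] for the fields the pipeline uses (one mRNA per
#' gene carrying the retained exon chain).
#'
#' @param ann A [genome_annotation()].
#' @param path Output path.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(ann$chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       names(ann$chrom_lengths)[i],
                       as.integer(ann$chrom_lengths[i])), con)
  g <- ann$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    rows <- c(
      sprintf("%s\tvescatlas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i], gid),
      sprintf("%s\tvescatlas\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i], gid, gid),
      sprintf("%s\tvescatlas\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.e%d;Parent=%s.t1",
              g$chrom[i], ex$start + 1L, ex$end, g$strand[i], gid,
              seq_len(nrow(ex)), gid))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Partition a genome into exon, intron and intergenic base counts
#'
#' Bases covered by any exon count as exon; bases inside a gene span but not
#' in any exon count as intron (exon takes precedence over intron where gene
#' models overlap); the remainder is intergenic. Counts are disjoint and
#' exhaustive per chromosome.
#'
#' @param ann A [genome_annotation()].
#' @return List with `counts` (chromosome x category matrix) and
#'   `proportions` (genome-wide, sums to 1).
#' @export
partition_genome <- function(ann) {
  chroms <- names(ann$chrom_lengths)
  counts <- matrix(0, nrow = length(chroms), ncol = 3,
                   dimnames = list(chroms, c("exon", "intron", "intergenic")))
  for (ch in chroms) {
    len <- ann$chrom_lengths[[ch]]
    e <- ann$exons[ann$exons$chrom == ch, ]
    g <- ann$genes[ann$genes$chrom == ch, ]
    if (nrow(g) == 0L) { counts[ch, "intergenic"] <- len; next }
    er <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    gr <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    exon_bp <- sum(IRanges::width(er))
    intron_bp <- sum(IRanges::width(BiocGenerics::setdiff(gr, er)))
    counts[ch, ] <- c(exon_bp, intron_bp, len - exon_bp - intron_bp)
  }
  tot <- colSums(counts)
  list(counts = counts, proportions = tot / sum(tot))
}

#' Count bases shared between an interval and a set of regions
#'
#' Overlapping regions in `regions` are flattened first so no base is counted
#' twice. Intervals are 0-based half-open; adjacent intervals share no bases.
#'
#' @param start,end Query interval (0-based half-open), single values.
#' @param regions Data frame with `start`, `end` columns (same chromosome as
#'   the query; chromosome bookkeeping is the caller's).
#' @return Number of shared bases (>= 0).
#' @export
overlap_bases <- function(start, end, regions) {
  stopifnot(length(start) == 1L, length(end) == 1L, start <= end)
  if (is.null(regions) || nrow(regions) == 0L || start == end) return(0)
  q <- IRanges::IRanges(start + 1L, end)
  r <- IRanges::reduce(IRanges::IRanges(regions$start + 1L, regions$end))
  sum(IRanges::width(BiocGenerics::intersect(q, r)))
}

#' Read a RepeatMasker .out file
#'
#' RepeatMasker coordinates are 1-based closed; they are converted to 0-based
#' half-open. The repeat name column becomes `family_id` and the class/family
#' column becomes `class_label`.
#'
#' @param path Path to a RepeatMasker `.out` file (3 header lines then a
#'   whitespace-separated table).
#' @return Data frame with columns `chrom`, `start`, `end`, `family_id`,
#'   `class_label`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  body <- lines[-seq_len(min(3L, length(lines)))]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      family_id = character(), class_label = character()))
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 11L)
  if (length(bad)) stop("malformed RepeatMasker line ", bad[1] + 3L, " in ", path)
  data.frame(
    chrom = vapply(fields, `[[`, character(1), 5L),
    start = as.integer(vapply(fields, `[[`, character(1), 6L)) - 1L,
    end = as.integer(vapply(fields, `[[`, character(1), 7L)),
    family_id = vapply(fields, `[[`, character(1), 10L),
    class_label = vapply(fields, `[[`, character(1), 11L),
    stringsAsFactors = FALSE)
}

#' Write a TE track in RepeatMasker .out layout
#'
#' @param te Data frame with `chrom`, `start`, `end`, `family_id`,
#'   `class_label` (0-based half-open).
#' @param path Output path.
#' @export
write_repeatmasker_out <- function(te, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""), con)
  if (nrow(te))
    writeLines(sprintf(" 1000  0.0  0.0  0.0  %s %d %d (0) + %s %s 1 %d (0) %d",
                       te$chrom, te$start + 1L, te$end, te$family_id,
                       te$class_label, te$end - te$start, seq_len(nrow(te))), con)
  invisible(path)
}

#' Read/write BED intervals
#'
#' BED is already 0-based half-open; no conversion is applied. Extra columns
#' beyond the first three are kept as-is.
#'
#' @param path File path.
#' @return Data frame with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' @rdname read_bed
#' @param df Data frame with `chrom`, `start`, `end` and optional extra columns.
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a TSV with header
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read structural-variant calls from a VCF
#'
#' VCF POS is 1-based; internally `pos = POS - 1` (0-based). For deletions
#' (and other span types) `end` comes from the END INFO key, falling back to
#' `pos + |SVLEN|`; for insertions `end = pos` and the length is `|SVLEN|`.
#' Records without SVTYPE are skipped with a warning. Calls shorter than
#' `min_length` (default 50 bp, the smallest SV size retained) are dropped.
#'
#' @param path Path to a VCF 4.x file with SVTYPE/SVLEN/END INFO keys.
#' @param caller Caller name attached to every record.
#' @param min_length Minimum retained SV length in bp.
#' @return Data frame of class `sv_calls`: `chrom`, `pos`, `end`, `sv_type`,
#'   `length`, `caller`, `id`.
#' @export
read_vcf_svs <- function(path, caller, min_length = 50) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  inf <- VariantAnnotation::info(v)
  n <- length(rr)
  if (n == 0L)
    return(sv_calls(data.frame(chrom = character(), pos = integer(),
                               end = integer(), sv_type = character(),
                               length = integer(), caller = character(),
                               id = character())))
  svtype <- as.character(inf$SVTYPE)
  svlen <- inf$SVLEN
  if (is(svlen, "list") || is(svlen, "List"))
    svlen <- vapply(svlen, function(x) if (length(x)) as.numeric(x[[1]]) else NA_real_,
                    numeric(1))
  endv <- as.numeric(inf$END)
  pos <- GenomicRanges::start(rr) - 1L
  keep <- !is.na(svtype) & nzchar(svtype)
  if (any(!keep))
    warning(sum(!keep), " record(s) without SVTYPE skipped in ", path)
  len <- abs(svlen)
  end0 <- ifelse(svtype == "INS", pos,
                 ifelse(!is.na(endv), endv, pos + len))
  len <- ifelse(svtype == "INS", len, end0 - pos)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                   pos = as.integer(pos), end = as.integer(end0),
                   sv_type = svtype, length = as.integer(len),
                   caller = caller, id = names(rr) %||% as.character(seq_len(n)),
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  df <- df[df$length >= min_length, , drop = FALSE]
  rownames(df) <- NULL
  sv_calls(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structural-variant call table
#'
#' @param df Data frame with columns `chrom`, `pos`, `end`, `sv_type`,
#'   `length`, `caller` (and optionally `id`).
#' @return The validated data frame with class `sv_calls`.
#' @export
sv_calls <- function(df) {
  need <- c("chrom", "pos", "end", "sv_type", "length", "caller")
  stopifnot(all(need %in% names(df)))
  if (nrow(df)) {
    stopifnot(all(df$pos <= df$end), all(df$length >= 0))
    if (!"id" %in% names(df)) df$id <- paste0("sv", seq_len(nrow(df)))
  } else if (!"id" %in% names(df)) df$id <- character()
  class(df) <- c("sv_calls", "data.frame")
  df
}

#' Write SV calls as a minimal VCF 4.2
#'
#' Inverse of [read_vcf_svs()] for the fields the pipeline uses.
#'
#' @param svs An [sv_calls()] data frame (0-based coordinates).
#' @param path Output path.
#' @param chrom_lengths Optional named vector for contig header lines.
#' @export
write_vcf_svs <- function(svs, path, chrom_lengths = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=vescatlas",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">")
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(hdr, con)
  if (nrow(svs)) {
    svlen <- ifelse(svs$sv_type == "DEL", -svs$length, svs$length)
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", svs$sv_type,
                    as.integer(svlen), as.integer(svs$end))
    writeLines(sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s",
                       svs$chrom, svs$pos + 1L, svs$id, svs$sv_type, info), con)
  }
  invisible(path)
}
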