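#' Specification for a toy genome
#'
#' Describes a small multi-chromosome genome of regularly spaced,
#' strand-alternating gene models, used as the scaffold for planted
#' chromatin landscapes. Stands in for a real genome annotation so that all
#' pipeline stages can be exercised without downloads.
#'
#' @param chrom_lengths Named integer vector (or list of `(name, length)`
#'   pairs) of chromosome lengths in bp.
#' @param n_genes Total gene count, laid out left to right across
#'   chromosomes in order.
#' @param gene_length Gene span, bp.
#' @param intergenic_spacing Gap between consecutive genes (and before the
#'   first), bp.
#' @param utr5_length 5' UTR length: the coding start sits this far
#'   downstream of the TSS, bp.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   output (including the GFF3 serialization).
#' @return An object of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(chrom_lengths = c(chr1 = 150000L, chr2 = 150000L),
                            n_genes = 80L, gene_length = 2400L,
                            intergenic_spacing = 1200L, utr5_length = 300L,
                            seed = 1L) {
  if (is.list(chrom_lengths))
    chrom_lengths <- stats::setNames(
      vapply(chrom_lengths, function(x) as.integer(x[[2L]]), integer(1)),
      vapply(chrom_lengths, function(x) as.character(x[[1L]]), character(1)))
  if (any(chrom_lengths <= 0L) || n_genes <= 0L || gene_length <= 0L ||
      intergenic_spacing < 0L)
    stop("all lengths and counts must be positive")
  if (utr5_length >= gene_length / 2)
    stop("utr5_length must be < gene_length / 2")
  structure(list(chrom_lengths = chrom_lengths,
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 intergenic_spacing = as.integer(intergenic_spacing),
                 utr5_length = as.integer(utr5_length),
                 seed = as.integer(seed)),
            class = "toy_genome_spec")
}

#' Build a toy genome annotation
#'
#' Genes are placed left to right with fixed spacing, alternating strand.
#' Each gene has one mRNA with two exons separated by a 150 bp intron, a
#' CDS starting `utr5_length` into the transcript and stopping 150 bp before
#' its 3' end, and a `shared_isoform` flag (90% `TRUE`, drawn from the
#' spec seed) marking genes whose model is consistent across samples and
#' therefore eligible for aggregate analyses. TSS/CSS/TES are stored as
#' 0-based base coordinates of the actual genomic base (for `-` strand
#' genes the TSS is the rightmost transcribed base).
#'
#' @param spec A [toy_genome_spec()].
#' @return Object of class `genome_annotation`: a list with data.tables
#'   `chroms` (chrom, length), `genes` (gene_id, chrom, strand, start, end,
#'   tss, css, tes, shared_isoform), `exons` and `cds` (gene_id, chrom,
#'   start, end), all 0-based half-open.
#' @export
build_toy_genome <- function(spec = toy_genome_spec()) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  set.seed(spec$seed)
  pitch <- spec$gene_length + spec$intergenic_spacing
  cap <- pmax(0L, (spec$chrom_lengths - spec$intergenic_spacing) %/% pitch)
  if (sum(cap) < spec$n_genes)
    stop("genes do not fit: chromosome '",
         names(spec$chrom_lengths)[length(spec$chrom_lengths)],
         "' overflows (capacity ", sum(cap), " < ", spec$n_genes, " genes)")
  per_chrom <- pmin(cap, pmax(0L, spec$n_genes -
                                c(0L, cumsum(head(cap, -1L)))))
  rows <- list()
  gi <- 0L
  for (ci in seq_along(spec$chrom_lengths)) {
    if (per_chrom[ci] == 0L) next
    k <- seq_len(per_chrom[ci]) - 1L
    gstart <- spec$intergenic_spacing + k * pitch
    rows[[ci]] <- data.table(
      gene_id = sprintf("G%04d", gi + seq_len(per_chrom[ci])),
      chrom = names(spec$chrom_lengths)[ci],
      strand = rep_len(c("+", "-"), per_chrom[ci]),
      start = gstart, end = gstart + spec$gene_length)
    gi <- gi + per_chrom[ci]
  }
  genes <- rbindlist(rows)
  u <- spec$utr5_length
  genes[, `:=`(
    tss = ifelse(strand == "+", start, end - 1L),
    css = ifelse(strand == "+", start + u, end - 1L - u),
    tes = ifelse(strand == "+", end - 1L, start))]
  genes[, shared_isoform := runif(.N) < 0.9]

  ## two exons around a 150 bp intron placed 1000 bp into the transcript;
  ## genes too short for that layout get a single exon
  ex1 <- 1000L; intron <- 150L
  exons <- genes[, {
    if (end - start < ex1 + intron + 100L) {
      list(start = start, end = end, exon_number = 1L)
    } else if (strand == "+") {
      list(start = c(start, start + ex1 + intron),
           end = c(start + ex1, end), exon_number = 1:2)
    } else {
      list(start = c(end - ex1, start),
           end = c(end, end - ex1 - intron), exon_number = 1:2)
    }
  }, by = .(gene_id, chrom, strand)]
  setorder(exons, chrom, start)

  ## CDS: css .. 150 bp short of the transcript 3' end, clipped to exons
  stop_off <- 150L
  cds <- genes[, {
    if (strand == "+") list(cs = css, ce = end - stop_off)
    else list(cs = start + stop_off, ce = css + 1L)
  }, by = .(gene_id, chrom)]
  cds <- exons[cds, on = "gene_id", allow.cartesian = TRUE][
    , .(chrom, start = pmax(start, cs), end = pmin(end, ce)),
    by = .(gene_id, exon_number)][start < end]
  cds <- cds[, .(gene_id, chrom, start, end)]
  setorder(cds, chrom, start)

  structure(list(
    chroms = data.table(chrom = names(spec$chrom_lengths),
                        length = as.integer(spec$chrom_lengths)),
    genes = genes[, .(gene_id, chrom, strand, start, end, tss, css, tes,
                      shared_isoform)],
    exons = exons[, .(gene_id, chrom, strand, start, end, exon_number)],
    cds = cds,
    spec = spec), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d chromosome(s), %d genes (%d shared-isoform)\n",
              nrow(x$chroms), nrow(x$genes), sum(x$genes$shared_isoform)))
  invisible(x)
}

#' Write a genome annotation as GFF3
#'
#' Emits gene/mRNA/exon/CDS features (1-based inclusive, per GFF3) through
#' rtracklayer. The `shared_isoform` flag is carried as an attribute on the
#' gene features so [read_annotation_gff3()] can restore it.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes
  feats <- list(
    data.table(chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, type = "gene", ID = g$gene_id,
               Parent = NA_character_,
               shared_isoform = tolower(as.character(g$shared_isoform))),
    data.table(chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, type = "mRNA",
               ID = paste0(g$gene_id, ".1"), Parent = g$gene_id,
               shared_isoform = NA_character_),
    annotation$exons[g, on = "gene_id"][, data.table(
      chrom = chrom, start = start, end = end, strand = strand,
      type = "exon", ID = paste0(gene_id, ".1.exon", exon_number),
      Parent = paste0(gene_id, ".1"), shared_isoform = NA_character_)],
    annotation$cds[g, on = "gene_id"][, data.table(
      chrom = chrom, start = start, end = end, strand = strand,
      type = "CDS", ID = paste0(gene_id, ".1.cds"),
      Parent = paste0(gene_id, ".1"), shared_isoform = NA_character_)])
  dt <- rbindlist(feats)
  setorder(dt, chrom, start, type)
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = dt$strand)
  S4Vectors::mcols(gr)$type <- dt$type
  S4Vectors::mcols(gr)$ID <- dt$ID
  S4Vectors::mcols(gr)$Parent <- dt$Parent
  S4Vectors::mcols(gr)$shared_isoform <- dt$shared_isoform
  S4Vectors::mcols(gr)$phase <- ifelse(dt$type == "CDS", 0L, NA_integer_)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a GFF3 annotation written by [write_annotation_gff3()]
#'
#' @param path GFF3 path.
#' @param chrom_lengths Optional chromosome table; if omitted, chromosome
#'   lengths are taken as the maximum annotated end per chromosome.
#' @return A `genome_annotation`.
#' @export
read_annotation_gff3 <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   ID = as.character(gr$ID))
  par <- gr$Parent
  dt$parent <- vapply(seq_along(par), function(i) {
    p <- par[[i]]
    if (length(p) == 0L || p == "") NA_character_ else as.character(p[[1L]])
  }, character(1))
  shared <- if ("shared_isoform" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$shared_isoform) else rep(NA_character_, length(gr))
  gdt <- dt[type == "gene"]
  genes <- data.table(gene_id = gdt$ID, chrom = gdt$chrom,
                      strand = gdt$strand, start = gdt$start, end = gdt$end,
                      shared_isoform = shared[dt$type == "gene"] == "true")
  genes[is.na(shared_isoform), shared_isoform := TRUE]
  mrna_gene <- stats::setNames(dt[type == "mRNA"]$parent,
                               dt[type == "mRNA"]$ID)
  exons <- dt[type == "exon",
              .(gene_id = mrna_gene[parent], chrom, strand, start, end)]
  setorder(exons, gene_id, start)
  exons[, exon_number := if (strand[1L] == "+") seq_len(.N) else rev(seq_len(.N)),
        by = gene_id]
  cds <- dt[type == "CDS", .(gene_id = mrna_gene[parent], chrom, start, end)]
  setorder(cds, chrom, start)
  cds_5p <- cds[, .(cs = min(start), ce = max(end)), by = gene_id]
  genes <- cds_5p[genes, on = "gene_id"]
  genes[, `:=`(tss = ifelse(strand == "+", start, end - 1L),
               tes = ifelse(strand == "+", end - 1L, start),
               css = ifelse(strand == "+", cs, ce - 1L))]
  if (is.null(chrom_lengths)) {
    chroms <- dt[, .(length = max(end)), by = chrom]
  } else {
    cl <- chrom_length_vec(chrom_lengths)
    chroms <- data.table(chrom = names(cl), length = as.integer(cl))
  }
  setorder(genes, chrom, start)
  structure(list(chroms = chroms,
                 genes = genes[, .(gene_id, chrom, strand, start, end, tss,
                                   css, tes, shared_isoform)],
                 exons = exons[, .(gene_id, chrom, strand, start, end,
                                   exon_number)],
                 cds = cds, spec = NULL),
            class = "genome_annotation")
}
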