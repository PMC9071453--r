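# In-code fixtures: inline GTF construction and direct alignment
# builders, so no binary files are shipped.

gtfExonLine <- function(chrom, start, end, strand, gene, tx,
                        biotype = "protein_coding", tag = NULL,
                        symbol = gene) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_type "%s";',
                   gene, tx, symbol, biotype)
  if (!is.null(tag)) attrs <- paste0(attrs, sprintf(' tag "%s";', tag))
  paste(chrom, "test", "exon", start, end, ".", strand, ".", attrs,
        sep = "\t")
}

writeGtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

toyAnnotation <- function(lines) loadAnnotation(writeGtf(lines))

# Build a GAlignments from block specifications.
# blocks: list of 2-column matrices (start, end per block)
makeAlignments <- function(chrom, blocks, strand, ids = NULL, mapq = 60L,
                           flag = NULL, seqlengths = c(chr1 = 1000000L)) {
  n <- length(blocks)
  if (is.null(ids)) ids <- sprintf("read%04d", seq_len(n))
  cigar <- vapply(blocks, function(b) {
    b <- matrix(b, ncol = 2)
    w <- b[, 2] - b[, 1] + 1L
    g <- if (nrow(b) > 1L) b[-1L, 1L] - b[-nrow(b), 2L] - 1L else integer()
    p <- paste0(w[1L], "M")
    if (length(g)) p <- paste0(p, paste0(g, "N", w[-1L], "M", collapse = ""))
    p
  }, character(1))
  pos <- vapply(blocks, function(b) as.integer(matrix(b, ncol = 2)[1L, 1L]),
                integer(1))
  chromv <- rep_len(chrom, n)
  strandv <- rep_len(strand, n)
  gal <- GenomicAlignments::GAlignments(
    seqnames = factor(chromv, levels = names(seqlengths)),
    pos = pos, cigar = cigar,
    strand = factor(strandv, levels = c("+", "-", "*")),
    names = ids, seqlengths = seqlengths)
  S4Vectors::mcols(gal)$flag <- if (is.null(flag))
    ifelse(strandv == "-", 16L, 0L) else as.integer(rep_len(flag, n))
  S4Vectors::mcols(gal)$mapq <- as.integer(rep_len(mapq, n))
  gal
}

# Two-gene toy annotation used across quantification tests:
# A: + strand, exons 1001-2000 and 3001-4000 (intron 2001-3000)
# B: + strand, single exon 9001-10000
toyTwoGeneAnnotation <- function() {
  sanitizeAnnotation(toyAnnotation(c(
    gtfExonLine("chr1", 1001, 2000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 3001, 4000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 9001, 10000, "+", "B", "B.t1"))))
}
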