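## Annotation sanitization: supplemental-gene merge, readthrough-transcript
## removal, de-overlap of genomic space claimed by >=2 genes, and intron
## derivation. Gene spans are always the hull of surviving transcripts.

#' Merge supplemental genes into a primary annotation
#'
#' Adds every supplemental gene absent from the primary annotation (keyed
#' on `gene_id`, optionally also matching by symbol) verbatim; genes
#' present in both are kept as in the primary. Coordinate conflicts for a
#' shared id defer to the primary and are logged.
#'
#' @param primary,supplement [GeneAnnotation-class] objects.
#' @param key `"gene_id"` (default) or `"gene_id_or_symbol"`: a
#'   supplemental gene already represented under either key is skipped.
#' @return a [GeneAnnotation-class]; `metadata()$added_genes` lists the ids
#'   added and `metadata()$merge_conflicts` the shared ids whose
#'   coordinates differ between the two inputs.
#' @export
mergeSupplementalGenes <- function(primary, supplement,
                                   key = c("gene_id", "gene_id_or_symbol")) {
  stopifnot(is(primary, "GeneAnnotation"), is(supplement, "GeneAnnotation"))
  key <- match.arg(key)
  pg <- primary@genes
  sg <- supplement@genes
  present <- names(sg) %in% names(pg)
  if (key == "gene_id_or_symbol")
    present <- present | mcols(sg)$symbol %in% mcols(pg)$symbol

  shared <- names(sg)[names(sg) %in% names(pg)]
  conflict <- shared[vapply(shared, function(id) {
    a <- pg[id]; b <- sg[id]
    !(as.character(seqnames(a)) == as.character(seqnames(b)) &&
      start(a) == start(b) && end(a) == end(b) &&
      as.character(strand(a)) == as.character(strand(b)))
  }, logical(1))]

  addIds <- names(sg)[!present]
  if (!length(addIds)) {
    out <- primary
  } else {
    addTx <- names(supplement@txGene)[supplement@txGene %in% addIds]
    genes <- suppressWarnings(c(pg, sg[addIds]))
    exons <- suppressWarnings(c(primary@exons, supplement@exons[addTx]))
    txGene <- c(primary@txGene, supplement@txGene[addTx])
    txTags <- suppressWarnings(c(primary@txTags, supplement@txTags[addTx]))
    out <- new("GeneAnnotation", genes = genes, exons = exons,
               txGene = txGene, txTags = txTags)
    metadata(out) <- metadata(primary)
  }
  metadata(out)$added_genes <- addIds
  metadata(out)$merge_conflicts <- conflict
  out
}

#' Drop readthrough-tagged transcripts
#'
#' Removes every transcript carrying the readthrough tag, recomputes gene
#' spans as the hull of the surviving transcripts, and drops (with a
#' report) genes left with no transcripts. Readthrough transcripts span
#' two adjacent genes and would otherwise make large regions appear shared
#' between them.
#'
#' @param ann a [GeneAnnotation-class].
#' @param tag the tag marking readthrough transcripts
#'   (default `"readthrough_transcript"`, the gencode convention).
#' @return a [GeneAnnotation-class]; `metadata()$dropped_readthrough` and
#'   `metadata()$dropped_genes` record the removals.
#' @export
dropReadthroughTranscripts <- function(ann, tag = "readthrough_transcript") {
  stopifnot(is(ann, "GeneAnnotation"))
  tagged <- names(ann@txTags)[vapply(as.list(ann@txTags),
                                     function(x) tag %in% x, logical(1))]
  if (!length(tagged)) {
    metadata(ann)$dropped_readthrough <- character()
    metadata(ann)$dropped_genes <- character()
    return(ann)
  }
  keepTx <- setdiff(names(ann@exons), tagged)
  txGene <- ann@txGene[keepTx]
  emptied <- setdiff(names(ann@genes), unname(txGene))
  geneAttr <- data.frame(gene_id = names(ann@genes),
                         symbol = mcols(ann@genes)$symbol,
                         biotype = mcols(ann@genes)$biotype,
                         stringsAsFactors = FALSE)
  out <- assembleAnnotation(ann@exons[keepTx], txGene,
                            ann@txTags[keepTx], geneAttr)
  metadata(out) <- metadata(ann)
  metadata(out)$dropped_readthrough <- tagged
  metadata(out)$dropped_genes <- emptied
  out
}

## Bases covered by >= 2 gene spans, as a GRanges. Blind mode pools both
## strands into one genomic space (strand "*"); aware mode computes shared
## space per strand.
sharedRegions <- function(spans, strandMode = c("blind", "aware")) {
  strandMode <- match.arg(strandMode)
  sliceShared <- function(gr, strandLabel) {
    if (!length(gr)) return(GRanges())
    cov <- coverage(granges(gr))
    irl <- as(IRanges::slice(cov, lower = 2L, rangesOnly = TRUE),
              "IRangesList")
    out <- as(irl, "GRanges")
    strand(out) <- strandLabel
    out
  }
  if (strandMode == "blind") {
    u <- granges(spans)
    strand(u) <- "*"
    sliceShared(u, "*")
  } else {
    c(sliceShared(spans[strand(spans) == "+"], "+"),
      sliceShared(spans[strand(spans) == "-"], "-"))
  }
}

## Per-gene subtraction of a removal set from a named GRangesList.
subtractByGene <- function(grl, removal, ignoreStrand) {
  if (!length(removal)) return(reduce(grl))
  u <- unlist(grl, use.names = FALSE)
  owner <- rep(names(grl), lengths(grl))
  pieces <- GenomicRanges::subtract(u, removal, ignore.strand = ignoreStrand)
  flat <- unlist(pieces, use.names = FALSE)
  owner2 <- rep(owner, S4Vectors::elementNROWS(pieces))
  out <- reduce(split(flat, factor(owner2, levels = names(grl))))
  names(out) <- names(grl)
  out
}

#' Remove genomic space claimed by two or more genes
#'
#' Computes, per chromosome (and per strand when `strandMode = "aware"`),
#' the set of bases covered by two or more gene spans and subtracts it
#' from every gene's annotated space. Removed bases are recorded in the
#' audit slot. Overlap is assessed on gene spans, so an exon of one gene
#' inside an intron of another is removed from both genes' sets.
#'
#' @param ann a [GeneAnnotation-class]; readthrough transcripts should
#'   already have been dropped (see [dropReadthroughTranscripts()]).
#' @param strandMode `"blind"` (default: both strands are one genomic
#'   space) or `"aware"` (antisense overlaps are retained).
#' @return a [SanitizedAnnotation-class] with the exonic sets populated;
#'   call [deriveIntronRegions()] to populate the intronic sets and drop
#'   emptied genes (or use [sanitizeAnnotation()] for the full pipeline).
#' @export
removeSharedRegions <- function(ann, strandMode = c("blind", "aware")) {
  stopifnot(is(ann, "GeneAnnotation"))
  strandMode <- match.arg(strandMode)
  spans <- ann@genes
  shared <- sharedRegions(spans, strandMode)
  ignore <- strandMode == "blind"

  ids <- names(spans)
  if (length(ids)) {
    exAll <- unlist(ann@exons, use.names = FALSE)
    exGene <- rep(unname(ann@txGene[names(ann@exons)]), lengths(ann@exons))
    exonUnion <- reduce(split(exAll, factor(exGene, levels = ids)))
    names(exonUnion) <- ids
    exonic <- subtractByGene(exonUnion, shared, ignore)
  } else {
    exonUnion <- GRangesList()
    exonic <- GRangesList()
  }
  genes <- spans
  if (length(genes)) mcols(genes)$intronless <- NA
  emptyList <- GRangesList(setNames(rep(list(GRanges()), length(ids)), ids))
  md <- metadata(ann)
  out <- new("SanitizedAnnotation",
             genes = genes, exonic = exonic, intronic = emptyList,
             removedShared = shared,
             droppedReadthrough = md$dropped_readthrough %||% character(),
             droppedGenes = md$dropped_genes %||% character(),
             strandMode = strandMode)
  metadata(out)$exon_union <- exonUnion
  out
}

#' Derive per-gene intronic regions
#'
#' Populates the intronic interval sets: per gene, the gene span minus the
#' union of all surviving transcripts' exons minus the removed shared
#' space. Genes whose intronic set is empty are flagged intronless; genes
#' with no surviving exonic or intronic bases are dropped and reported.
#'
#' @param sann a [SanitizedAnnotation-class] from [removeSharedRegions()].
#' @return a [SanitizedAnnotation-class] with intronic sets populated.
#' @export
deriveIntronRegions <- function(sann) {
  stopifnot(is(sann, "SanitizedAnnotation"))
  exonUnion <- metadata(sann)$exon_union
  if (is.null(exonUnion))
    stop("exonic sets must be finalized by removeSharedRegions() first")
  ids <- names(sann@genes)
  if (!length(ids)) return(sann)
  ignore <- sann@strandMode == "blind"
  spanList <- GRangesList(as.list(split(granges(sann@genes),
                                        factor(ids, levels = ids))))
  names(spanList) <- ids
  nonExon <- subtractByGene(spanList,
                            reduce(unlist(exonUnion, use.names = FALSE)),
                            ignoreStrand = FALSE)
  intronic <- subtractByGene(nonExon, sann@removedShared, ignore)

  exonic <- sann@exonic
  empty <- lengths(exonic) == 0L & lengths(intronic) == 0L
  keep <- ids[!empty]
  genes <- sann@genes[keep]
  mcols(genes)$intronless <- lengths(intronic[keep]) == 0L
  out <- new("SanitizedAnnotation",
             genes = genes,
             exonic = exonic[keep],
             intronic = intronic[keep],
             removedShared = sann@removedShared,
             droppedReadthrough = sann@droppedReadthrough,
             droppedGenes = c(sann@droppedGenes, ids[empty]),
             strandMode = sann@strandMode)
  metadata(out) <- metadata(sann)
  metadata(out)$exon_union <- exonUnion[keep]
  out
}

#' Sanitize a gene annotation
#'
#' Full sanitization pipeline: optionally merge a supplemental gene set,
#' drop readthrough-tagged transcripts, remove genomic space claimed by
#' two or more gene spans, and derive per-gene intronic regions. The
#' result is the coordinate backbone used by every downstream
#' quantification step.
#'
#' @param ann primary [GeneAnnotation-class].
#' @param supplement optional [GeneAnnotation-class] of genes to merge in
#'   (e.g. genes present in one annotation source but not another).
#' @param strandMode de-overlap mode, `"blind"` (default) or `"aware"`;
#'   see [removeSharedRegions()].
#' @param readthroughTag tag marking readthrough transcripts.
#' @param mergeKey passed to [mergeSupplementalGenes()].
#' @return a [SanitizedAnnotation-class].
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'  paste0("chr1\ts\texon\t101\t300\t.\t+\t.\t",
#'    'gene_id "A"; transcript_id "A.1"; gene_type "protein_coding";'),
#'  paste0("chr1\ts\texon\t901\t1000\t.\t+\t.\t",
#'    'gene_id "A"; transcript_id "A.1"; gene_type "protein_coding";'),
#'  paste0("chr1\ts\texon\t951\t1400\t.\t+\t.\t",
#'    'gene_id "B"; transcript_id "B.1"; gene_type "protein_coding";')), gtf)
#' sann <- sanitizeAnnotation(loadAnnotation(gtf))
#' removedShared(sann)   # chr1:951-1000, claimed by both genes
#' regionLengths(sann)
#' @export
sanitizeAnnotation <- function(ann, supplement = NULL,
                               strandMode = c("blind", "aware"),
                               readthroughTag = "readthrough_transcript",
                               mergeKey = "gene_id") {
  strandMode <- match.arg(strandMode)
  if (!is.null(supplement))
    ann <- mergeSupplementalGenes(ann, supplement, key = mergeKey)
  ann <- dropReadthroughTranscripts(ann, tag = readthroughTag)
  deriveIntronRegions(removeSharedRegions(ann, strandMode))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
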