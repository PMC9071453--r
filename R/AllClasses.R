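#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame Rle
#'   runValue isTRUEorFALSE split
#' @importFrom BiocGenerics start end width strand start<- end<- strand<-
#'   unlist sort table as.data.frame range
#' @importFrom IRanges IRanges IRangesList CharacterList
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames coverage
#'   reduce findOverlaps pintersect
#' @importFrom stats median rbeta rbinom rlnorm runif setNames qnorm pnorm
#' @importFrom utils write.table read.delim head tail
NULL

#' Raw gene annotation
#'
#' Container for a parsed gene annotation prior to sanitization: one range
#' per gene (the gene span, i.e. the hull of its transcripts), the exon
#' chains of every transcript, the transcript-to-gene map, and any
#' annotation tags carried by each transcript (e.g.
#' \code{"readthrough_transcript"}).
#'
#' @slot genes [GenomicRanges::GRanges] named by \code{gene_id}, with
#'   metadata columns \code{gene_id}, \code{symbol} and \code{biotype}.
#' @slot exons [GenomicRanges::GRangesList] of exon intervals, one element
#'   per transcript, named by \code{transcript_id}. Exons within a
#'   transcript are disjoint and sorted by start.
#' @slot txGene named \code{character}: \code{transcript_id -> gene_id}.
#' @slot txTags [IRanges::CharacterList] of annotation tags per transcript,
#'   named by \code{transcript_id}.
#'
#' @details Validity requires that every transcript maps to a known gene,
#' that all transcripts of a gene share its strand and chromosome, that
#' exon chains are disjoint and sorted, and that each gene span equals the
#' hull of its transcripts.
#'
#' @seealso [loadAnnotation()], [sanitizeAnnotation()]
#' @export
setClass("GeneAnnotation",
  contains = "Annotated",
  slots = c(
    genes  = "GRanges",
    exons  = "GRangesList",
    txGene = "character",
    txTags = "CharacterList"
  )
)

setValidity("GeneAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  if (length(g) && (is.null(names(g)) || anyDuplicated(names(g))))
    msg <- c(msg, "genes must be uniquely named by gene_id")
  if (!all(c("gene_id", "symbol", "biotype") %in% colnames(mcols(g))))
    msg <- c(msg, "genes must carry gene_id, symbol, biotype metadata")
  tx <- object@exons
  if (length(tx)) {
    if (is.null(names(tx)) || anyDuplicated(names(tx)))
      msg <- c(msg, "exons must be uniquely named by transcript_id")
    if (!identical(sort(names(tx)), sort(names(object@txGene))))
      msg <- c(msg, "txGene must map exactly the transcripts in exons")
    if (!all(object@txGene %in% names(g)))
      msg <- c(msg, "every transcript must map to a known gene_id")
    # disjoint, sorted exon chains
    red <- reduce(tx)
    if (!identical(sum(width(red)), sum(width(tx))))
      msg <- c(msg, "exon intervals within a transcript must be disjoint")
    # strand/seqnames consistency and hull property per gene
    txSpan <- unlist(range(tx), use.names = FALSE)
    names(txSpan) <- names(tx)
    byGene <- split(txSpan, object@txGene[names(tx)])
    rng <- range(byGene)
    multi <- S4Vectors::elementNROWS(rng) != 1L
    if (any(multi))
      return(paste0("transcripts of one gene disagree in strand or ",
                    "chromosome: ",
                    paste(head(names(byGene)[multi], 5), collapse = ", ")))
    hull <- unlist(rng, use.names = TRUE)
    common <- intersect(names(hull), names(g))
    bad <- vapply(common, function(id) {
      h <- hull[id]; gg <- g[id]
      !(as.character(seqnames(h)) == as.character(seqnames(gg)) &&
        as.character(strand(h)) == as.character(strand(gg)) &&
        start(h) == start(gg) && end(h) == end(gg))
    }, logical(1))
    if (any(bad))
      msg <- c(msg, paste0("gene span must equal the hull of its ",
                           "transcripts (same chrom/strand): ",
                           paste(head(common[bad], 5), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Sanitized gene annotation
#'
#' The coordinate backbone for all downstream quantification: per-gene
#' disjoint exonic and intronic interval sets after readthrough-transcript
#' removal and de-overlap of genomic space claimed by two or more genes,
#' together with an audit trail.
#'
#' @slot genes [GenomicRanges::GRanges] gene spans (recomputed hulls), named
#'   by \code{gene_id}, with metadata columns \code{gene_id}, \code{symbol},
#'   \code{biotype} and \code{intronless}.
#' @slot exonic,intronic [GenomicRanges::GRangesList] named by
#'   \code{gene_id}: the disjoint interval sets used for read assignment.
#' @slot removedShared [GenomicRanges::GRanges] of bases covered by two or
#'   more gene spans that were subtracted from every gene.
#' @slot droppedReadthrough \code{character} of removed transcript ids.
#' @slot droppedGenes \code{character} of gene ids dropped because no
#'   annotated bases survived sanitization (or no transcripts survived
#'   readthrough removal).
#' @slot strandMode \code{"blind"} or \code{"aware"}: whether de-overlap
#'   treated the two strands as one genomic space (default) or separately.
#'
#' @details Validity enforces the two core contracts: within a gene the
#' exonic and intronic sets are disjoint, and across genes no base belongs
#' to more than one gene's exonic+intronic set (per strand when
#' \code{strandMode == "aware"}).
#'
#' @seealso [sanitizeAnnotation()], [regionLengths()], [countSample()]
#' @export
setClass("SanitizedAnnotation",
  contains = "Annotated",
  slots = c(
    genes             = "GRanges",
    exonic            = "GRangesList",
    intronic          = "GRangesList",
    removedShared     = "GRanges",
    droppedReadthrough = "character",
    droppedGenes      = "character",
    strandMode        = "character"
  )
)

setValidity("SanitizedAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  ids <- names(g)
  if (length(g) && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "genes must be uniquely named by gene_id")
  if (!identical(names(object@exonic), ids) ||
      !identical(names(object@intronic), ids))
    msg <- c(msg, "exonic and intronic must be named parallel to genes")
  if (!(object@strandMode %in% c("blind", "aware")))
    msg <- c(msg, "strandMode must be 'blind' or 'aware'")
  if (length(g)) {
    ignore <- identical(object@strandMode, "blind")
    for (i in seq_along(g)) {
      if (length(object@exonic[[i]]) && length(object@intronic[[i]]) &&
          length(findOverlaps(object@exonic[[i]], object@intronic[[i]],
                              ignore.strand = TRUE)))
        return(paste0("exonic and intronic overlap within gene ", ids[i]))
    }
    ann <- unlist(object@exonic, use.names = FALSE)
    ann <- c(ann, unlist(object@intronic, use.names = FALSE))
    owner <- c(rep(ids, lengths(object@exonic)),
               rep(ids, lengths(object@intronic)))
    hits <- findOverlaps(ann, ann, ignore.strand = ignore)
    hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
    bad <- owner[S4Vectors::queryHits(hits)] != owner[S4Vectors::subjectHits(hits)]
    if (any(bad))
      msg <- c(msg, "annotated regions of two genes overlap: de-overlap is not total")
  }
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' Accessors for annotation objects
#'
#' @param x a [GeneAnnotation-class] or [SanitizedAnnotation-class].
#' @return `geneRanges` returns the gene-span [GenomicRanges::GRanges];
#'   `exonicRegions` / `intronicRegions` the per-gene
#'   [GenomicRanges::GRangesList] of disjoint intervals; `removedShared`
#'   the audit [GenomicRanges::GRanges] of bases claimed by two or more
#'   genes; `droppedReadthrough` / `droppedGenes` character vectors of
#'   removed transcript/gene ids; `exonsByTranscript` the raw exon chains;
#'   `transcriptGene` the transcript-to-gene map.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname annotation-accessors
#' @export
setMethod("geneRanges", "GeneAnnotation", function(x) x@genes)
#' @rdname annotation-accessors
#' @export
setMethod("geneRanges", "SanitizedAnnotation", function(x) x@genes)

#' @rdname annotation-accessors
#' @export
setGeneric("exonicRegions", function(x) standardGeneric("exonicRegions"))
#' @rdname annotation-accessors
#' @export
setMethod("exonicRegions", "SanitizedAnnotation", function(x) x@exonic)

#' @rdname annotation-accessors
#' @export
setGeneric("intronicRegions", function(x) standardGeneric("intronicRegions"))
#' @rdname annotation-accessors
#' @export
setMethod("intronicRegions", "SanitizedAnnotation", function(x) x@intronic)

#' @rdname annotation-accessors
#' @export
setGeneric("removedShared", function(x) standardGeneric("removedShared"))
#' @rdname annotation-accessors
#' @export
setMethod("removedShared", "SanitizedAnnotation", function(x) x@removedShared)

#' @rdname annotation-accessors
#' @export
setGeneric("droppedReadthrough", function(x) standardGeneric("droppedReadthrough"))
#' @rdname annotation-accessors
#' @export
setMethod("droppedReadthrough", "SanitizedAnnotation",
          function(x) x@droppedReadthrough)

#' @rdname annotation-accessors
#' @export
setGeneric("droppedGenes", function(x) standardGeneric("droppedGenes"))
#' @rdname annotation-accessors
#' @export
setMethod("droppedGenes", "SanitizedAnnotation", function(x) x@droppedGenes)

#' @rdname annotation-accessors
#' @export
setGeneric("exonsByTranscript", function(x) standardGeneric("exonsByTranscript"))
#' @rdname annotation-accessors
#' @export
setMethod("exonsByTranscript", "GeneAnnotation", function(x) x@exons)

#' @rdname annotation-accessors
#' @export
setGeneric("transcriptGene", function(x) standardGeneric("transcriptGene"))
#' @rdname annotation-accessors
#' @export
setMethod("transcriptGene", "GeneAnnotation", function(x) x@txGene)

#' Region lengths of a sanitized annotation
#'
#' Summed widths of the surviving exonic and intronic interval sets, the
#' quantities that length-normalize TPM and the splicing ratio.
#'
#' @param x a [SanitizedAnnotation-class].
#' @return `data.frame` with columns `gene_id`, `exonic_length`,
#'   `intronic_length`, `intronless`.
#' @export
regionLengths <- function(x) {
  stopifnot(is(x, "SanitizedAnnotation"))
  data.frame(
    gene_id         = names(x@genes),
    exonic_length   = as.integer(sum(width(x@exonic))),
    intronic_length = as.integer(sum(width(x@intronic))),
    intronless      = lengths(x@intronic) == 0L,
    row.names       = NULL,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation with", length(object@genes), "genes and",
      length(object@exons), "transcripts\n")
  if (length(object@genes)) {
    bt <- table(mcols(object@genes)$biotype)
    cat("  biotypes:", paste(names(bt), bt, sep = ":", collapse = ", "), "\n")
  }
})

setMethod("show", "SanitizedAnnotation", function(object) {
  cat("SanitizedAnnotation with", length(object@genes), "genes",
      sprintf("(strand mode: %s)\n", object@strandMode))
  rl <- if (length(object@genes)) regionLengths(object) else NULL
  if (!is.null(rl)) {
    cat(sprintf("  exonic: %d bp; intronic: %d bp; intronless genes: %d\n",
                sum(rl$exonic_length), sum(rl$intronic_length),
                sum(rl$intronless)))
  }
  cat(sprintf("  removed shared space: %d bp in %d regions\n",
              sum(width(object@removedShared)), length(object@removedShared)))
  cat(sprintf("  dropped: %d readthrough transcripts, %d emptied genes\n",
              length(object@droppedReadthrough), length(object@droppedGenes)))
})
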