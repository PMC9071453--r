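#' Load a gene annotation from GTF
#'
#' Parses a gencode-dialect GTF (attributes `gene_id`, `gene_name`,
#' `gene_type`, `tag`) into a [GeneAnnotation-class]. Only `exon` features
#' define gene structure; gene spans are (re)computed as the hull of each
#' gene's transcripts, so the object always satisfies the hull invariant.
#' Genes contributing no exons are rejected (recorded in
#' `metadata(x)$rejected_no_exon`).
#'
#' @param path path to a GTF file. GTF coordinates (1-based, closed) are
#'   used natively; all interval arithmetic is delegated to
#'   GenomicRanges/IRanges.
#' @return a [GeneAnnotation-class].
#'
#' @details Malformed lines (fewer than 9 tab-separated fields) raise an
#' error naming the offending line number; an exon feature without a
#' `gene_id` or `transcript_id` attribute is an error; transcripts of one
#' gene on different strands or chromosomes are an error. An empty file
#' yields an empty annotation.
#'
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
#'   'gene_id "G1"; transcript_id "G1.t1"; gene_name "G1"; ',
#'   'gene_type "protein_coding";'), gtf)
#' ann <- loadAnnotation(gtf)
#' width(geneRanges(ann))  # 100 bases
#' @export
loadAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(body)) return(emptyGeneAnnotation())
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  buildGeneAnnotation(gr)
}

## Assemble a GeneAnnotation from an rtracklayer-style GRanges with a
## `type` column and gencode attribute columns.
buildGeneAnnotation <- function(gr) {
  if (!length(gr)) return(emptyGeneAnnotation())
  mc <- mcols(gr)
  if (is.null(mc$gene_id)) stop("annotation features carry no gene_id attribute")
  ex <- gr[mc$type == "exon"]
  if (!length(ex)) return(emptyGeneAnnotation(rejected = unique(mc$gene_id)))
  exm <- mcols(ex)
  if (anyNA(exm$gene_id)) stop("exon feature missing gene_id attribute")
  if (is.null(exm$transcript_id) || anyNA(exm$transcript_id))
    stop("exon feature missing transcript_id attribute")

  txGene <- tapply(as.character(exm$gene_id), as.character(exm$transcript_id),
                   function(x) {
                     u <- unique(x)
                     if (length(u) > 1L)
                       stop("transcript assigned to multiple genes: ",
                            paste(u, collapse = ", "))
                     u
                   })
  txGene <- setNames(as.character(txGene), names(txGene))

  exons <- GenomicRanges::sort(
    split(granges(ex), as.character(exm$transcript_id)))
  if (!identical(sum(width(reduce(exons))), sum(width(exons))))
    stop("overlapping exon intervals within a transcript")

  tags <- extractTags(gr, as.character(mcols(gr)$transcript_id))
  tags <- tags[names(exons)]
  names(tags) <- names(exons)

  ## per-gene attributes: prefer gene rows, fall back to exon rows
  geneAttr <- attrPerGene(gr)
  rejected <- setdiff(geneAttr$gene_id, unname(txGene))

  ann <- assembleAnnotation(exons, txGene, tags, geneAttr)
  metadata(ann)$rejected_no_exon <- rejected
  ann
}

## Collapse `tag` attribute values per transcript (handles both atomic and
## list-valued columns as produced by rtracklayer for repeated keys).
extractTags <- function(gr, txid) {
  tagcol <- mcols(gr)$tag
  n <- length(gr)
  if (is.null(tagcol)) tagcol <- rep(NA_character_, n)
  if (!is.list(tagcol) && !is(tagcol, "List"))
    tagcol <- as.list(tagcol)
  keep <- !is.na(txid)
  flat <- mapply(function(tg, id) {
    tg <- tg[!is.na(tg)]
    if (!length(tg)) character() else tg
  }, tagcol[keep], txid[keep], SIMPLIFY = FALSE)
  byTx <- split(flat, txid[keep])
  out <- lapply(byTx, function(x) unique(unlist(x, use.names = FALSE)))
  CharacterList(out)
}

attrPerGene <- function(gr) {
  mc <- mcols(gr)
  gid <- as.character(mc$gene_id)
  sym <- if (!is.null(mc$gene_name)) as.character(mc$gene_name) else gid
  bio <- if (!is.null(mc$gene_type)) as.character(mc$gene_type)
         else rep("unknown", length(gr))
  ok <- !is.na(gid)
  first <- !duplicated(gid[ok])
  data.frame(gene_id = gid[ok][first],
             symbol  = ifelse(is.na(sym[ok][first]), gid[ok][first],
                              sym[ok][first]),
             biotype = ifelse(is.na(bio[ok][first]), "unknown",
                              bio[ok][first]),
             stringsAsFactors = FALSE)
}

## Build the object, recomputing gene spans as transcript hulls.
assembleAnnotation <- function(exons, txGene, tags, geneAttr) {
  txSpan <- unlist(range(exons), use.names = FALSE)
  names(txSpan) <- names(exons)
  byGene <- split(txSpan, txGene[names(exons)])
  rng <- range(byGene)
  multi <- S4Vectors::elementNROWS(rng) != 1L
  if (any(multi))
    stop("transcripts of gene(s) ",
         paste(head(names(byGene)[multi], 5), collapse = ", "),
         " disagree in strand or chromosome")
  genes <- unlist(rng, use.names = TRUE)
  idx <- match(names(genes), geneAttr$gene_id)
  mcols(genes)$gene_id <- names(genes)
  mcols(genes)$symbol  <- ifelse(is.na(idx), names(genes),
                                 geneAttr$symbol[idx])
  mcols(genes)$biotype <- ifelse(is.na(idx), "unknown",
                                 geneAttr$biotype[idx])
  new("GeneAnnotation", genes = genes, exons = exons,
      txGene = txGene[names(exons)], txTags = tags)
}

emptyGeneAnnotation <- function(rejected = character()) {
  g <- GRanges()
  mcols(g)$gene_id <- character()
  mcols(g)$symbol <- character()
  mcols(g)$biotype <- character()
  ann <- new("GeneAnnotation", genes = g, exons = GRangesList(),
             txGene = setNames(character(), character()),
             txTags = CharacterList())
  metadata(ann)$rejected_no_exon <- rejected
  ann
}

#' Write a gene annotation as GTF
#'
#' Emits gene, transcript and exon rows with gencode-style attributes
#' (`gene_id`, `gene_name`, `gene_type`, `transcript_id`, `tag`), suitable
#' for round-tripping through [loadAnnotation()].
#'
#' @param ann a [GeneAnnotation-class].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
exportAnnotationGtf <- function(ann, path) {
  stopifnot(is(ann, "GeneAnnotation"))
  g <- ann@genes
  rows <- list()
  if (length(g)) {
    grow <- granges(g)
    mcols(grow) <- DataFrame(type = "gene",
                             gene_id = names(g),
                             gene_name = mcols(g)$symbol,
                             gene_type = mcols(g)$biotype)
    txSpan <- unlist(range(ann@exons), use.names = FALSE)
    txid <- names(ann@exons)
    gid <- unname(ann@txGene[txid])
    gidx <- match(gid, names(g))
    trow <- txSpan
    tagstr <- vapply(as.list(ann@txTags[txid]), function(x)
      if (length(x)) x[1L] else NA_character_, character(1))
    mcols(trow) <- DataFrame(type = "transcript", gene_id = gid,
                             gene_name = mcols(g)$symbol[gidx],
                             gene_type = mcols(g)$biotype[gidx],
                             transcript_id = txid, tag = tagstr)
    erow <- unlist(ann@exons, use.names = FALSE)
    etx <- rep(txid, lengths(ann@exons))
    egid <- unname(ann@txGene[etx])
    egidx <- match(egid, names(g))
    mcols(erow) <- DataFrame(type = "exon", gene_id = egid,
                             gene_name = mcols(g)$symbol[egidx],
                             gene_type = mcols(g)$biotype[egidx],
                             transcript_id = etx,
                             tag = vapply(as.list(ann@txTags[etx]), function(x)
                               if (length(x)) x[1L] else NA_character_,
                               character(1)))
    mcols(grow)$transcript_id <- NA_character_
    mcols(grow)$tag <- NA_character_
    all <- c(grow, trow, erow)
    all <- all[order(as.factor(seqnames(all)), start(all),
                     match(mcols(all)$type, c("gene", "transcript", "exon")))]
    rtracklayer::export(all, path, format = "gtf")
  } else {
    writeLines(character(), path)
  }
  invisible(path)
}

#' Export a sanitized annotation
#'
#' Writes the sanitized gene set as GTF (gene rows plus the surviving
#' exonic intervals as exon features), BED6 files of the exonic and
#' intronic interval sets (name = gene_id), and a TSV audit report of
#' dropped transcripts, dropped genes and removed shared bases.
#'
#' @param sann a [SanitizedAnnotation-class].
#' @param prefix output path prefix; files `<prefix>.sanitized.gtf`,
#'   `<prefix>.exonic.bed`, `<prefix>.intronic.bed`, `<prefix>.audit.tsv`
#'   are written.
#' @return named character vector of the written paths, invisibly.
#' @export
exportSanitizedAnnotation <- function(sann, prefix) {
  stopifnot(is(sann, "SanitizedAnnotation"))
  g <- sann@genes
  gtf <- paste0(prefix, ".sanitized.gtf")
  if (length(g)) {
    grow <- granges(g)
    mcols(grow) <- DataFrame(type = "gene", gene_id = names(g),
                             gene_name = mcols(g)$symbol,
                             gene_type = mcols(g)$biotype,
                             transcript_id = NA_character_)
    erow <- unlist(sann@exonic, use.names = FALSE)
    egid <- rep(names(g), lengths(sann@exonic))
    eg <- match(egid, names(g))
    mcols(erow) <- DataFrame(type = "exon", gene_id = egid,
                             gene_name = mcols(g)$symbol[eg],
                             gene_type = mcols(g)$biotype[eg],
                             transcript_id = paste0(egid, ".sanitized"))
    all <- c(grow, erow)
    all <- all[order(as.factor(seqnames(all)), start(all),
                     match(mcols(all)$type, c("gene", "exon")))]
    rtracklayer::export(all, gtf, format = "gtf")
  } else writeLines(character(), gtf)

  bedOut <- function(grl, path) {
    x <- unlist(grl, use.names = FALSE)
    if (length(x)) {
      mcols(x) <- DataFrame(name = rep(names(grl), lengths(grl)), score = 0L)
      x <- x[order(as.factor(seqnames(x)), start(x))]
    }
    rtracklayer::export(x, path, format = "bed")
    path
  }
  exbed <- bedOut(sann@exonic, paste0(prefix, ".exonic.bed"))
  inbed <- bedOut(sann@intronic, paste0(prefix, ".intronic.bed"))

  audit <- paste0(prefix, ".audit.tsv")
  rs <- sann@removedShared
  block <- function(event, id, chrom = NA_character_, s = NA_integer_,
                    e = NA_integer_) {
    n <- max(length(id), length(chrom))
    if (!n) return(NULL)
    data.frame(event = rep(event, n), id = rep_len(id, n),
               chrom = rep_len(chrom, n), start = rep_len(s, n),
               end = rep_len(e, n), stringsAsFactors = FALSE)
  }
  auditDf <- rbind(
    block("dropped_readthrough_transcript", sann@droppedReadthrough),
    block("dropped_gene", sann@droppedGenes),
    block("removed_shared_region", rep(NA_character_, length(rs)),
          as.character(seqnames(rs)), start(rs), end(rs)))
  if (is.null(auditDf))
    auditDf <- data.frame(event = character(), id = character(),
                          chrom = character(), start = integer(),
                          end = integer())
  write.table(auditDf, audit, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gtf = gtf, exonic = exbed, intronic = inbed, audit = audit))
}
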