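## Detection of genes whose signal plausibly derives from upstream
## readthrough (DoG-like) transcription: a strand-aware 2 kb upstream
## flank is scored for coverage breadth and TPM ratio against the gene.

#' Build upstream flank regions
#'
#' For each gene, the strand-aware upstream flank of `flank` bases
#' (immediately 5' of the gene span), with any base overlapping any
#' other gene's span subtracted, mirroring
#' `bedtools flank -l 2000 -r 0 -s` followed by `bedtools subtract`.
#'
#' @param sann a [SanitizedAnnotation-class].
#' @param flank nominal flank length in bases (default 2000).
#' @param seqlengths optional named vector of chromosome lengths used to
#'   clip flanks at chromosome ends; taken from the annotation's
#'   seqinfo when present.
#' @return a list with `regions` (a [GenomicRanges::GRangesList] named by
#'   gene, strand set to the gene strand) and `summary` (`data.frame`
#'   with `gene_id`, `nominal_length`, `effective_length`).
#' @examples
#' # a + strand gene at 10001-20000 gets flank 8001-10000
#' @export
buildUpstreamRegions <- function(sann, flank = 2000L, seqlengths = NULL) {
  stopifnot(is(sann, "SanitizedAnnotation"))
  spans <- sann@genes
  up <- GenomicRanges::flank(granges(spans), width = flank, start = TRUE)
  ## clip at chromosome boundaries
  start(up) <- pmax(start(up), 1L)
  sl <- seqlengths %||% GenomeInfoDb::seqlengths(spans)
  if (!all(is.na(sl))) {
    lim <- sl[as.character(seqnames(up))]
    end(up) <- ifelse(is.na(lim), end(up), pmin(end(up), lim))
  }
  allSpans <- reduce(granges(spans), ignore.strand = TRUE)
  regions <- GenomicRanges::subtract(up, allSpans, ignore.strand = TRUE)
  names(regions) <- names(spans)
  eff <- as.integer(sum(width(regions)))
  list(regions = regions,
       summary = data.frame(gene_id = names(spans),
                            strand = as.character(strand(spans)),
                            nominal_length = as.integer(flank),
                            effective_length = eff,
                            stringsAsFactors = FALSE))
}

#' Extract intergenic alignments
#'
#' Emits exactly the alignments whose aligned blocks overlap no gene's
#' exonic or intronic interval set by one base or more (strand-blind, as
#' for read extraction from a BAM by assignment status).
#'
#' @inheritParams assignReads
#' @return the subset of `alignments` with no annotated overlap.
#' @export
collectIntergenicAlignments <- function(alignments, sann) {
  stopifnot(is(sann, "SanitizedAnnotation"))
  fb <- fragmentBlocks(alignments)
  feats <- featureTable(sann)
  flat <- unlist(fb$blocks, use.names = FALSE)
  readIdx <- rep(seq_along(fb$blocks), lengths(fb$blocks))
  hit <- unique(readIdx[S4Vectors::queryHits(
    findOverlaps(flat, feats, ignore.strand = TRUE))])
  keepIds <- fb$ids[setdiff(seq_along(fb$blocks), hit)]
  if (is(alignments, "GAlignments") || is(alignments, "GRangesList")) {
    nm <- names(alignments) %||% as.character(seq_along(alignments))
    alignments[nm %in% keepIds]
  } else {
    stop("unsupported alignment container")
  }
}

#' Score upstream regions for readthrough contamination
#'
#' Split-aware coverage of each gene's upstream flank by intergenic
#' alignments, under a configurable strand policy, yielding the covered
#' breadth and an upstream TPM computed with the same per-sample
#' normalization denominator as the gene TPMs. A gene is flagged when
#' the upstream/gene TPM ratio is at least `ratioMin` **and** breadth is
#' at least `breadthMin` (inclusive thresholds).
#'
#' @param upstream result of [buildUpstreamRegions()].
#' @param intergenic alignments from [collectIntergenicAlignments()].
#' @param tpm the sample's [combinedTpm()] table (supplies each gene's
#'   TPM and, via its `rate_sum` attribute, the normalization
#'   denominator).
#' @param strandPolicy which intergenic alignments count towards the
#'   flank: `"antisense_of_flank"` (default; alignment strand opposite
#'   the gene strand, which under reverse-stranded chemistry captures
#'   sense transcription running into the gene, mirroring
#'   `bedtools coverage -S -split`), `"sense_of_flank"`, or
#'   `"unstranded"`.
#' @param ratioMin,breadthMin inclusive flagging thresholds
#'   (defaults 0.20 and 0.70).
#' @return `data.frame` with columns `gene_id`, `effective_length`,
#'   `breadth`, `upstream_tpm`, `gene_tpm`, `ratio`, `evaluable`,
#'   `flagged`. Genes with zero effective flank or zero gene TPM are not
#'   evaluable and never flagged.
#' @export
scoreUpstream <- function(upstream, intergenic, tpm,
                          strandPolicy = c("antisense_of_flank",
                                           "sense_of_flank", "unstranded"),
                          ratioMin = 0.20, breadthMin = 0.70) {
  strandPolicy <- match.arg(strandPolicy)
  regions <- upstream$regions
  summ <- upstream$summary
  stopifnot(identical(tpm$gene_id, summ$gene_id))
  rateSum <- attr(tpm, "rate_sum")
  if (is.null(rateSum))
    stop("tpm table lacks its rate_sum attribute; use combinedTpm()")

  fb <- fragmentBlocks(intergenic)
  flat <- unlist(fb$blocks, use.names = FALSE)
  readIdx <- rep(seq_along(fb$blocks), lengths(fb$blocks))

  regFlat <- unlist(regions, use.names = FALSE)
  regGene <- rep(seq_along(regions), lengths(regions))
  geneStrand <- summ$strand

  n <- nrow(summ)
  count <- integer(n)
  covered <- integer(n)
  if (length(flat) && length(regFlat)) {
    hits <- findOverlaps(flat, regFlat, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    g <- regGene[s]
    readStrand <- fb$strand[readIdx[q]]
    ok <- switch(strandPolicy,
      antisense_of_flank = readStrand != geneStrand[g],
      sense_of_flank     = readStrand == geneStrand[g],
      unstranded         = rep(TRUE, length(q)))
    q <- q[ok]; s <- s[ok]; g <- g[ok]
    if (length(q)) {
      ## read count: distinct fragments overlapping the region >= 1 base
      frag <- readIdx[q]
      cnt <- table(factor(g[!duplicated(paste(frag, g))], levels = seq_len(n)))
      count <- as.integer(cnt)
      ## breadth: bases of the region covered by any retained block
      ints <- pintersect(flat[q], regFlat[s], ignore.strand = TRUE)
      grl <- reduce(split(granges(ints), factor(g, levels = seq_len(n))))
      covered <- as.integer(sum(width(grl)))
    }
  }
  eff <- summ$effective_length
  geneTpm <- tpm$tpm_combined
  breadth <- ifelse(eff > 0, covered / eff, 0)
  upTpm <- ifelse(eff > 0 & rateSum > 0,
                  1e6 * (count / (eff / 1000)) / rateSum, 0)
  evaluable <- eff > 0 & geneTpm > 0
  ratio <- ifelse(evaluable, upTpm / geneTpm, NA_real_)
  flagged <- evaluable & !is.na(ratio) &
    ratio >= ratioMin & breadth >= breadthMin
  data.frame(gene_id = summ$gene_id,
             effective_length = eff,
             breadth = breadth,
             upstream_tpm = upTpm,
             gene_tpm = geneTpm,
             ratio = ratio,
             evaluable = evaluable,
             flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Apply the upstream-readthrough filter to an IP comparison
#'
#' A gene flagged in either the input or the IP condition is removed from
#' that IP-versus-input comparison.
#'
#' @param scoresInput,scoresIp score tables from [scoreUpstream()]
#'   computed on the same annotation.
#' @return character vector of gene ids to remove (the union of flagged
#'   genes).
#' @export
applyUpstreamFilter <- function(scoresInput, scoresIp) {
  if (!identical(sort(scoresInput$gene_id), sort(scoresIp$gene_id)))
    stop("score tables cover different gene universes")
  sort(union(scoresInput$gene_id[scoresInput$flagged],
             scoresIp$gene_id[scoresIp$flagged]))
}
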