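## Exon/intron-aware read assignment and quantification against a
## sanitized annotation: minimum-overlap gene assignment, combined
## exonic+intronic TPM, and the per-gene intron/exon splicing ratio.

#' Read short-read alignments from BAM
#'
#' Thin wrapper over [GenomicAlignments::readGAlignments()] that retains
#' the `flag` and `mapq` fields needed downstream and drops unmapped
#' records. For paired-end data the two mates of a pair are merged into
#' one fragment (union of aligned blocks), which is then counted once.
#'
#' @param bam path to a coordinate-sorted BAM.
#' @param paired logical; read as fragments via
#'   [GenomicAlignments::readGAlignmentPairs()].
#' @param region optional [GenomicRanges::GRanges] restricting input;
#'   requires a BAM index.
#' @return a [GenomicAlignments::GAlignments] (or, for paired input, a
#'   [GenomicRanges::GRangesList] of fragment blocks with `flag`/`mapq`
#'   metadata), named by read id.
#' @export
readShortReadAlignments <- function(bam, paired = FALSE, region = NULL) {
  if (!is.null(region) &&
      !file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("random access requested but BAM index is missing for ", bam)
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(
      what = c("flag", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  } else {
    Rsamtools::ScanBamParam(
      what = c("flag", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
      which = region)
  }
  if (paired) {
    gp <- GenomicAlignments::readGAlignmentPairs(bam, use.names = TRUE,
                                                 param = param)
    grl <- GenomicAlignments::grglist(gp)
    mcols(grl)$flag <- mcols(GenomicAlignments::first(gp))$flag
    mcols(grl)$mapq <- mcols(GenomicAlignments::first(gp))$mapq
    grl
  } else {
    GenomicAlignments::readGAlignments(bam, use.names = TRUE, param = param)
  }
}

## Normalize alignments to a GRangesList of aligned blocks (one element
## per usable fragment) plus alignment strand. Secondary, supplementary
## and unmapped records are skipped.
fragmentBlocks <- function(alignments) {
  if (is(alignments, "GAlignments")) {
    fl <- mcols(alignments)$flag
    if (!is.null(fl) && length(fl)) {
      fl <- as.integer(fl)
      keep <- bitwAnd(fl, 0x4L) == 0L & bitwAnd(fl, 0x100L) == 0L &
        bitwAnd(fl, 0x800L) == 0L
      alignments <- alignments[keep]
    }
    grl <- GenomicAlignments::grglist(alignments)
    list(blocks = grl,
         strand = as.character(strand(alignments)),
         ids = names(alignments) %||% as.character(seq_along(alignments)))
  } else if (is(alignments, "GRangesList")) {
    fl <- mcols(alignments)$flag
    if (!is.null(fl) && length(fl)) {
      fl <- as.integer(fl)
      keep <- bitwAnd(fl, 0x4L) == 0L & bitwAnd(fl, 0x100L) == 0L &
        bitwAnd(fl, 0x800L) == 0L
      alignments <- alignments[keep]
    }
    st <- vapply(seq_along(alignments), function(i) {
      s <- runValue(strand(alignments))[[i]]
      as.character(s[1L])
    }, character(1))
    list(blocks = alignments, strand = st,
         ids = names(alignments) %||% as.character(seq_along(alignments)))
  } else {
    stop("unsupported alignment container: ", class(alignments)[1L])
  }
}

## Flat feature table of a sanitized annotation: one GRanges with
## gene index and region label per interval.
featureTable <- function(sann) {
  ids <- names(sann@genes)
  ex <- unlist(sann@exonic, use.names = FALSE)
  ino <- unlist(sann@intronic, use.names = FALSE)
  feats <- c(ex, ino)
  mcols(feats) <- DataFrame(
    gene = c(rep(seq_along(ids), lengths(sann@exonic)),
             rep(seq_along(ids), lengths(sann@intronic))),
    region = rep(c(1L, 2L), c(length(ex), length(ino))))  # 1 exonic, 2 intronic
  feats
}

#' Assign reads to exonic or intronic gene regions
#'
#' featureCounts-style assignment with a minimum-overlap rule: a
#' fragment's aligned blocks are intersected with every gene's exonic and
#' intronic interval sets on the strand implied by the library chemistry;
#' a (gene, region) pair is a candidate when the total overlap reaches
#' `minOverlap` bases. A fragment with candidates in two or more genes is
#' ambiguous; within one gene the region with the larger overlap wins,
#' ties going to exonic.
#'
#' @param alignments a [GenomicAlignments::GAlignments] (or
#'   [GenomicRanges::GRangesList] of fragment blocks) named by read id.
#'   Secondary, supplementary and unmapped records are skipped.
#' @param sann a [SanitizedAnnotation-class].
#' @param minOverlap minimum total overlap in bases (default 20).
#' @param strandedness `"reverse"` (default; dUTP-stranded chemistry, the
#'   fragment's transcript strand is opposite the alignment strand),
#'   `"forward"`, or `"unstranded"`.
#' @param onAmbiguous `"count"` (default) tallies cross-gene ambiguous
#'   fragments; `"error"` raises an internal-consistency error instead
#'   (cross-gene candidates are rare on a sanitized annotation but can
#'   still arise when a fragment straddles two abutting genes).
#' @return `data.frame` with one row per usable fragment: `read_id`,
#'   `gene_id` (NA unless assigned), `region` (`"exonic"`/`"intronic"`),
#'   and `status` (`assigned`/`unassigned`/`ambiguous`).
#' @examples
#' # see countSample() for an end-to-end example
#' @export
assignReads <- function(alignments, sann, minOverlap = 20L,
                        strandedness = c("reverse", "forward", "unstranded"),
                        onAmbiguous = c("count", "error")) {
  strandedness <- match.arg(strandedness)
  onAmbiguous <- match.arg(onAmbiguous)
  stopifnot(is(sann, "SanitizedAnnotation"))
  fb <- fragmentBlocks(alignments)
  n <- length(fb$blocks)
  out <- data.frame(read_id = fb$ids,
                    gene_id = rep(NA_character_, n),
                    region = rep(NA_character_, n),
                    status = rep("unassigned", n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  feats <- featureTable(sann)
  if (!length(feats)) return(out)

  flat <- unlist(fb$blocks, use.names = FALSE)
  readIdx <- rep(seq_len(n), lengths(fb$blocks))
  hits <- findOverlaps(flat, feats, ignore.strand = TRUE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ## strand compatibility of the fragment with the feature's gene strand
    effStrand <- switch(strandedness,
      reverse = chartr("+-", "-+", fb$strand),
      forward = fb$strand,
      unstranded = NULL)
    if (!is.null(effStrand)) {
      fs <- as.character(strand(feats))[s]
      ok <- fs == "*" | fs == effStrand[readIdx[q]]
      q <- q[ok]; s <- s[ok]
    }
    if (length(q)) {
      w <- width(pintersect(flat[q], feats[s], ignore.strand = TRUE))
      gene <- mcols(feats)$gene[s]
      region <- mcols(feats)$region[s]
      rd <- readIdx[q]
      key <- (as.numeric(rd) - 1) * (length(sann@genes) * 2) +
        (gene - 1) * 2 + region
      agg <- rowsum(w, group = key, reorder = FALSE)
      k <- as.numeric(rownames(agg))
      aw <- agg[, 1L]
      keep <- aw >= minOverlap
      if (any(keep)) {
        k <- k[keep]; aw <- aw[keep]
        rdA <- floor((k - 1) / (length(sann@genes) * 2)) + 1
        rem <- (k - 1) %% (length(sann@genes) * 2)
        geneA <- floor(rem / 2) + 1
        regA <- rem %% 2 + 1
        ## order candidates per read: exonic-precedence on overlap ties
        ord <- order(rdA, -aw, regA)
        rdA <- rdA[ord]; geneA <- geneA[ord]; regA <- regA[ord]; aw <- aw[ord]
        geneCount <- tapply(geneA, rdA, function(x) length(unique(x)))
        ambReads <- as.integer(names(geneCount)[geneCount > 1L])
        if (length(ambReads) && onAmbiguous == "error")
          stop("fragment(s) with qualifying overlap in two or more genes: ",
               "annotation not sanitized or genes abut (e.g. read ",
               out$read_id[ambReads[1L]], ")")
        first <- !duplicated(rdA)
        sel <- first & !(rdA %in% ambReads)
        out$gene_id[rdA[sel]] <- names(sann@genes)[geneA[sel]]
        out$region[rdA[sel]] <- c("exonic", "intronic")[regA[sel]]
        out$status[rdA[sel]] <- "assigned"
        out$status[ambReads] <- "ambiguous"
      }
    }
  }
  out
}

#' Count a sample's fragments per gene and region
#'
#' Tallies [assignReads()] over one sample's alignments into a per-gene
#' table of exonic and intronic fragment counts, with the unassigned and
#' ambiguous remainders kept so that the bookkeeping identity
#' `assigned + unassigned + ambiguous = usable fragments` holds.
#'
#' @inheritParams assignReads
#' @param sampleId label stored with the table.
#' @return `data.frame` with columns `gene_id`, `exonic_count`,
#'   `intronic_count` (one row per annotated gene, in annotation order)
#'   and attributes `sample_id`, `unassigned`, `ambiguous`, `n_fragments`.
#' @export
countSample <- function(alignments, sann, minOverlap = 20L,
                        strandedness = c("reverse", "forward", "unstranded"),
                        sampleId = "sample",
                        onAmbiguous = c("count", "error")) {
  asg <- assignReads(alignments, sann, minOverlap = minOverlap,
                     strandedness = strandedness, onAmbiguous = onAmbiguous)
  ids <- names(sann@genes)
  lev <- factor(asg$gene_id, levels = ids)
  tab <- data.frame(
    gene_id = ids,
    exonic_count = as.integer(table(lev[asg$status == "assigned" &
                                          asg$region == "exonic"])),
    intronic_count = as.integer(table(lev[asg$status == "assigned" &
                                            asg$region == "intronic"])),
    stringsAsFactors = FALSE)
  attr(tab, "sample_id") <- sampleId
  attr(tab, "unassigned") <- sum(asg$status == "unassigned")
  attr(tab, "ambiguous") <- sum(asg$status == "ambiguous")
  attr(tab, "n_fragments") <- nrow(asg)
  tab
}

#' Combined exonic+intronic TPM
#'
#' Length-normalized expression computed separately for each gene's
#' exonic and intronic regions and then summed, so that long introns do
#' not deflate (nor intronic reads inflate) the per-gene value. The
#' per-region rate is `count / (region length in kb)`; in the default
#' joint mode one million is apportioned across all exonic and intronic
#' rates together, while split mode normalizes the exonic and intronic
#' families to one million each.
#'
#' @param counts a count table from [countSample()].
#' @param sann the [SanitizedAnnotation-class] the counts were made on.
#' @param mode `"joint"` (default) or `"split"`.
#' @return `data.frame` with columns `gene_id`, `tpm_exonic`,
#'   `tpm_intronic`, `tpm_combined`, and attributes `mode`, `rate_sum`
#'   (the joint normalization denominator in fragments/kb) and
#'   `sample_id`.
#' @export
combinedTpm <- function(counts, sann, mode = c("joint", "split")) {
  mode <- match.arg(mode)
  rl <- regionLengths(sann)
  stopifnot(identical(counts$gene_id, rl$gene_id))
  if (any(counts$exonic_count > 0 & rl$exonic_length == 0) ||
      any(counts$intronic_count > 0 & rl$intronic_length == 0))
    stop("nonzero count on zero-length region: annotation inconsistency")
  rateEx <- ifelse(rl$exonic_length > 0,
                   counts$exonic_count / (rl$exonic_length / 1000), 0)
  rateIn <- ifelse(rl$intronic_length > 0,
                   counts$intronic_count / (rl$intronic_length / 1000), 0)
  rateSum <- sum(rateEx) + sum(rateIn)
  if (mode == "joint") {
    denom <- rateSum
    tpmEx <- if (denom > 0) 1e6 * rateEx / denom else rateEx * 0
    tpmIn <- if (denom > 0) 1e6 * rateIn / denom else rateIn * 0
  } else {
    tpmEx <- if (sum(rateEx) > 0) 1e6 * rateEx / sum(rateEx) else rateEx * 0
    tpmIn <- if (sum(rateIn) > 0) 1e6 * rateIn / sum(rateIn) else rateIn * 0
  }
  out <- data.frame(gene_id = counts$gene_id,
                    tpm_exonic = tpmEx,
                    tpm_intronic = tpmIn,
                    tpm_combined = tpmEx + tpmIn,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "rate_sum") <- rateSum
  attr(out, "sample_id") <- attr(counts, "sample_id")
  out
}

#' Per-gene intron/exon splicing ratio across two samples
#'
#' The ratio of length-normalized intronic read density to exonic read
#' density per gene: 0 indicates fully spliced transcripts, 1 equal
#' intronic and exonic densities (unspliced-like). Values above 1 are
#' reported as computed. Genes are eligible when they carry a genomically
#' encoded intron and reach the combined-TPM floor in **both** samples.
#'
#' @param countsA,countsB count tables from [countSample()] for the two
#'   samples (e.g. two IP conditions).
#' @param tpmA,tpmB matching tables from [combinedTpm()].
#' @param sann the shared [SanitizedAnnotation-class].
#' @param tpmMin combined-TPM eligibility floor applied to both samples
#'   (default 1).
#' @return `data.frame` with columns `gene_id`, `ratio_a`, `ratio_b`,
#'   `eligible`. Ratios are NA for intronless genes or zero exonic
#'   counts; exactly 0 when the intronic count is 0.
#' @export
splicingRatio <- function(countsA, tpmA, countsB, tpmB, sann, tpmMin = 1) {
  rl <- regionLengths(sann)
  stopifnot(identical(countsA$gene_id, rl$gene_id),
            identical(countsB$gene_id, rl$gene_id),
            identical(tpmA$gene_id, rl$gene_id),
            identical(tpmB$gene_id, rl$gene_id))
  oneRatio <- function(counts) {
    ok <- counts$exonic_count > 0 & rl$exonic_length > 0 &
      rl$intronic_length > 0
    r <- rep(NA_real_, nrow(counts))
    r[ok] <- (counts$intronic_count[ok] / rl$intronic_length[ok]) /
      (counts$exonic_count[ok] / rl$exonic_length[ok])
    r
  }
  eligible <- rl$intronic_length > 0 &
    tpmA$tpm_combined >= tpmMin & tpmB$tpm_combined >= tpmMin
  data.frame(gene_id = rl$gene_id,
             ratio_a = oneRatio(countsA),
             ratio_b = oneRatio(countsB),
             eligible = eligible,
             stringsAsFactors = FALSE)
}
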