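## Long-read (nanopore direct-RNA) pipeline: alignment filtering, gene
## assignment by largest overlap, per-read intron-retention calls,
## poly(A) QC-tag filtering, and per-gene tail-length statistics.

#' Read long-read spliced alignments from BAM
#'
#' @param bam path to a coordinate-sorted BAM of spliced long-read
#'   alignments.
#' @return a [GenomicAlignments::GAlignments] named by read id, carrying
#'   `flag` and `mapq`.
#' @export
readLongReadAlignments <- function(bam) {
  param <- Rsamtools::ScanBamParam(what = c("flag", "mapq"))
  GenomicAlignments::readGAlignments(bam, use.names = TRUE, param = param)
}

#' Filter long-read alignments
#'
#' Retains primary alignments with MAPQ of at least 1, dropping MAPQ-0
#' (multi-mapping), supplementary, secondary and unmapped records — the
#' `samtools view -bq 1 -F 2048` semantics plus secondary removal.
#'
#' @param alignments a [GenomicAlignments::GAlignments] with `flag` and
#'   `mapq` metadata columns.
#' @return the retained subset, with attribute `n_removed` (named counts
#'   of `mapq0`, `supplementary`, `secondary`, `unmapped`).
#' @export
filterLongAlignments <- function(alignments) {
  fl <- mcols(alignments)$flag
  mq <- mcols(alignments)$mapq
  if (is.null(fl) || is.null(mq))
    stop("alignments must carry flag and mapq metadata")
  unmapped <- bitwAnd(fl, 0x4L) != 0L
  secondary <- bitwAnd(fl, 0x100L) != 0L
  supplementary <- bitwAnd(fl, 0x800L) != 0L
  mapq0 <- !is.na(mq) & mq == 0L
  keep <- !unmapped & !secondary & !supplementary & !mapq0
  out <- alignments[keep]
  attr(out, "n_removed") <- c(
    mapq0 = sum(mapq0 & !unmapped & !secondary & !supplementary),
    supplementary = sum(supplementary),
    secondary = sum(secondary & !supplementary),
    unmapped = sum(unmapped))
  out
}

#' Assign long reads to genes by largest overlap
#'
#' Long-read mode: each read goes to the gene whose annotated
#' (exonic+intronic) space its aligned blocks overlap most, provided the
#' overlap reaches `minOverlap` bases. Reads mapped to mitochondrial
#' chromosomes are removed (they are not nuclear-encoded transcripts) and
#' counted.
#'
#' @param alignments filtered [GenomicAlignments::GAlignments] (see
#'   [filterLongAlignments()]).
#' @param sann a [SanitizedAnnotation-class].
#' @param minOverlap minimum overlap in bases (default 20).
#' @param strandedness `"unstranded"` (default: direct-RNA reads align in
#'   the sense orientation and the annotation assignment does not
#'   restrict strand), `"forward"`, or `"reverse"`.
#' @param mitoChroms chromosome names treated as mitochondrial
#'   (default `c("chrM", "MT")`).
#' @return `data.frame` with one row per non-mitochondrial read:
#'   `read_id`, `gene_id` (NA when no gene reaches `minOverlap`),
#'   `overlap` (bases). Attribute `n_mito` counts removed mitochondrial
#'   reads.
#' @export
assignLongReads <- function(alignments, sann, minOverlap = 20L,
                            strandedness = c("unstranded", "forward",
                                             "reverse"),
                            mitoChroms = c("chrM", "MT")) {
  strandedness <- match.arg(strandedness)
  stopifnot(is(sann, "SanitizedAnnotation"))
  isMito <- as.character(GenomicAlignments::seqnames(alignments)) %in%
    mitoChroms
  nMito <- sum(isMito)
  alignments <- alignments[!isMito]
  fb <- fragmentBlocks(alignments)
  n <- length(fb$blocks)
  out <- data.frame(read_id = fb$ids,
                    gene_id = rep(NA_character_, n),
                    overlap = rep(0L, n),
                    stringsAsFactors = FALSE)
  attr(out, "n_mito") <- nMito
  if (!n) return(out)
  feats <- featureTable(sann)
  if (!length(feats)) return(out)
  flat <- unlist(fb$blocks, use.names = FALSE)
  readIdx <- rep(seq_len(n), lengths(fb$blocks))
  hits <- findOverlaps(flat, feats, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  if (strandedness != "unstranded") {
    eff <- if (strandedness == "forward") fb$strand
           else chartr("+-", "-+", fb$strand)
    fs <- as.character(strand(feats))[s]
    ok <- fs == "*" | fs == eff[readIdx[q]]
    q <- q[ok]; s <- s[ok]
  }
  if (!length(q)) return(out)
  w <- width(pintersect(flat[q], feats[s], ignore.strand = TRUE))
  rd <- readIdx[q]
  gene <- mcols(feats)$gene[s]
  key <- (as.numeric(rd) - 1) * length(sann@genes) + gene
  agg <- rowsum(w, group = key, reorder = FALSE)
  k <- as.numeric(rownames(agg)); aw <- agg[, 1L]
  rdA <- floor((k - 1) / length(sann@genes)) + 1
  geneA <- (k - 1) %% length(sann@genes) + 1
  ord <- order(rdA, -aw, geneA)
  rdA <- rdA[ord]; geneA <- geneA[ord]; aw <- aw[ord]
  first <- !duplicated(rdA) & aw >= minOverlap
  out$gene_id[rdA[first]] <- names(sann@genes)[geneA[first]]
  out$overlap[rdA[first]] <- as.integer(aw[first])
  out
}

#' Flag per-read intron retention
#'
#' Counts, for each gene-assigned read, the number of distinct intronic
#' intervals of its gene that the read's aligned blocks overlap by at
#' least `intronMinOverlap` bases. A read is intron-containing when the
#' count is one or more.
#'
#' @param alignments the same alignments passed to [assignLongReads()]
#'   (mitochondrial reads are ignored here since they carry no gene).
#' @param assigned the assignment table from [assignLongReads()].
#' @param sann a [SanitizedAnnotation-class].
#' @param intronMinOverlap minimum bases inside an intronic interval for
#'   it to count as retained (default 20, matching the gene-assignment
#'   overlap rule).
#' @return `assigned` with an added integer column `retained_introns`
#'   and logical `intron_containing`.
#' @export
flagIntronRetention <- function(alignments, assigned, sann,
                                intronMinOverlap = 20L) {
  stopifnot(is(sann, "SanitizedAnnotation"))
  fb <- fragmentBlocks(alignments)
  idx <- match(assigned$read_id, fb$ids)
  retained <- integer(nrow(assigned))
  hasGene <- !is.na(assigned$gene_id) & !is.na(idx)
  if (any(hasGene)) {
    ino <- unlist(sann@intronic, use.names = FALSE)
    inoGene <- rep(names(sann@genes), lengths(sann@intronic))
    if (length(ino)) {
      blocks <- fb$blocks[idx[hasGene]]
      flat <- unlist(blocks, use.names = FALSE)
      rowIdx <- rep(which(hasGene), lengths(blocks))
      hits <- findOverlaps(flat, ino, ignore.strand = TRUE)
      if (length(hits)) {
        q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
        ## restrict to introns of the read's own gene
        ok <- inoGene[s] == assigned$gene_id[rowIdx[q]]
        q <- q[ok]; s <- s[ok]
        if (length(q)) {
          w <- width(pintersect(flat[q], ino[s], ignore.strand = TRUE))
          ## per (read row, intron) total overlap, to merge multi-block hits
          key <- paste(rowIdx[q], s)
          tot <- rowsum(w, group = key, reorder = FALSE)
          goodKey <- rownames(tot)[tot[, 1L] >= intronMinOverlap]
          if (length(goodKey)) {
            rows <- as.integer(sub(" .*", "", goodKey))
            cnt <- table(factor(rows, levels = seq_len(nrow(assigned))))
            retained <- as.integer(cnt)
          }
        }
      }
    }
  }
  assigned$retained_introns <- retained
  assigned$intron_containing <- retained >= 1L
  assigned
}

#' Filter poly(A) tail estimates by QC tag
#'
#' Retains exactly the tail estimates whose QC tag is not in the reject
#' set. Idempotent.
#'
#' @param tails `data.frame` with columns `read_id`, `qc_tag`,
#'   `tail_length` (the output schema of a nanopore tail-estimation
#'   step; [readTailEstimates()] maps the on-disk column names).
#' @param rejectTags tags whose reads are discarded (default
#'   `READ_FAILED_LOAD`, `SUFFCLIP`, `NOREGION`).
#' @return the retained subset, with attribute `n_rejected`.
#' @export
applyPolyaQc <- function(tails,
                         rejectTags = c("READ_FAILED_LOAD", "SUFFCLIP",
                                        "NOREGION")) {
  need <- c("read_id", "qc_tag", "tail_length")
  if (!all(need %in% names(tails)))
    stop("tail table must have columns: ", paste(need, collapse = ", "))
  keep <- !(tails$qc_tag %in% rejectTags)
  out <- tails[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Read a tail-estimate table
#'
#' Reads the standard nanopore tail-estimation TSV (columns `readname`,
#' `qc_tag`, `polya_length`, extra columns ignored) into the internal
#' schema.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `read_id`, `qc_tag`, `tail_length`.
#' @export
readTailEstimates <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("readname", "qc_tag", "polya_length")
  if (!all(need %in% names(x)))
    stop("tail TSV must have columns: ", paste(need, collapse = ", "))
  data.frame(read_id = x$readname, qc_tag = x$qc_tag,
             tail_length = as.numeric(x$polya_length),
             stringsAsFactors = FALSE)
}

#' Join gene-assigned reads with tail estimates
#'
#' Inner join on read id; reads with a surviving alignment but no usable
#' tail estimate (or vice versa) are dropped and counted.
#'
#' @param assigned table from [assignLongReads()] (optionally through
#'   [flagIntronRetention()]).
#' @param tails QC-filtered table from [applyPolyaQc()].
#' @return per-read `data.frame` (`read_id`, `gene_id`, `tail_length`,
#'   plus any retention columns), gene-assigned reads only, with
#'   attributes `n_no_tail` and `n_no_alignment`.
#' @export
joinTailEstimates <- function(assigned, tails) {
  a <- assigned[!is.na(assigned$gene_id), , drop = FALSE]
  idx <- match(a$read_id, tails$read_id)
  out <- a[!is.na(idx), , drop = FALSE]
  out$tail_length <- tails$tail_length[idx[!is.na(idx)]]
  rownames(out) <- NULL
  attr(out, "n_no_tail") <- sum(is.na(idx))
  attr(out, "n_no_alignment") <- sum(!(tails$read_id %in% a$read_id))
  out
}

#' Per-gene poly(A) tail statistics
#'
#' Per gene and condition: read count, median tail length (arithmetic
#' midpoint for even counts) and maximum tail length. Genes with fewer
#' than `minReads` reads are omitted from the statistics table (the
#' per-read table remains the record of their reads). Optionally
#' stratified by intron-containing versus fully spliced reads, or by
#' gene biotype.
#'
#' @param perRead table from [joinTailEstimates()].
#' @param condition condition label stored in the output.
#' @param minReads minimum reads per gene (default 10).
#' @param by `NULL` (default), `"retention"` (requires an
#'   `intron_containing` column) or `"biotype"` (requires `sann`).
#' @param sann annotation supplying biotypes when `by = "biotype"`.
#' @return `data.frame` with columns `gene_id`, `condition`,
#'   (`stratum`,) `n_reads`, `median_tail`, `max_tail`.
#' @export
geneTailStatistics <- function(perRead, condition = "condition",
                               minReads = 10L, by = NULL, sann = NULL) {
  if (!nrow(perRead)) {
    return(data.frame(gene_id = character(), condition = character(),
                      n_reads = integer(), median_tail = numeric(),
                      max_tail = numeric(), stringsAsFactors = FALSE))
  }
  group <- perRead$gene_id
  stratum <- NULL
  if (!is.null(by)) {
    by <- match.arg(by, c("retention", "biotype"))
    if (by == "retention") {
      if (is.null(perRead$intron_containing))
        stop("per-read table lacks intron_containing; run flagIntronRetention()")
      stratum <- ifelse(perRead$intron_containing, "intron_containing",
                        "spliced")
    } else {
      if (is.null(sann)) stop("by = 'biotype' requires sann")
      stratum <- mcols(sann@genes)$biotype[match(perRead$gene_id,
                                                 names(sann@genes))]
    }
    group <- paste(group, stratum, sep = "\r")
  }
  spl <- split(perRead$tail_length, group)
  n <- lengths(spl)
  med <- vapply(spl, median, numeric(1))
  mx <- vapply(spl, max, numeric(1))
  keep <- n >= minReads
  key <- names(spl)[keep]
  out <- data.frame(gene_id = if (is.null(stratum)) key
                    else sub("\r.*", "", key),
                    condition = rep(condition, length(key)),
                    n_reads = as.integer(n[keep]),
                    median_tail = med[keep],
                    max_tail = mx[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(stratum)) out$stratum <- sub(".*\r", "", key)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Cross-condition change in median tail length
#'
#' Per-gene difference in median poly(A) tail length between two
#' conditions (B minus A; negative values mean shorter tails in B),
#' restricted to genes with at least `minReadsEach` reads in **both**
#' conditions.
#'
#' @param statsA,statsB tables from [geneTailStatistics()] (unstratified)
#'   for the two conditions.
#' @param minReadsEach per-condition read minimum (default 35).
#' @return `data.frame` with columns `gene_id`, `n_reads_a`, `n_reads_b`,
#'   `median_a`, `median_b`, `delta_median`.
#' @export
tailLengthChange <- function(statsA, statsB, minReadsEach = 35L) {
  common <- intersect(statsA$gene_id, statsB$gene_id)
  ia <- match(common, statsA$gene_id)
  ib <- match(common, statsB$gene_id)
  ok <- statsA$n_reads[ia] >= minReadsEach & statsB$n_reads[ib] >= minReadsEach
  data.frame(gene_id = common[ok],
             n_reads_a = statsA$n_reads[ia][ok],
             n_reads_b = statsB$n_reads[ib][ok],
             median_a = statsA$median_tail[ia][ok],
             median_b = statsB$median_tail[ib][ok],
             delta_median = statsB$median_tail[ib][ok] -
               statsA$median_tail[ia][ok],
             stringsAsFactors = FALSE)
}
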