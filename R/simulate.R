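## Deterministic synthetic-data generator with planted ground truth.
## Emits annotations exhibiting the pathologies the sanitizer handles
## (overlapping gene pairs, readthrough transcripts, intronless genes,
## processed pseudogenes), stranded short-read alignments with exonic /
## intronic / upstream-readthrough components, long reads with
## per-condition poly(A) tail distributions, retention, QC-tag mixtures
## and contaminants, and differential tables with planted labels.
## Identical (seed, config) always yields byte-identical outputs.

#' Simulation configuration
#'
#' Assembles and validates the parameter set driving the synthetic-data
#' generator. Defaults emulate the statistical structure the analysis
#' assumes: poly(A) tail modes near 230 nt (nuclear IP) and 80 nt
#' (cytoplasmic IP) with a ~12 nt minimum-binding floor in IP samples,
#' reverse-stranded short-read chemistry, upstream-readthrough (DoG)
#' genes at 40% signal ratio and full flank breadth, and gencode-style
#' annotation pathologies.
#'
#' @param seed integer seed; with an identical config it makes every
#'   output byte-identical.
#' @param n_chromosomes,chrom_length genome shape (chromosomes named
#'   `chr1..chrN` plus `chrM`).
#' @param n_genes total genes to place (error if they cannot be packed).
#' @param overlap_pairs,antisense_pairs planted same-strand /
#'   opposite-strand overlapping gene pairs.
#' @param overlap_width_range sampled width in bases of each planted
#'   shared region.
#' @param readthrough_genes genes given an extra transcript tagged
#'   `readthrough_transcript` spanning their downstream neighbour.
#' @param intronless_fraction,pseudogene_fraction,lncRNA_fraction
#'   biotype/structure mixture (processed pseudogenes are intronless).
#' @param alt_tx_fraction fraction of multi-exon genes given a second,
#'   exon-skipping transcript.
#' @param max_exons maximum exons per gene (sampled 2..max for
#'   intron-bearing genes).
#' @param exon_width_range,intron_width_range sampled feature widths in
#'   bases (minimum 150 so a short read never straddles three features).
#' @param gap_range sampled intergenic gap in bases; the default keeps
#'   every nominal 2 kb upstream flank fully intergenic.
#' @param expr_meanlog,expr_sdlog log-normal fragment-count parameters
#'   per gene.
#' @param unspliced_fraction fixed per-gene pre-mRNA fraction, or `NULL`
#'   to draw per gene from `Beta(unspliced_alpha, unspliced_beta)`.
#' @param unspliced_alpha,unspliced_beta Beta parameters (defaults 2, 5).
#' @param read_length short-read length (default 75).
#' @param dog_genes,dog_upstream_ratio,dog_upstream_breadth planted
#'   upstream-readthrough genes and their signal ratio/breadth.
#' @param flank nominal upstream flank (default 2000, matching the
#'   detection rule).
#' @param conditions named list of long-read conditions, each
#'   `list(mode=, sd=, floor=)`; `floor` is the minimum tail length
#'   (truncation) for IP-like conditions, 0 for totals.
#' @param reads_per_gene long reads per gene per condition.
#' @param retention_prob per-intron retention probability per long read.
#' @param qc_reject_fraction,mapq0_fraction,supplementary_fraction,mito_fraction
#'   planted contaminant fractions among long reads.
#' @param n_diff_genes rows of the synthetic differential table.
#' @param diff_enriched_fraction,diff_depleted_fraction planted label mix.
#' @return a validated list of class `ripscape_sim_config`.
#' @export
simConfig <- function(seed = 1L,
                      n_chromosomes = 2L,
                      chrom_length = 250000L,
                      n_genes = 30L,
                      overlap_pairs = 3L,
                      antisense_pairs = 1L,
                      overlap_width_range = c(300L, 800L),
                      readthrough_genes = 2L,
                      intronless_fraction = 0.1,
                      pseudogene_fraction = 0.05,
                      lncRNA_fraction = 0.1,
                      alt_tx_fraction = 0.15,
                      max_exons = 10L,
                      exon_width_range = c(150L, 600L),
                      intron_width_range = c(150L, 1500L),
                      gap_range = c(4500L, 7000L),
                      expr_meanlog = log(300),
                      expr_sdlog = 0.6,
                      unspliced_fraction = NULL,
                      unspliced_alpha = 2,
                      unspliced_beta = 5,
                      read_length = 75L,
                      dog_genes = 3L,
                      dog_upstream_ratio = 0.4,
                      dog_upstream_breadth = 1.0,
                      flank = 2000L,
                      conditions = list(
                        nuclear_PABPN_IP = list(mode = 230, sd = 40,
                                                floor = 12),
                        cytoplasmic_PABPC_IP = list(mode = 80, sd = 40,
                                                    floor = 12)),
                      reads_per_gene = 50L,
                      retention_prob = 0.2,
                      qc_reject_fraction = 0.1,
                      mapq0_fraction = 0.05,
                      supplementary_fraction = 0.03,
                      mito_fraction = 0.03,
                      n_diff_genes = 1000L,
                      diff_enriched_fraction = 0.2,
                      diff_depleted_fraction = 0.2) {
  cfg <- as.list(environment())
  fr <- c("intronless_fraction", "pseudogene_fraction", "lncRNA_fraction",
          "alt_tx_fraction", "dog_upstream_ratio", "dog_upstream_breadth",
          "retention_prob", "qc_reject_fraction", "mapq0_fraction",
          "supplementary_fraction", "mito_fraction",
          "diff_enriched_fraction", "diff_depleted_fraction")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(f, " must be a fraction in [0, 1]")
  }
  if (!is.null(cfg$unspliced_fraction) &&
      (cfg$unspliced_fraction < 0 || cfg$unspliced_fraction > 1))
    stop("unspliced_fraction must be in [0, 1] (or NULL)")
  if (cfg$seed >= 2^31 - 10) stop("seed too large")
  class(cfg) <- "ripscape_sim_config"
  cfg
}

## ---- annotation simulation ----

#' Simulate a gene annotation with planted pathologies
#'
#' Places genes with 1-10 exons on `chr1..chrN`, then plants: overlapping
#' gene pairs (same- and opposite-strand, with known shared intervals),
#' readthrough-tagged transcripts spanning two adjacent genes, intronless
#' genes and processed pseudogenes, and second transcripts with skipped
#' exons. Gene spacing guarantees that each gene's nominal upstream flank
#' is intergenic unless an overlap was planted.
#'
#' @param cfg a [simConfig()].
#' @param dir optional output directory; when given, `annotation.gtf`,
#'   `truth_genes.tsv` and `truth_shared.tsv` are written there.
#' @return list with `annotation` (a [GeneAnnotation-class]), `truth`
#'   (list: `genes` data.frame, `shared` GRanges of planted shared
#'   intervals, `readthrough` transcript ids), and `seqlengths`.
#' @export
simulateAnnotation <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "ripscape_sim_config"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  seqlengths <- setNames(c(rep(cfg$chrom_length, cfg$n_chromosomes), 16569L),
                         c(chroms, "chrM"))
  n <- cfg$n_genes
  ids <- sprintf("G%04d", seq_len(n))

  ## structural classes
  nPseudo <- round(cfg$pseudogene_fraction * n)
  nLnc <- round(cfg$lncRNA_fraction * n)
  biotype <- rep("protein_coding", n)
  if (nPseudo > 0) biotype[seq_len(nPseudo)] <- "processed_pseudogene"
  if (nLnc > 0) biotype[nPseudo + seq_len(nLnc)] <- "lncRNA"
  biotype <- sample(biotype)
  intronless <- biotype == "processed_pseudogene"
  extra <- which(!intronless)
  nIntronless <- round(cfg$intronless_fraction * n)
  if (nIntronless > 0 && length(extra))
    intronless[sample(extra, min(nIntronless, length(extra)))] <- TRUE

  ## exon/intron structure (features >= 150 bp so a 75 nt read never
  ## straddles three features)
  structure <- lapply(seq_len(n), function(i) {
    k <- if (intronless[i]) 1L else sample(2:cfg$max_exons, 1L)
    exw <- sample(cfg$exon_width_range[1]:cfg$exon_width_range[2], k,
                  replace = TRUE)
    inw <- if (k > 1L)
      sample(cfg$intron_width_range[1]:cfg$intron_width_range[2], k - 1L,
             replace = TRUE)
    else integer()
    list(exw = exw, inw = inw, len = sum(exw) + sum(inw))
  })
  strandv <- sample(c("+", "-"), n, replace = TRUE)

  ## sequential placement with generous gaps (flank-clean by construction)
  chromOf <- character(n); startOf <- integer(n)
  ci <- 1L; cursor <- 5000L
  for (i in seq_len(n)) {
    len <- structure[[i]]$len
    while (cursor + len > seqlengths[chroms[ci]] - 3000L) {
      ci <- ci + 1L
      if (ci > length(chroms))
        stop("infeasible packing: genes exceed chromosome space; ",
             "increase chrom_length or n_chromosomes, or reduce n_genes")
      cursor <- 5000L
    }
    chromOf[i] <- chroms[ci]
    startOf[i] <- cursor
    cursor <- cursor + len + sample(cfg$gap_range[1]:cfg$gap_range[2], 1L)
  }

  ## choose special genes: overlap pairs (second of each pair is shifted
  ## onto the first), readthrough donors, DoG genes -- all disjoint roles
  ord <- seq_len(n)
  ## a planted overlap must leave >= 300 bp of each gene un-shared; the
  ## sampled width is clipped per pair so short genes still qualify
  minPairLen <- cfg$overlap_width_range[1] + 300L
  pairCandidates <- which(vapply(seq_len(n - 1L), function(i)
    chromOf[i] == chromOf[i + 1L] &&
      structure[[i]]$len > minPairLen && structure[[i + 1L]]$len > minPairLen,
    logical(1)))
  nPairs <- cfg$overlap_pairs + cfg$antisense_pairs
  ## non-adjacent pair anchors so planted overlaps never chain
  anchors <- integer()
  if (nPairs > 0L) {
    for (p in pairCandidates) {
      if (!length(anchors) || p > max(anchors) + 1L) anchors <- c(anchors, p)
      if (length(anchors) >= nPairs) break
    }
    if (length(anchors) < nPairs)
      stop("infeasible packing: not enough adjacent same-chromosome gene ",
           "pairs for the requested overlap pairs")
  }
  pairAnchor <- anchors
  pairKind <- rep(c("same", "anti"),
                  c(cfg$overlap_pairs, cfg$antisense_pairs))
  inPair <- sort(c(pairAnchor, pairAnchor + 1L))

  free <- setdiff(ord, inPair)
  rtCandidates <- free[vapply(free, function(i)
    i < n && chromOf[i] == chromOf[i + 1L] && !((i + 1L) %in% inPair),
    logical(1))]
  ## readthrough donors must also not chain
  rtPick <- integer()
  if (cfg$readthrough_genes > 0L) {
    for (p in rtCandidates) {
      if (!length(rtPick) || p > max(rtPick) + 1L) rtPick <- c(rtPick, p)
      if (length(rtPick) >= cfg$readthrough_genes) break
    }
    if (length(rtPick) < cfg$readthrough_genes)
      stop("infeasible packing: not enough free adjacent pairs for ",
           "readthrough transcripts")
  }
  free <- setdiff(free, c(rtPick, rtPick + 1L))
  if (length(free) < cfg$dog_genes)
    stop("infeasible packing: not enough free genes for DoG planting")
  dogPick <- if (cfg$dog_genes > 0) sort(sample(free, cfg$dog_genes))
             else integer()

  ## apply overlap shifts and fix pair strands
  sharedList <- list()
  for (pi in seq_along(pairAnchor)) {
    i <- pairAnchor[pi]; j <- i + 1L
    w <- sample(cfg$overlap_width_range[1]:cfg$overlap_width_range[2], 1L)
    w <- min(w, structure[[i]]$len - 300L, structure[[j]]$len - 300L)
    endI <- startOf[i] + structure[[i]]$len - 1L
    startOf[j] <- endI - w + 1L
    strandv[i] <- "+"
    strandv[j] <- if (pairKind[pi] == "same") "+" else "-"
    sharedList[[pi]] <- data.frame(
      chrom = chromOf[i], start = startOf[j], end = endI,
      same_strand = pairKind[pi] == "same",
      gene_a = ids[i], gene_b = ids[j], stringsAsFactors = FALSE)
  }
  sharedDf <- do.call(rbind, c(sharedList,
                               list(data.frame(chrom = character(),
                                               start = integer(),
                                               end = integer(),
                                               same_strand = logical(),
                                               gene_a = character(),
                                               gene_b = character()))))
  ## readthrough donor must share strand with its transcript; free choice
  for (i in rtPick) strandv[i] <- strandv[i]

  ## assemble transcripts
  exonsL <- list(); txGene <- character(); txTags <- list()
  altEligible <- which(!intronless & lengths(lapply(structure,
                                                   `[[`, "exw")) >= 3L)
  nAlt <- round(cfg$alt_tx_fraction * length(altEligible))
  altPick <- if (nAlt > 0) sort(sample(altEligible, nAlt)) else integer()
  for (i in seq_len(n)) {
    st <- structure[[i]]
    starts <- startOf[i] + cumsum(c(0L, head(st$exw, -1L) +
                                      st$inw))
    ex <- GRanges(chromOf[i], IRanges(starts, width = st$exw),
                  strand = strandv[i])
    t1 <- paste0(ids[i], ".t1")
    exonsL[[t1]] <- ex
    txGene[t1] <- ids[i]
    txTags[[t1]] <- character()
    if (i %in% altPick) {
      skip <- sample(2:(length(ex) - 1L), 1L)
      t2 <- paste0(ids[i], ".t2")
      exonsL[[t2]] <- ex[-skip]
      txGene[t2] <- ids[i]
      txTags[[t2]] <- character()
    }
  }
  ## readthrough transcripts: span donor start .. neighbour end
  for (i in rtPick) {
    j <- i + 1L
    rtId <- paste0(ids[i], ".rt")
    endJ <- startOf[j] + structure[[j]]$len - 1L
    ex <- GRanges(chromOf[i],
                  IRanges(start = c(startOf[i], endJ - 199L),
                          end = c(startOf[i] + 199L, endJ)),
                  strand = strandv[i])
    exonsL[[rtId]] <- ex
    txGene[rtId] <- ids[i]
    txTags[[rtId]] <- "readthrough_transcript"
  }

  exons <- GRangesList(exonsL)
  geneAttr <- data.frame(gene_id = ids,
                         symbol = paste0("SYM", seq_len(n)),
                         biotype = biotype, stringsAsFactors = FALSE)
  ann <- assembleAnnotation(exons, txGene, CharacterList(txTags), geneAttr)

  ## planted expression / splicing truth
  expr <- pmax(1L, as.integer(round(rlnorm(n, cfg$expr_meanlog,
                                           cfg$expr_sdlog))))
  uf <- if (is.null(cfg$unspliced_fraction))
    rbeta(n, cfg$unspliced_alpha, cfg$unspliced_beta)
  else rep(cfg$unspliced_fraction, n)
  uf[intronless] <- 0

  exonicLen <- vapply(seq_len(n), function(i) sum(structure[[i]]$exw),
                      numeric(1))
  truthGenes <- data.frame(
    gene_id = ids, chrom = chromOf, start = startOf,
    end = startOf + vapply(structure, `[[`, numeric(1), "len") - 1L,
    strand = strandv, biotype = biotype,
    n_exons = vapply(structure, function(s) length(s$exw), numeric(1)),
    exonic_length = exonicLen,
    intronic_length = vapply(structure, function(s) sum(s$inw), numeric(1)),
    expression = expr,
    unspliced_fraction = uf,
    dog = seq_len(n) %in% dogPick,
    in_overlap_pair = seq_len(n) %in% inPair,
    readthrough_donor = seq_len(n) %in% rtPick,
    stringsAsFactors = FALSE)

  shared <- if (nrow(sharedDf))
    GRanges(sharedDf$chrom, IRanges(sharedDf$start, sharedDf$end),
            same_strand = sharedDf$same_strand,
            gene_a = sharedDf$gene_a, gene_b = sharedDf$gene_b)
  else GRanges()

  out <- list(annotation = ann,
              truth = list(genes = truthGenes, shared = shared,
                           readthrough = paste0(ids[rtPick], ".rt")),
              seqlengths = seqlengths,
              config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    exportAnnotationGtf(ann, file.path(dir, "annotation.gtf"))
    write.table(truthGenes, file.path(dir, "truth_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(shared), file.path(dir, "truth_shared.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

## map a transcript-coordinate interval [s, s+len-1] (along concatenated
## exons in genomic order) to genomic blocks
txToGenomic <- function(exStarts, exWidths, s, len) {
  cum <- cumsum(exWidths)
  first <- which(s <= cum)[1L]
  res_start <- integer(); res_end <- integer()
  remaining <- len
  offset <- s - c(0L, cum)[first] - 1L
  i <- first
  while (remaining > 0L) {
    gs <- exStarts[i] + offset
    take <- min(exWidths[i] - offset, remaining)
    res_start <- c(res_start, gs)
    res_end <- c(res_end, gs + take - 1L)
    remaining <- remaining - take
    offset <- 0L
    i <- i + 1L
  }
  cbind(res_start, res_end)
}

#' Simulate stranded short-read alignments with planted truth
#'
#' Per gene, fragments are drawn in proportion to planted expression;
#' each fragment comes from a spliced transcript with probability
#' `1 - unspliced_fraction` (blocks follow the exon chain, splice
#' junctions included) and otherwise from unspliced pre-mRNA (one
#' contiguous block anywhere in the gene span). Planted DoG genes
#' additionally receive intergenic coverage across their upstream flank
#' at the configured TPM ratio and breadth. Alignment strand follows the
#' reverse-stranded (dUTP) convention. Every read carries a truth record
#' of its origin gene and compartment.
#'
#' @param sim result of [simulateAnnotation()] (same config).
#' @param sampleId sample label (also the SAM file stem when writing).
#' @param streamOffset integer added to the seed so multiple samples from
#'   one config are independent yet reproducible.
#' @param dir optional output directory; writes `<sampleId>.sam` and
#'   `truth_reads_<sampleId>.tsv`.
#' @return list with `alignments` (a [GenomicAlignments::GAlignments],
#'   names = read ids) and `truth` (per-read data.frame: `read_id`,
#'   `gene_id`, `compartment` of `exonic`/`intronic`/`upstream`).
#' @export
simulateShortReads <- function(sim, sampleId = "ip", streamOffset = 0L,
                               dir = NULL) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L + 7L * streamOffset)
  tg <- sim$truth$genes
  rl <- cfg$read_length
  ann <- sim$annotation

  parts <- vector("list", nrow(tg))
  for (i in seq_len(nrow(tg))) {
    gid <- tg$gene_id[i]
    txs <- names(ann@txGene)[ann@txGene == gid &
                               !grepl("\\.rt$", names(ann@txGene))]
    N <- tg$expression[i]
    u <- tg$unspliced_fraction[i]
    span <- c(tg$start[i], tg$end[i])
    spanLen <- span[2] - span[1] + 1L
    nUnspliced <- if (spanLen >= rl) rbinom(1L, N, u) else 0L
    nMature <- N - nUnspliced
    alnStrand <- if (tg$strand[i] == "+") "-" else "+"  # reverse chemistry

    pos <- integer(); cig <- character(); comp <- character()

    if (nMature > 0L) {
      whichTx <- sample(txs, nMature, replace = TRUE)
      for (tx in unique(whichTx)) {
        exr <- ann@exons[[tx]]
        exStarts <- start(exr); exWidths <- width(exr)
        cum <- cumsum(exWidths)
        L <- cum[length(cum)]
        n <- sum(whichTx == tx)
        if (L < rl || n == 0L) next
        s <- sample.int(L - rl + 1L, n, replace = TRUE)
        fi <- findInterval(s - 1L, cum) + 1L       # exon containing s
        off <- s - c(0L, cum)[fi] - 1L             # 0-based offset in exon
        fits <- s + rl - 1L <= cum[fi]             # read within one exon
        pos <- c(pos, exStarts[fi[fits]] + off[fits])
        cig <- c(cig, rep(paste0(rl, "M"), sum(fits)))
        for (s1 in s[!fits]) {                     # junction reads
          blk <- txToGenomic(exStarts, exWidths, s1, rl)
          w <- blk[, 2L] - blk[, 1L] + 1L
          g <- blk[-1L, 1L] - blk[-nrow(blk), 2L] - 1L
          pos <- c(pos, blk[1L, 1L])
          cig <- c(cig, paste0(w[1L], "M",
                               paste0(g, "N", w[-1L], "M", collapse = "")))
        }
        comp <- c(comp, rep("exonic", n))
      }
    }
    if (nUnspliced > 0L) {
      ## cumulative intron mask over the span for exact compartment truth;
      ## alternative transcripts are exon-skipping subsets of .t1, so the
      ## exon union (hence the mask) is .t1's chain
      ex1 <- ann@exons[[paste0(gid, ".t1")]]
      inIntron <- rep(1L, spanLen)
      for (e in seq_along(ex1))
        inIntron[(start(ex1)[e] - span[1] + 1L):(end(ex1)[e] - span[1] + 1L)] <- 0L
      cumIn <- c(0L, cumsum(inIntron))
      ss <- sample.int(spanLen - rl + 1L, nUnspliced, replace = TRUE)
      nIn <- cumIn[ss + rl] - cumIn[ss]
      pos <- c(pos, span[1] + ss - 1L)
      cig <- c(cig, rep(paste0(rl, "M"), nUnspliced))
      comp <- c(comp, ifelse(nIn * 2L > rl, "intronic", "exonic"))
    }

    ## planted upstream readthrough coverage for DoG genes
    if (tg$dog[i]) {
      nIntr <- sum(comp == "intronic")
      nExon <- sum(comp == "exonic")
      rate <- nExon / (tg$exonic_length[i] / 1000) +
        (if (tg$intronic_length[i] > 0)
           nIntr / (tg$intronic_length[i] / 1000) else 0)
      eff <- cfg$flank
      covLen <- max(rl, round(cfg$dog_upstream_breadth * eff))
      nUp <- max(ceiling((covLen - rl) / (rl - 1)) + 1L,
                 round(cfg$dog_upstream_ratio * rate * (eff / 1000)))
      if (tg$strand[i] == "+") {
        covStart <- tg$start[i] - covLen
        covEnd <- tg$start[i] - 1L
      } else {
        covStart <- tg$end[i] + 1L
        covEnd <- tg$end[i] + covLen
      }
      starts <- unique(as.integer(round(seq(covStart, covEnd - rl + 1L,
                                            length.out = nUp))))
      ## pad with repeats at the proximal end to reach nUp exactly
      starts <- c(starts, rep(covEnd - rl + 1L, nUp - length(starts)))
      pos <- c(pos, starts)
      cig <- c(cig, rep(paste0(rl, "M"), nUp))
      comp <- c(comp, rep("upstream", nUp))
    }

    if (length(pos))
      parts[[i]] <- data.frame(chrom = tg$chrom[i], pos = pos, cigar = cig,
                               strand = alnStrand, gene = gid, comp = comp,
                               stringsAsFactors = FALSE)
  }

  flat <- do.call(rbind, parts)
  out <- flattenSimReads(flat, sim$seqlengths, prefix = sampleId,
                         mapq = 60L)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeSyntheticSam(out$alignments, file.path(dir, paste0(sampleId,
                                                            ".sam")),
                      sim$seqlengths)
    write.table(out$truth,
                file.path(dir, paste0("truth_reads_", sampleId, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

## shared flattener: builds GAlignments + truth df from a flat table of
## (chrom, pos, cigar, strand, gene, comp)
flattenSimReads <- function(flat, seqlengths, prefix, mapq = 60L) {
  k <- if (is.null(flat)) 0L else nrow(flat)
  if (k) {
    chromV <- flat$chrom; posV <- flat$pos; cigarV <- flat$cigar
    strandV <- flat$strand; geneV <- flat$gene; compV <- flat$comp
    idV <- sprintf("%s_%s_%06d", prefix, geneV, seq_len(k))
  }
  if (!k) {
    gal <- GenomicAlignments::GAlignments()
    return(list(alignments = gal,
                truth = data.frame(read_id = character(),
                                   gene_id = character(),
                                   compartment = character())))
  }
  posV <- as.integer(posV)
  ord <- order(factor(chromV, levels = names(seqlengths)), posV, idV)
  gal <- GenomicAlignments::GAlignments(
    seqnames = factor(chromV[ord], levels = names(seqlengths)),
    pos = posV[ord], cigar = cigarV[ord],
    strand = factor(strandV[ord], levels = c("+", "-", "*")),
    names = idV[ord],
    seqlengths = seqlengths)
  mcols(gal)$flag <- ifelse(strandV[ord] == "-", 16L, 0L)
  mcols(gal)$mapq <- rep(as.integer(mapq), k)
  list(alignments = gal,
       truth = data.frame(read_id = idV[ord], gene_id = geneV[ord],
                          compartment = compV[ord],
                          stringsAsFactors = FALSE))
}

#' Simulate long reads and tail estimates with planted truth
#'
#' Per condition and gene, emits full-length spliced reads whose blocks
#' follow the primary exon chain with each intron independently retained
#' at the configured probability; per-read poly(A) tails are drawn from
#' the condition's truncated-Normal distribution (floored at the
#' condition's minimum-binding tail for IP-like conditions). Planted
#' fractions of reads are made MAPQ-0, supplementary, QC-rejectable or
#' mitochondrial.
#'
#' @param sim result of [simulateAnnotation()].
#' @param dir optional output directory; per condition writes
#'   `<condition>.sam`, `<condition>.polya.tsv` and
#'   `truth_longreads_<condition>.tsv`.
#' @return named list per condition: `alignments`
#'   ([GenomicAlignments::GAlignments]), `tails` (data.frame `read_id`,
#'   `qc_tag`, `tail_length`), `truth` (per-read data.frame with planted
#'   gene, retention, tail and contaminant status).
#' @export
simulateLongReads <- function(sim, dir = NULL) {
  cfg <- sim$config
  set.seed(cfg$seed + 2L)
  tg <- sim$truth$genes
  ann <- sim$annotation
  rejectTags <- c("READ_FAILED_LOAD", "SUFFCLIP", "NOREGION")
  out <- list()
  for (cond in names(cfg$conditions)) {
    cc <- cfg$conditions[[cond]]
    recs <- list()
    truthRows <- list()
    k <- 0L
    for (i in seq_len(nrow(tg))) {
      gid <- tg$gene_id[i]
      ex <- ann@exons[[paste0(gid, ".t1")]]
      nIntrons <- length(ex) - 1L
      alnStrand <- tg$strand[i]  # direct RNA aligns in sense orientation
      nr <- cfg$reads_per_gene
      ## truncated-Normal tails via inverse CDF (deterministic under seed)
      lo <- pnorm((cc$floor - cc$mode) / cc$sd)
      tails <- round(cc$mode + cc$sd * qnorm(runif(nr, lo, 1)), 2)
      retained <- if (nIntrons > 0)
        matrix(runif(nr * nIntrons) < cfg$retention_prob, nrow = nr)
      else matrix(logical(0), nrow = nr)
      isMito <- runif(nr) < cfg$mito_fraction
      isMapq0 <- runif(nr) < cfg$mapq0_fraction
      isSupp <- runif(nr) < cfg$supplementary_fraction
      isRej <- runif(nr) < cfg$qc_reject_fraction
      rejTag <- sample(rejectTags, nr, replace = TRUE)
      mitoPos <- sample.int(15000L, nr, replace = TRUE)
      reads <- vector("list", nr)
      for (r in seq_len(nr)) {
        k <- k + 1L
        id <- sprintf("lr_%s_%s_%06d", cond, gid, k)
        if (isMito[r]) {
          blocks <- cbind(mitoPos[r], mitoPos[r] + 999L)
          chrom <- "chrM"
        } else {
          keepInt <- if (nIntrons > 0) retained[r, ] else logical()
          bs <- start(ex); be <- end(ex)
          ## merge exons across retained introns
          segS <- bs[1L]; segE <- be[1L]
          resS <- integer(); resE <- integer()
          if (length(ex) > 1L) {
            for (e in 2:length(ex)) {
              if (keepInt[e - 1L]) {
                segE <- be[e]
              } else {
                resS <- c(resS, segS); resE <- c(resE, segE)
                segS <- bs[e]; segE <- be[e]
              }
            }
          }
          resS <- c(resS, segS); resE <- c(resE, segE)
          blocks <- cbind(resS, resE)
          chrom <- tg$chrom[i]
        }
        reads[[r]] <- list(blocks = blocks, compartment = "long",
                           id = id, chrom = chrom,
                           strand = alnStrand,
                           mapq = if (isMapq0[r]) 0L else 60L,
                           supp = isSupp[r],
                           qc = if (isRej[r]) rejTag[r] else "PASS",
                           tail = tails[r],
                           nRet = if (nIntrons > 0) sum(retained[r, ])
                                  else 0L,
                           mito = isMito[r])
      }
      recs[[gid]] <- reads
    }
    flat <- unlist(recs, recursive = FALSE, use.names = FALSE)
    chromV <- vapply(flat, `[[`, character(1), "chrom")
    posV <- vapply(flat, function(x) as.integer(x$blocks[1L, 1L]),
                   integer(1))
    idV <- vapply(flat, `[[`, character(1), "id")
    ord <- order(factor(chromV, levels = names(sim$seqlengths)), posV, idV)
    flat <- flat[ord]
    cig <- vapply(flat, function(x) {
      w <- x$blocks[, 2L] - x$blocks[, 1L] + 1L
      g <- if (nrow(x$blocks) > 1L)
        x$blocks[-1L, 1L] - x$blocks[-nrow(x$blocks), 2L] - 1L
      else integer()
      p <- paste0(w[1L], "M")
      if (length(g)) p <- paste0(p, paste0(g, "N", w[-1L], "M",
                                           collapse = ""))
      p
    }, character(1))
    strandV <- vapply(flat, `[[`, character(1), "strand")
    gal <- GenomicAlignments::GAlignments(
      seqnames = factor(vapply(flat, `[[`, character(1), "chrom"),
                        levels = names(sim$seqlengths)),
      pos = vapply(flat, function(x) as.integer(x$blocks[1L, 1L]),
                   integer(1)),
      cigar = cig,
      strand = factor(strandV, levels = c("+", "-", "*")),
      names = vapply(flat, `[[`, character(1), "id"),
      seqlengths = sim$seqlengths)
    flag <- ifelse(strandV == "-", 16L, 0L) +
      ifelse(vapply(flat, `[[`, logical(1), "supp"), 2048L, 0L)
    mcols(gal)$flag <- as.integer(flag)
    mcols(gal)$mapq <- vapply(flat, `[[`, integer(1), "mapq")
    truth <- data.frame(
      read_id = names(gal),
      gene_id = rep(tg$gene_id, each = cfg$reads_per_gene)[ord],
      condition = cond,
      tail_length = vapply(flat, `[[`, numeric(1), "tail"),
      qc_tag = vapply(flat, `[[`, character(1), "qc"),
      mapq0 = vapply(flat, function(x) x$mapq == 0L, logical(1)),
      supplementary = vapply(flat, `[[`, logical(1), "supp"),
      mito = vapply(flat, `[[`, logical(1), "mito"),
      retained_introns = vapply(flat, function(x) as.integer(x$nRet),
                                integer(1)),
      stringsAsFactors = FALSE)
    truth$kept_expected <- !truth$mapq0 & !truth$supplementary &
      !truth$mito & truth$qc_tag == "PASS"
    tailsDf <- data.frame(read_id = truth$read_id, qc_tag = truth$qc_tag,
                          tail_length = truth$tail_length,
                          stringsAsFactors = FALSE)
    out[[cond]] <- list(alignments = gal, tails = tailsDf, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      writeSyntheticSam(gal, file.path(dir, paste0(cond, ".sam")),
                        sim$seqlengths)
      pa <- data.frame(readname = tailsDf$read_id, qc_tag = tailsDf$qc_tag,
                       polya_length = tailsDf$tail_length)
      write.table(pa, file.path(dir, paste0(cond, ".polya.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(truth,
                  file.path(dir, paste0("truth_longreads_", cond, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Simulate a differential-abundance table with planted labels
#'
#' Gene records are partitioned into planted enriched / depleted / ns
#' labels with `baseMean`, `log2FoldChange` and `padj` drawn to respect
#' (or deliberately violate, for the ns rows) the classification
#' thresholds, including strict-inequality boundary rows
#' (`log2FoldChange` exactly at the cut) and missing-`padj` rows.
#'
#' @param cfg a [simConfig()].
#' @param dir optional output directory; writes `differential.tsv` and
#'   `truth_differential.tsv`.
#' @return list with `table` (data.frame `gene_id`, `baseMean`,
#'   `log2FoldChange`, `padj`) and `truth` (data.frame `gene_id`,
#'   `label`).
#' @export
simulateDifferentialTable <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "ripscape_sim_config"))
  set.seed(cfg$seed + 3L)
  n <- cfg$n_diff_genes
  ids <- sprintf("DG%05d", seq_len(n))
  nE <- round(cfg$diff_enriched_fraction * n)
  nD <- round(cfg$diff_depleted_fraction * n)
  label <- sample(rep(c("enriched", "depleted", "ns"),
                      c(nE, nD, n - nE - nD)))
  bm <- numeric(n); lfc <- numeric(n); padj <- numeric(n)
  isE <- label == "enriched"; isD <- label == "depleted"
  isN <- label == "ns"
  bm[isE] <- runif(sum(isE), 51, 5000)
  lfc[isE] <- runif(sum(isE), 0.6, 3)
  padj[isE] <- runif(sum(isE), 0, 0.009)
  bm[isD] <- runif(sum(isD), 51, 5000)
  lfc[isD] <- -runif(sum(isD), 0.6, 3)
  padj[isD] <- runif(sum(isD), 0, 0.009)
  ## ns rows cycle through the distinct failure modes, including exact
  ## boundary rows (strict inequalities) and missing padj
  nsIdx <- which(isN)
  mode5 <- (seq_along(nsIdx) - 1L) %% 5L
  for (m in 0:4) {
    sel <- nsIdx[mode5 == m]
    if (!length(sel)) next
    if (m == 0L) {            # log2fc exactly at the cut
      bm[sel] <- runif(length(sel), 51, 5000)
      lfc[sel] <- sample(c(0.5, -0.5), length(sel), replace = TRUE)
      padj[sel] <- runif(length(sel), 0, 0.009)
    } else if (m == 1L) {     # padj fails (non-strict cut)
      bm[sel] <- runif(length(sel), 51, 5000)
      lfc[sel] <- runif(length(sel), 0.6, 3)
      padj[sel] <- runif(length(sel), 0.011, 0.5)
    } else if (m == 2L) {     # baseMean at or below the strict cut
      bm[sel] <- sample(c(50, runif(length(sel), 0, 50)), length(sel))
      lfc[sel] <- runif(length(sel), 0.6, 3)
      padj[sel] <- runif(length(sel), 0, 0.009)
    } else if (m == 3L) {     # missing padj despite a large effect
      bm[sel] <- runif(length(sel), 51, 5000)
      lfc[sel] <- sample(c(-1, 1), length(sel), replace = TRUE) *
        runif(length(sel), 0.6, 3)
      padj[sel] <- NA_real_
    } else {                  # small effect
      bm[sel] <- runif(length(sel), 51, 5000)
      lfc[sel] <- runif(length(sel), -0.5, 0.5)
      padj[sel] <- runif(length(sel), 0, 0.009)
    }
  }
  tab <- data.frame(gene_id = ids, baseMean = bm, log2FoldChange = lfc,
                    padj = padj, stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, label = label,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(tab, file.path(dir, "differential.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(dir, "truth_differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, truth = truth)
}

#' Run the whole synthetic pipeline input generation
#'
#' Convenience wrapper generating the annotation, one input-like and one
#' IP-like short-read sample, all long-read conditions and the
#' differential table, optionally writing every output (GTF, SAM, TSV —
#' all plain text) under one directory.
#'
#' @param cfg a [simConfig()].
#' @param dir optional output directory.
#' @return list with `annotation` (the [simulateAnnotation()] result),
#'   `short` (named list of [simulateShortReads()] results for `input`
#'   and `ip`), `long` ([simulateLongReads()] result) and `differential`.
#' @export
simulateAll <- function(cfg, dir = NULL) {
  simAnn <- simulateAnnotation(cfg, dir = dir)
  short <- list(
    input = simulateShortReads(simAnn, sampleId = "input",
                               streamOffset = 0L, dir = dir),
    ip = simulateShortReads(simAnn, sampleId = "ip", streamOffset = 1L,
                            dir = dir))
  long <- simulateLongReads(simAnn, dir = dir)
  diffTab <- simulateDifferentialTable(cfg, dir = dir)
  list(annotation = simAnn, short = short, long = long,
       differential = diffTab)
}

#' Write alignments as a coordinate-sorted SAM file
#'
#' Minimal deterministic SAM writer for synthetic alignments (sequence
#' and quality fields are `*`); convert with [samToBam()] when a BAM is
#' needed.
#'
#' @param alignments a [GenomicAlignments::GAlignments] with `flag` and
#'   `mapq` metadata, named by read id.
#' @param path output SAM path.
#' @param seqlengths named chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
writeSyntheticSam <- function(alignments, path, seqlengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  if (length(alignments)) {
    ord <- order(factor(as.character(GenomicAlignments::seqnames(alignments)),
                        levels = names(seqlengths)),
                 GenomicAlignments::start(alignments))
    a <- alignments[ord]
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                    names(a), mcols(a)$flag,
                    as.character(GenomicAlignments::seqnames(a)),
                    GenomicAlignments::start(a), mcols(a)$mapq,
                    GenomicAlignments::cigar(a))
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert SAM to sorted, indexed BAM
#'
#' @param sam path to a SAM file.
#' @param destination output stem (default: the SAM path without
#'   extension); `<destination>.bam` and its index are created.
#' @return the BAM path.
#' @export
samToBam <- function(sam, destination = sub("\\.sam$", "", sam)) {
  Rsamtools::asBam(sam, destination, overwrite = TRUE,
                   indexDestination = TRUE)
}
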