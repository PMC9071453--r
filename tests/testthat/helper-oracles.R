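# Brute-force per-base oracles, independent of the package's interval
# arithmetic: genomes are materialized as per-base ownership vectors and
# every rule is applied by direct counting.

# Per-base ownership maps of a sanitized annotation.
# Returns list(chrom -> list(gene = integer vector (0 = none, i = gene i),
#                            region = integer vector (0/1 exonic/2 intronic)))
# and asserts while building that no base is claimed twice (strand-blind).
oracleBaseMaps <- function(sann, seqlengths, checkDisjoint = TRUE) {
  ids <- names(geneRanges(sann))
  maps <- lapply(seqlengths, function(L) {
    list(gene = integer(L), region = integer(L))
  })
  fill <- function(gr, gi, code) {
    for (k in seq_along(gr)) {
      ch <- as.character(GenomeInfoDb::seqnames(gr))[k]
      idx <- start(gr)[k]:end(gr)[k]
      if (checkDisjoint &&
          any(maps[[ch]]$gene[idx] != 0L & maps[[ch]]$gene[idx] != gi))
        stop("oracle: base claimed by two genes")
      maps[[ch]]$gene[idx] <<- gi
      maps[[ch]]$region[idx] <<- code
    }
  }
  ex <- exonicRegions(sann); ino <- intronicRegions(sann)
  for (i in seq_along(ids)) {
    fill(ex[[i]], i, 1L)
    fill(ino[[i]], i, 2L)
  }
  maps
}

# Per-base membership count over raw gene spans (for de-overlap checks).
oracleSpanCoverage <- function(ann, seqlengths, strand = NULL) {
  g <- geneRanges(ann)
  if (!is.null(strand)) g <- g[as.character(BiocGenerics::strand(g)) == strand]
  cov <- lapply(seqlengths, function(L) integer(L))
  for (k in seq_along(g)) {
    ch <- as.character(GenomeInfoDb::seqnames(g))[k]
    idx <- start(g)[k]:end(g)[k]
    cov[[ch]][idx] <- cov[[ch]][idx] + 1L
  }
  cov
}

# Brute-force read assignment: per read, count overlapping bases per
# (gene, region) directly on the base maps and apply the candidate /
# ambiguity / precedence rules.
oracleAssign <- function(alignments, sann, maps, minOverlap = 20,
                         strandedness = "reverse") {
  ids <- names(geneRanges(sann))
  geneStrand <- as.character(BiocGenerics::strand(geneRanges(sann)))
  grl <- GenomicAlignments::grglist(alignments)
  alnStrand <- as.character(BiocGenerics::strand(alignments))
  n <- length(grl)
  res <- data.frame(read_id = names(grl),
                    gene_id = rep(NA_character_, n),
                    region = rep(NA_character_, n),
                    status = rep("unassigned", n),
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    blocks <- grl[[r]]
    ch <- as.character(GenomeInfoDb::seqnames(blocks))[1]
    idx <- unlist(lapply(seq_along(blocks), function(b)
      start(blocks)[b]:end(blocks)[b]))
    gvec <- maps[[ch]]$gene[idx]
    rvec <- maps[[ch]]$region[idx]
    eff <- switch(strandedness,
                  reverse = chartr("+-", "-+", alnStrand[r]),
                  forward = alnStrand[r],
                  unstranded = NA_character_)
    cand <- list()
    for (gi in unique(gvec[gvec != 0L])) {
      if (!is.na(eff) && geneStrand[gi] != eff) next
      ovEx <- sum(gvec == gi & rvec == 1L)
      ovIn <- sum(gvec == gi & rvec == 2L)
      if (ovEx >= minOverlap)
        cand[[length(cand) + 1L]] <- list(g = gi, reg = "exonic", ov = ovEx)
      if (ovIn >= minOverlap)
        cand[[length(cand) + 1L]] <- list(g = gi, reg = "intronic", ov = ovIn)
    }
    if (!length(cand)) next
    genes <- unique(vapply(cand, `[[`, numeric(1), "g"))
    if (length(genes) > 1L) {
      res$status[r] <- "ambiguous"
      next
    }
    ovs <- vapply(cand, `[[`, numeric(1), "ov")
    best <- cand[ovs == max(ovs)]
    reg <- if (length(best) > 1L) "exonic" else best[[1L]]$reg
    res$gene_id[r] <- ids[genes]
    res$region[r] <- reg
    res$status[r] <- "assigned"
  }
  res
}

# Brute-force per-read intron retention count against the per-base maps.
oracleRetention <- function(alignments, assigned, sann, minOverlap = 20) {
  ino <- intronicRegions(sann)
  grl <- GenomicAlignments::grglist(alignments)
  nm <- names(grl)
  vapply(seq_len(nrow(assigned)), function(k) {
    gid <- assigned$gene_id[k]
    if (is.na(gid)) return(0L)
    blocks <- grl[[match(assigned$read_id[k], nm)]]
    idx <- unlist(lapply(seq_along(blocks), function(b)
      start(blocks)[b]:end(blocks)[b]))
    introns <- ino[[gid]]
    cnt <- 0L
    for (j in seq_along(introns)) {
      ov <- sum(idx >= start(introns)[j] & idx <= end(introns)[j])
      if (ov >= minOverlap) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
}

# Closed-form expected splicing ratio under the generator's geometry:
# exhaustive enumeration of unspliced-read start positions decides the
# probability a pre-mRNA read is binned intronic; mature reads are always
# exonic. Returns one expected ratio per gene (NA for intronless genes).
expectedSplicingRatios <- function(sim) {
  tg <- sim$truth$genes
  ann <- sim$annotation
  rl <- sim$config$read_length
  vapply(seq_len(nrow(tg)), function(i) {
    if (tg$intronic_length[i] == 0) return(NA_real_)
    ex <- exonsByTranscript(ann)[[paste0(tg$gene_id[i], ".t1")]]
    spanLen <- tg$end[i] - tg$start[i] + 1L
    inIntron <- rep(1L, spanLen)
    for (e in seq_along(ex))
      inIntron[(start(ex)[e] - tg$start[i] + 1L):
                 (end(ex)[e] - tg$start[i] + 1L)] <- 0L
    cumIn <- c(0L, cumsum(inIntron))
    ss <- seq_len(spanLen - rl + 1L)
    nIn <- cumIn[ss + rl] - cumIn[ss]
    pIn <- mean(nIn * 2L > rl)
    u <- tg$unspliced_fraction[i]
    cIn <- u * pIn
    cEx <- (1 - u) + u * (1 - pIn)
    (cIn / tg$intronic_length[i]) / (cEx / tg$exonic_length[i])
  }, numeric(1))
}

# Compact-genome configuration used for criterion-scale annotations
# (small genes and gaps so <= 100 kb genomes hold dozens of genes).
compactConfig <- function(seed, n_genes, chrom_length, overlap_pairs = 0,
                          antisense_pairs = 0, readthrough_genes = 0,
                          dog_genes = 0, ...) {
  simConfig(seed = seed, n_genes = n_genes, n_chromosomes = 1L,
            chrom_length = as.integer(chrom_length),
            overlap_pairs = overlap_pairs,
            antisense_pairs = antisense_pairs,
            readthrough_genes = readthrough_genes,
            dog_genes = dog_genes,
            max_exons = 5L,
            exon_width_range = c(250L, 450L),
            intron_width_range = c(250L, 700L),
            overlap_width_range = c(200L, 400L),
            gap_range = c(2500L, 3500L), ...)
}
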