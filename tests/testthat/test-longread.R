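# Long-read filtering, gene assignment, intron retention, poly(A) QC and
# per-gene tail statistics.

test_that("alignment filtering drops MAPQ-0, supplementary and secondary records", {
  gal <- makeAlignments("chr1",
    list(cbind(1001L, 2000L), cbind(1001L, 2000L), cbind(1001L, 2000L),
         cbind(1001L, 2000L)),
    strand = "+",
    ids = c("ok", "mapq0", "supp", "sec"),
    mapq = c(60L, 0L, 60L, 60L),
    flag = c(0L, 0L, 2048L, 256L))
  kept <- filterLongAlignments(gal)
  expect_equal(names(kept), "ok")
  nr <- attr(kept, "n_removed")
  expect_equal(unname(nr[c("mapq0", "supplementary", "secondary")]),
               c(1L, 1L, 1L))
})

test_that("gene assignment picks the largest qualifying overlap and drops chrM", {
  sann <- toyTwoGeneAnnotation()
  sl <- c(chr1 = 1000000L, chrM = 16569L)
  gal <- makeAlignments(
    c("chr1", "chr1", "chr1", "chrM"),
    list(rbind(c(1001L, 2000L), c(3001L, 4000L)),  # full exon chain of A
         cbind(9481L, 10030L),                     # 520 nt on B, rest outside
         cbind(4500L, 4600L),                      # intergenic
         cbind(100L, 1099L)),                      # mitochondrial
    strand = "+",
    ids = c("full", "partial", "none", "mito"),
    seqlengths = sl)
  asg <- assignLongReads(gal, sann)
  expect_equal(attr(asg, "n_mito"), 1L)
  expect_false("mito" %in% asg$read_id)
  expect_equal(asg$gene_id[asg$read_id == "full"], "A")
  expect_equal(asg$overlap[asg$read_id == "full"], 2000L)
  expect_equal(asg$gene_id[asg$read_id == "partial"], "B")
  expect_true(is.na(asg$gene_id[asg$read_id == "none"]))

  # below the overlap floor: 15 nt on B only
  galLow <- makeAlignments("chr1", list(cbind(9986L, 10060L)),
                           strand = "+", ids = "low", seqlengths = sl)
  expect_true(is.na(assignLongReads(galLow, sann)$gene_id))
})

test_that("intron retention counts distinct overlapped introns per read", {
  # gene with exons 1-200, 801-1000, 1601-1800 (introns 201-800, 1001-1600)
  sann <- sanitizeAnnotation(toyAnnotation(c(
    gtfExonLine("chr1", 1, 200, "+", "G", "G.t1"),
    gtfExonLine("chr1", 801, 1000, "+", "G", "G.t1"),
    gtfExonLine("chr1", 1601, 1800, "+", "G", "G.t1"))))
  gal <- makeAlignments("chr1", list(
    rbind(c(1L, 200L), c(801L, 1000L), c(1601L, 1800L)),  # spliced
    rbind(c(1L, 1000L), c(1601L, 1800L)),                  # intron 1 retained
    cbind(1L, 1800L),                                      # both retained
    rbind(c(1L, 210L), c(801L, 1000L)),       # 10 nt into intron 1: below floor
    rbind(c(1L, 230L), c(801L, 1000L))),      # 30 nt into intron 1: retained
    strand = "+",
    ids = c("spliced", "one", "two", "tip", "deep"))
  asg <- flagIntronRetention(gal, assignLongReads(gal, sann), sann)
  expect_equal(asg$retained_introns[match(c("spliced", "one", "two",
                                            "tip", "deep"), asg$read_id)],
               c(0L, 1L, 2L, 0L, 1L))
  expect_equal(asg$intron_containing,
               asg$retained_introns >= 1L)
})

test_that("synthetic retention flags match truth and the per-base oracle", {
  cfg <- simConfig(seed = 17, n_genes = 8, n_chromosomes = 1,
                   chrom_length = 120000L, overlap_pairs = 0,
                   antisense_pairs = 0, readthrough_genes = 0,
                   dog_genes = 0, reads_per_gene = 15,
                   mito_fraction = 0, mapq0_fraction = 0,
                   supplementary_fraction = 0, qc_reject_fraction = 0)
  sim <- simulateAnnotation(cfg)
  sann <- sanitizeAnnotation(sim$annotation)
  lr <- simulateLongReads(sim)[[1]]
  asg <- flagIntronRetention(lr$alignments,
                             assignLongReads(lr$alignments, sann), sann)
  truth <- lr$truth[match(asg$read_id, lr$truth$read_id), ]
  expect_identical(asg$gene_id, truth$gene_id)
  expect_identical(asg$retained_introns, truth$retained_introns)
  orc <- oracleRetention(lr$alignments, asg, sann)
  expect_identical(asg$retained_introns, orc)

  # retention probability 1 marks every read of intron-bearing genes
  cfgAll <- simConfig(seed = 17, n_genes = 8, n_chromosomes = 1,
                      chrom_length = 120000L, overlap_pairs = 0,
                      antisense_pairs = 0, readthrough_genes = 0,
                      dog_genes = 0, reads_per_gene = 5,
                      retention_prob = 1, mito_fraction = 0,
                      mapq0_fraction = 0, supplementary_fraction = 0,
                      qc_reject_fraction = 0)
  simAll <- simulateAnnotation(cfgAll)
  sannAll <- sanitizeAnnotation(simAll$annotation)
  lrAll <- simulateLongReads(simAll)[[1]]
  asgAll <- flagIntronRetention(lrAll$alignments,
                                assignLongReads(lrAll$alignments, sannAll),
                                sannAll)
  rl <- regionLengths(sannAll)
  intronBearing <- rl$gene_id[!rl$intronless]
  expect_true(all(asgAll$intron_containing[asgAll$gene_id %in%
                                             intronBearing]))
})

test_that("QC-tag filtering keeps exactly the non-rejected estimates", {
  tails <- data.frame(
    read_id = paste0("r", 1:4),
    qc_tag = c("PASS", "SUFFCLIP", "NOREGION", "READ_FAILED_LOAD"),
    tail_length = c(100, 90, 80, 70))
  kept <- applyPolyaQc(tails)
  expect_equal(kept$read_id, "r1")
  expect_equal(attr(kept, "n_rejected"), 3L)
  # idempotent
  again <- applyPolyaQc(kept)
  expect_equal(again$read_id, kept$read_id)
  expect_equal(attr(again, "n_rejected"), 0L)
  # empty stream
  expect_equal(nrow(applyPolyaQc(tails[0, ])), 0L)
})

test_that("planted contaminant counts are removed exactly and the join is lossless", {
  cfg <- simConfig(seed = 29, n_genes = 10, n_chromosomes = 1,
                   chrom_length = 150000L, overlap_pairs = 0,
                   antisense_pairs = 0, readthrough_genes = 0,
                   dog_genes = 0, reads_per_gene = 40)
  sim <- simulateAnnotation(cfg)
  sann <- sanitizeAnnotation(sim$annotation)
  lr <- simulateLongReads(sim)[[1]]
  truth <- lr$truth

  kept <- filterLongAlignments(lr$alignments)
  nr <- attr(kept, "n_removed")
  expect_equal(unname(nr["mapq0"]), sum(truth$mapq0 & !truth$supplementary))
  expect_equal(unname(nr["supplementary"]), sum(truth$supplementary))

  asg <- assignLongReads(kept, sann)
  expect_equal(attr(asg, "n_mito"),
               sum(truth$mito & !truth$mapq0 & !truth$supplementary))

  tails <- applyPolyaQc(lr$tails)
  expect_equal(attr(tails, "n_rejected"), sum(truth$qc_tag != "PASS"))

  pr <- joinTailEstimates(asg, tails)
  expect_setequal(pr$read_id, truth$read_id[truth$kept_expected])
  # survivors join losslessly: every kept read has its planted tail
  expect_equal(pr$tail_length,
               truth$tail_length[match(pr$read_id, truth$read_id)])
})

test_that("tail statistics honor the read minimum and midpoint median", {
  perRead <- data.frame(
    gene_id = c(rep("A", 3), rep("B", 4)),
    read_id = paste0("r", 1:7),
    tail_length = c(50, 100, 150, 10, 20, 30, 40))
  st <- geneTailStatistics(perRead, condition = "n", minReads = 1)
  expect_equal(st$median_tail[st$gene_id == "A"], 100)
  expect_equal(st$max_tail[st$gene_id == "A"], 150)
  expect_equal(st$median_tail[st$gene_id == "B"], 25)  # even-n midpoint
  # genes below the floor are omitted
  st10 <- geneTailStatistics(perRead, condition = "n", minReads = 10)
  expect_equal(nrow(st10), 0L)
  st4 <- geneTailStatistics(perRead, condition = "n", minReads = 4)
  expect_equal(st4$gene_id, "B")
  # order invariance
  perm <- sample(nrow(perRead))
  stP <- geneTailStatistics(perRead[perm, ], condition = "n", minReads = 1)
  expect_equal(stP, st)
})

test_that("tail-length change requires the per-condition read floor", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  n_reads = c(50L, 34L, 60L),
                  median_tail = c(230, 230, 230))
  b <- data.frame(gene_id = c("g1", "g2", "g3"),
                  n_reads = c(40L, 80L, 35L),
                  median_tail = c(80, 80, 100))
  d <- tailLengthChange(a, b, minReadsEach = 35)
  expect_setequal(d$gene_id, c("g1", "g3"))   # g2 fails in condition A
  expect_equal(d$delta_median[d$gene_id == "g1"], -150)
  expect_equal(d$delta_median[d$gene_id == "g3"], -130)
})

test_that("QC and alignment filtering commute", {
  cfg <- simConfig(seed = 41, n_genes = 6, n_chromosomes = 1,
                   chrom_length = 100000L, overlap_pairs = 0,
                   antisense_pairs = 0, readthrough_genes = 0,
                   dog_genes = 0, reads_per_gene = 25)
  sim <- simulateAnnotation(cfg)
  sann <- sanitizeAnnotation(sim$annotation)
  lr <- simulateLongReads(sim)[[1]]
  # order A: alignment filter then QC join
  prA <- joinTailEstimates(
    assignLongReads(filterLongAlignments(lr$alignments), sann),
    applyPolyaQc(lr$tails))
  # order B: QC first, then alignment filter
  tailsB <- applyPolyaQc(lr$tails)
  asgB <- assignLongReads(filterLongAlignments(lr$alignments), sann)
  prB <- joinTailEstimates(asgB, tailsB)
  expect_equal(prA[order(prA$read_id), ], prB[order(prB$read_id), ])
  # tail stats invariant to read order
  s1 <- geneTailStatistics(prA, "c")
  s2 <- geneTailStatistics(prA[rev(seq_len(nrow(prA))), ], "c")
  expect_equal(s1, s2)
})

test_that("tail table round-trips through the nanopore TSV schema", {
  cfg <- simConfig(seed = 2, n_genes = 5, n_chromosomes = 1,
                   chrom_length = 100000L, overlap_pairs = 0,
                   antisense_pairs = 0, readthrough_genes = 0, dog_genes = 0,
                   reads_per_gene = 5)
  sim <- simulateAnnotation(cfg)
  dir <- tempfile(); dir.create(dir)
  lr <- simulateLongReads(sim, dir = dir)
  cond <- names(lr)[1]
  back <- readTailEstimates(file.path(dir, paste0(cond, ".polya.tsv")))
  expect_equal(back, lr[[cond]]$tails)
})
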