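# Annotation sanitization: GTF parsing, supplemental merge, readthrough
# removal, de-overlap and intron derivation.

test_that("GTF parsing converts coordinates and validates structure", {
  ann <- toyAnnotation(gtfExonLine("chr1", 101, 200, "+", "G1", "G1.t1"))
  g <- geneRanges(ann)
  expect_equal(unname(width(g)), 100L)
  expect_equal(unname(start(g)), 101L)
  expect_equal(mcols(g)$biotype, "protein_coding")

  # empty file -> empty annotation, no error
  empty <- loadAnnotation(writeGtf(character()))
  expect_s4_class(empty, "GeneAnnotation")
  expect_length(geneRanges(empty), 0L)

  # malformed line names the line number
  bad <- writeGtf(c(gtfExonLine("chr1", 1, 10, "+", "G", "G.t"),
                    "chr1\tonly\tthree"))
  expect_error(loadAnnotation(bad), "line 2")

  # two transcripts of one gene on opposite strands
  expect_error(toyAnnotation(c(
    gtfExonLine("chr1", 101, 200, "+", "G1", "G1.t1"),
    gtfExonLine("chr1", 301, 400, "-", "G1", "G1.t2"))),
    "strand")

  # exon without gene_id
  noid <- writeGtf("chr1\ttest\texon\t1\t10\t.\t+\t.\ttranscript_id \"t\";")
  expect_error(loadAnnotation(noid), "gene_id")
})

test_that("supplemental genes merge by id with conflicts deferring to primary", {
  primary <- toyAnnotation(c(
    gtfExonLine("chr1", 1001, 2000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 5001, 6000, "+", "B", "B.t1")))
  supplement <- toyAnnotation(c(
    gtfExonLine("chr1", 5001, 6500, "+", "B", "B.alt"),  # conflicting coords
    gtfExonLine("chr1", 9001, 9500, "-", "C", "C.t1")))

  merged <- mergeSupplementalGenes(primary, supplement)
  expect_setequal(names(geneRanges(merged)), c("A", "B", "C"))
  expect_equal(metadata(merged)$added_genes, "C")
  expect_equal(metadata(merged)$merge_conflicts, "B")
  # B kept as in primary
  expect_equal(unname(end(geneRanges(merged)["B"])), 6000L)

  # empty supplement is the identity
  emptySup <- loadAnnotation(writeGtf(character()))
  same <- mergeSupplementalGenes(primary, emptySup)
  expect_identical(names(geneRanges(same)), names(geneRanges(primary)))
  expect_length(metadata(same)$added_genes, 0L)
})

test_that("merged overlapping supplemental gene is resolved by de-overlap", {
  primary <- toyAnnotation(gtfExonLine("chr1", 1001, 3000, "+", "A", "A.t1"))
  supplement <- toyAnnotation(gtfExonLine("chr1", 2501, 4000, "+", "X", "X.t1"))
  sann <- sanitizeAnnotation(mergeSupplementalGenes(primary, supplement))
  # brute-force disjointness: no base claimed by both genes
  maps <- oracleBaseMaps(sann, c(chr1 = 5000L))
  expect_true(all(maps$chr1$gene %in% c(0L, 1L, 2L)))
  # the shared stretch 2501-3000 belongs to neither
  expect_true(all(maps$chr1$gene[2501:3000] == 0L))
})

test_that("readthrough-tagged transcripts are dropped and spans recomputed", {
  ann <- toyAnnotation(c(
    gtfExonLine("chr1", 1001, 2000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 1001, 1200, "+", "A", "A.rt",
                tag = "readthrough_transcript"),
    gtfExonLine("chr1", 5801, 6000, "+", "A", "A.rt",
                tag = "readthrough_transcript"),
    gtfExonLine("chr1", 5001, 6000, "+", "B", "B.t1")))
  out <- dropReadthroughTranscripts(ann)
  expect_equal(metadata(out)$dropped_readthrough, "A.rt")
  expect_equal(unname(end(geneRanges(out)["A"])), 2000L)  # hull recomputed
  expect_length(metadata(out)$dropped_genes, 0L)

  # gene whose only transcript is tagged is dropped and reported
  ann2 <- toyAnnotation(c(
    gtfExonLine("chr1", 1001, 2000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 5001, 6000, "+", "B", "B.rt",
                tag = "readthrough_transcript")))
  out2 <- dropReadthroughTranscripts(ann2)
  expect_equal(metadata(out2)$dropped_genes, "B")
  expect_false("B" %in% names(geneRanges(out2)))

  # annotation without tags passes through unchanged
  clean <- toyAnnotation(c(
    gtfExonLine("chr1", 1001, 2000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 5001, 6000, "+", "B", "B.t1")))
  out3 <- dropReadthroughTranscripts(clean)
  expect_identical(geneRanges(out3), geneRanges(clean))
  expect_identical(exonsByTranscript(out3), exonsByTranscript(clean))
})

test_that("shared-region removal matches interval arithmetic examples", {
  # A=[1001,2000], B=[1501,2500] same strand, blind mode
  ann <- toyAnnotation(c(
    gtfExonLine("chr1", 1001, 2000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 1501, 2500, "+", "B", "B.t1")))
  sann <- sanitizeAnnotation(ann, strandMode = "blind")
  rs <- removedShared(sann)
  expect_equal(unname(start(rs)), 1501L)
  expect_equal(unname(end(rs)), 2000L)
  expect_equal(unname(start(exonicRegions(sann)[["A"]])), 1001L)
  expect_equal(unname(end(exonicRegions(sann)[["A"]])), 1500L)
  expect_equal(unname(start(exonicRegions(sann)[["B"]])), 2001L)

  # same coordinates on opposite strands, aware mode: nothing removed
  ann2 <- toyAnnotation(c(
    gtfExonLine("chr1", 1001, 2000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 1501, 2500, "-", "B", "B.t1")))
  sann2 <- sanitizeAnnotation(ann2, strandMode = "aware")
  expect_length(removedShared(sann2), 0L)
  expect_equal(unname(width(exonicRegions(sann2)[["A"]])), 1000L)
  # blind mode on the same input does remove
  sann2b <- sanitizeAnnotation(ann2, strandMode = "blind")
  expect_equal(sum(width(removedShared(sann2b))), 500L)
})

test_that("triple-tiled genes lose every base covered twice or more (oracle)", {
  ann <- toyAnnotation(c(
    gtfExonLine("chr1", 1001, 4000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 3001, 7000, "+", "B", "B.t1"),
    gtfExonLine("chr1", 3501, 9000, "+", "C", "C.t1")))
  sann <- sanitizeAnnotation(ann)
  # brute-force per-base membership count over the toy chromosome
  cov <- oracleSpanCoverage(ann, c(chr1 = 10000L))$chr1
  expectRemoved <- which(cov >= 2L)
  got <- sort(unlist(lapply(seq_along(removedShared(sann)), function(k)
    start(removedShared(sann))[k]:end(removedShared(sann))[k])))
  expect_identical(as.integer(got), as.integer(expectRemoved))
  # total disjointness after removal
  maps <- oracleBaseMaps(sann, c(chr1 = 10000L))
  claimed <- which(maps$chr1$gene != 0L)
  expect_true(all(cov[claimed] == 1L))
})

test_that("intron derivation is span minus exons minus shared", {
  # single transcript: span 1-1000-ish with terminal exons
  ann <- toyAnnotation(c(
    gtfExonLine("chr1", 1, 200, "+", "A", "A.t1"),
    gtfExonLine("chr1", 801, 1000, "+", "A", "A.t1")))
  sann <- sanitizeAnnotation(ann)
  intr <- intronicRegions(sann)[["A"]]
  expect_equal(unname(start(intr)), 201L)
  expect_equal(unname(end(intr)), 800L)
  expect_equal(sum(width(intr)), 600L)
  expect_false(regionLengths(sann)$intronless)

  # single-exon gene: intronless
  ann1 <- toyAnnotation(gtfExonLine("chr1", 1, 500, "+", "S", "S.t1"))
  sann1 <- sanitizeAnnotation(ann1)
  expect_length(intronicRegions(sann1)[["S"]], 0L)
  expect_true(regionLengths(sann1)$intronless)

  # two transcripts with different exon chains: intron = span minus union
  ann2 <- toyAnnotation(c(
    gtfExonLine("chr1", 1, 200, "+", "A", "A.t1"),
    gtfExonLine("chr1", 801, 1000, "+", "A", "A.t1"),
    gtfExonLine("chr1", 401, 500, "+", "A", "A.t2"),
    gtfExonLine("chr1", 801, 1000, "+", "A", "A.t2")))
  sann2 <- sanitizeAnnotation(ann2)
  # per-base oracle: exon union is 1-200, 401-500, 801-1000
  maps <- oracleBaseMaps(sann2, c(chr1 = 1500L))
  expect_identical(which(maps$chr1$region == 2L),
                   c(201:400, 501:800))
})

test_that("conservation, idempotence and order independence hold", {
  cfg <- simConfig(seed = 11, n_genes = 20, n_chromosomes = 1,
                   chrom_length = 250000L, overlap_pairs = 2,
                   antisense_pairs = 1, readthrough_genes = 1,
                   dog_genes = 0)
  sim <- simulateAnnotation(cfg)
  ann <- dropReadthroughTranscripts(sim$annotation)
  sann <- deriveIntronRegions(removeSharedRegions(ann))

  # conservation: exonic + intronic + shared-within-span = span
  g <- geneRanges(sann)
  rl <- regionLengths(sann)
  sharedWithin <- vapply(seq_along(g), function(i)
    sum(width(GenomicRanges::intersect(removedShared(sann), granges(g[i]),
                                       ignore.strand = TRUE))),
    numeric(1))
  expect_equal(rl$exonic_length + rl$intronic_length + sharedWithin,
               unname(width(g)))

  # idempotence: sanitizing the sanitized exonic sets changes nothing
  sann2 <- deriveIntronRegions(removeSharedRegions(ann))
  expect_identical(exonicRegions(sann), exonicRegions(sann2))
  expect_identical(intronicRegions(sann), intronicRegions(sann2))

  # order independence: permuting input transcripts yields identical sets
  perm <- sample(length(ann@exons))
  annP <- new("GeneAnnotation",
              genes = ann@genes[sample(length(ann@genes))],
              exons = ann@exons[perm],
              txGene = ann@txGene[perm],
              txTags = ann@txTags[perm])
  sannP <- deriveIntronRegions(removeSharedRegions(annP))
  ids <- names(geneRanges(sann))
  expect_setequal(ids, names(geneRanges(sannP)))
  for (id in ids) {
    expect_identical(exonicRegions(sann)[[id]], exonicRegions(sannP)[[id]])
    expect_identical(intronicRegions(sann)[[id]],
                     intronicRegions(sannP)[[id]])
  }
})

test_that("sanitized annotation round-trips through GTF and BED export", {
  cfg <- simConfig(seed = 3, n_genes = 12, n_chromosomes = 1,
                   chrom_length = 150000L, overlap_pairs = 1,
                   antisense_pairs = 0, readthrough_genes = 1, dog_genes = 0)
  sim <- simulateAnnotation(cfg)
  gtf <- tempfile(fileext = ".gtf")
  exportAnnotationGtf(sim$annotation, gtf)
  rt <- loadAnnotation(gtf)
  expect_setequal(names(geneRanges(rt)), names(geneRanges(sim$annotation)))
  expect_identical(unname(ranges(geneRanges(rt)[names(geneRanges(sim$annotation))])),
                   unname(ranges(geneRanges(sim$annotation))))
  # readthrough tags survive the round trip
  sannA <- sanitizeAnnotation(sim$annotation)
  sannB <- sanitizeAnnotation(rt)
  expect_setequal(droppedReadthrough(sannA), droppedReadthrough(sannB))
  expect_identical(regionLengths(sannA), regionLengths(sannB))

  prefix <- tempfile()
  files <- exportSanitizedAnnotation(sannA, prefix)
  expect_true(all(file.exists(files)))
  bed <- rtracklayer::import(files[["exonic"]], format = "bed")
  expect_setequal(unique(bed$name), names(geneRanges(sannA)))
})
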