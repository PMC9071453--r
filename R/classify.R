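## Enrichment/depletion classification of an externally produced
## differential-abundance table, Venn-style set overlaps, and the
## histone-gene background ratio filter.

#' Classify genes as enriched, depleted or not significant
#'
#' Applies fixed thresholds to a differential-abundance results table
#' (columns `gene_id`, `baseMean`, `log2FoldChange`, `padj`): enriched
#' when `log2FoldChange > lfc`, depleted when `log2FoldChange < -lfc`,
#' in both cases requiring `padj <= padjMax` and `baseMean > baseMeanMin`;
#' everything else (including rows with missing `padj`, as produced by
#' independent filtering) is `ns`. The fold-change and baseMean cuts are
#' strict inequalities; the adjusted-p cut is non-strict.
#'
#' @param diff `data.frame` with columns `gene_id`, `baseMean`,
#'   `log2FoldChange`, `padj` (extra columns are ignored).
#' @param lfc,padjMax,baseMeanMin thresholds
#'   (defaults 0.5, 0.01, 50).
#' @return `data.frame` with columns `gene_id` and `klass`
#'   (`"enriched"`, `"depleted"`, `"ns"`).
#' @examples
#' d <- data.frame(gene_id = c("a", "b", "c"),
#'                 baseMean = c(60, 60, 60),
#'                 log2FoldChange = c(0.6, 0.5, -0.8),
#'                 padj = c(0.005, 0.005, NA))
#' classifyGenes(d)$klass  # enriched, ns (strict >), ns (missing padj)
#' @export
classifyGenes <- function(diff, lfc = 0.5, padjMax = 0.01,
                          baseMeanMin = 50) {
  need <- c("gene_id", "baseMean", "log2FoldChange", "padj")
  if (!all(need %in% names(diff)))
    stop("differential table must have columns: ",
         paste(need, collapse = ", "))
  sig <- !is.na(diff$padj) & diff$padj <= padjMax &
    !is.na(diff$baseMean) & diff$baseMean > baseMeanMin &
    !is.na(diff$log2FoldChange)
  klass <- rep("ns", nrow(diff))
  klass[sig & diff$log2FoldChange > lfc] <- "enriched"
  klass[sig & diff$log2FoldChange < -lfc] <- "depleted"
  data.frame(gene_id = diff$gene_id, klass = klass,
             stringsAsFactors = FALSE)
}

#' Overlap enrichment classifications of two comparisons
#'
#' Venn-style set algebra over the enriched and depleted gene sets of two
#' IP-versus-input comparisons computed on the same gene universe.
#'
#' @param classesA,classesB tables from [classifyGenes()].
#' @return list with elements `enriched` and `depleted`, each a list of
#'   `only_a`, `only_b`, `both` (character id vectors) plus a `counts`
#'   named integer vector.
#' @export
overlapSets <- function(classesA, classesB) {
  if (!identical(sort(classesA$gene_id), sort(classesB$gene_id)))
    stop("classifications cover different gene universes")
  one <- function(kl) {
    a <- classesA$gene_id[classesA$klass == kl]
    b <- classesB$gene_id[classesB$klass == kl]
    res <- list(only_a = sort(setdiff(a, b)),
                only_b = sort(setdiff(b, a)),
                both = sort(intersect(a, b)))
    res$counts <- c(only_a = length(res$only_a),
                    only_b = length(res$only_b),
                    both = length(res$both))
    res
  }
  list(enriched = one("enriched"), depleted = one("depleted"))
}

#' Histone-gene background ratio filter
#'
#' Replication-dependent histone transcripts are non-polyadenylated and
#' depleted from poly(A)-binding-protein IPs, so their IP/input TPM ratio
#' estimates the nonspecific background. Any gene whose own ratio falls
#' below a summary statistic of the histone ratios is removed.
#'
#' @param tpmIp,tpmInput [combinedTpm()] tables for the IP and input
#'   samples (same gene universe and order).
#' @param histoneIds character vector of histone gene ids; at least one
#'   must be present in the tables.
#' @param summary `"median"` (default) or `"max"`: the statistic of the
#'   histone ratios used as the background threshold.
#' @param pseudocount added to numerator and denominator TPM before the
#'   ratio (default 0.5), so zero-TPM genes behave continuously.
#' @return list with `retained` and `removed` (character id vectors),
#'   `threshold`, and `ratios` (`data.frame` of gene_id, ratio).
#' @export
backgroundThresholdFilter <- function(tpmIp, tpmInput, histoneIds,
                                      summary = c("median", "max"),
                                      pseudocount = 0.5) {
  summary <- match.arg(summary)
  stopifnot(identical(tpmIp$gene_id, tpmInput$gene_id))
  if (!length(histoneIds))
    stop("histoneIds must be nonempty")
  present <- histoneIds %in% tpmIp$gene_id
  if (!any(present))
    stop("no histone gene detected in the TPM tables")
  ratio <- (tpmIp$tpm_combined + pseudocount) /
    (tpmInput$tpm_combined + pseudocount)
  hr <- ratio[match(histoneIds[present], tpmIp$gene_id)]
  thr <- if (summary == "median") median(hr) else max(hr)
  keep <- ratio >= thr
  list(retained = tpmIp$gene_id[keep],
       removed = tpmIp$gene_id[!keep],
       threshold = thr,
       ratios = data.frame(gene_id = tpmIp$gene_id, ratio = ratio,
                           stringsAsFactors = FALSE))
}
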