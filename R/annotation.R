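#' Segmental duplication coverage of partitions
#'
#' Fraction of each partition's bases covered by the union of an interval
#' set (intervals are merged before measuring, so overlapping or abutting
#' pieces are never double counted).
#'
#' @param partitions a [partition_table].
#' @param intervals interval `data.frame` (`chrom`, `start`, `end`, 0-based
#'   half-open), e.g. segmental duplications from [read_bed()].
#' @return Numeric vector in `[0, 1]`, one fraction per partition.
#' @export
segdup_fraction <- function(partitions, intervals) {
  if (!nrow(intervals)) return(rep(0, nrow(partitions)))
  merged <- GenomicRanges::reduce(intervals_as_granges(intervals))
  pg <- partitions_as_granges(partitions)
  covered <- rep(0, nrow(partitions))
  ov <- GenomicRanges::findOverlaps(pg, merged)
  if (length(ov)) {
    inter <- GenomicRanges::pintersect(pg[S4Vectors::queryHits(ov)],
                                       merged[S4Vectors::subjectHits(ov)])
    w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(w))] <- w
  }
  covered / (partitions$end - partitions$start)
}

#' Flag the most tissue-specific genes
#'
#' Flags the top fraction of genes by a tissue-specificity statistic (e.g.
#' cortex-vs-nonbrain specific expression t). Exactly
#' `ceiling(top_fraction * n)` genes are flagged; ties at the cutoff are
#' broken deterministically by gene id order.
#'
#' @param genes gene `data.frame` with a `specificity_t` column.
#' @param top_fraction fraction of genes to flag (default 0.10, the top
#'   decile).
#' @return `genes` with a logical `brain_specific` column.
#' @export
brain_specific_set <- function(genes, top_fraction = 0.10) {
  if (!"specificity_t" %in% names(genes) || anyNA(genes$specificity_t)) {
    stop("genes must carry a complete specificity_t column")
  }
  m <- ceiling(top_fraction * nrow(genes))
  picked <- order(-genes$specificity_t, genes$gene_id)[seq_len(m)]
  genes$brain_specific <- seq_len(nrow(genes)) %in% picked
  genes
}

#' Residual test for regional gene-class density
#'
#' Regresses the per-partition count of a gene class (e.g. cortex-specific
#' genes) on the total gene count (OLS with intercept), standardizes the
#' residuals to z-scores, and reports two-sided normal-tail p-values. A
#' large positive z marks a partition with more class genes than its total
#' gene count predicts.
#'
#' @param specific_counts,total_counts per-partition counts (same length,
#'   >= 3 partitions).
#' @return `data.frame` with `residual_z` and `p_value` per partition.
#' @export
density_residual_test <- function(specific_counts, total_counts) {
  stopifnot(length(specific_counts) == length(total_counts))
  if (length(total_counts) < 3) stop("need at least 3 partitions")
  if (stats::sd(total_counts) == 0) stop("total counts are constant")
  fit <- stats::lm(specific_counts ~ total_counts)
  r <- stats::resid(fit)
  s <- stats::sd(r)
  # exactly proportional counts leave no residual spread
  z <- if (s < max(abs(specific_counts), 1) * 1e-12) r * 0 else r / s
  data.frame(residual_z = unname(z),
             p_value = 2 * stats::pnorm(-abs(unname(z))))
}

#' Pearson correlation of per-partition values
#'
#' @param x,y numeric vectors (>= 3 pairs, non-constant).
#' @return List with `r` and the two-sided t-based `p_value`.
#' @export
density_correlation <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Chi-square enrichment of a gene class in a region
#'
#' 2x2 chi-square test (without continuity correction) of hit status
#' against region membership. `expected_hits` is the count of in-region
#' hits expected under proportionality,
#' `genome_hits * region_total / genome_total`. A warning recommends an
#' exact test when any expected cell is below 5.
#'
#' @param region_hits hits inside the region.
#' @param region_total genes inside the region.
#' @param genome_hits hits genome wide (including the region).
#' @param genome_total genes genome wide.
#' @return List: `chi2`, `p_value`, `expected_hits`.
#' @export
enrichment_chi2 <- function(region_hits, region_total, genome_hits,
                            genome_total) {
  if (region_total > genome_total ||
      region_hits > min(region_total, genome_hits)) {
    stop("inconsistent counts")
  }
  tab <- matrix(c(region_hits, region_total - region_hits,
                  genome_hits - region_hits,
                  (genome_total - region_total) -
                    (genome_hits - region_hits)),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in 2x2 table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected cell count < 5; consider an exact test")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p_value = ct$p.value,
       expected_hits = genome_hits * region_total / genome_total)
}

#' Replicate-averaged peak density z-scores
#'
#' For each replicate interval set (e.g. H3K27ac ChIP peaks), counts the
#' peaks whose midpoint lies in each partition, standardizes the counts to
#' mean 0 / s.d. 1 across partitions, then averages the z-scores across
#' replicates. Midpoint assignment avoids double counting peaks that span a
#' partition boundary.
#'
#' @param peak_sets list of interval `data.frame`s (one per replicate).
#' @param partitions a [partition_table] (>= 2 partitions).
#' @return Numeric vector: averaged z per partition.
#' @export
peak_density_z <- function(peak_sets, partitions) {
  if (!length(peak_sets)) stop("need at least one replicate")
  if (nrow(partitions) < 2) stop("need at least 2 partitions")
  zs <- vapply(peak_sets, function(peaks) {
    mid <- floor((peaks$start + peaks$end) / 2)
    mids <- data.frame(gene_id = sprintf("p%d", seq_along(mid)),
                       chrom = peaks$chrom, start = mid, end = mid + 1)
    counts <- lengths(assign_genes(mids, partitions))
    if (stats::sd(counts) == 0) stop("peak counts constant across partitions")
    (counts - mean(counts)) / stats::sd(counts)
  }, numeric(nrow(partitions)))
  rowMeans(zs)
}
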