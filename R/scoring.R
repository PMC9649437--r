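#' Linear polygenic scoring
#'
#' Computes per-sample polygenic scores as the weighted sum of effect-allele
#' dosages, `score_i = sum_j dosage_ij * weight_j`, over all SNPs or a
#' contiguous subset (the sum form of PLINK-style `--score`; any positive
#' rescaling cancels in the transmission normalization downstream, so the
#' simpler dialect is used). Missing dosages are imputed to twice the
#' effect-allele frequency estimated from the non-missing samples of that
#' SNP; a SNP missing in every sample is excluded with a warning.
#'
#' @param d dosage matrix (samples x SNPs), columns aligned to and named as
#'   in `snps`.
#' @param snps a [snp_map()] supplying the weights.
#' @param subset integer vector of SNP map row indices to score over
#'   (default: all SNPs).
#' @return Named numeric vector of scores, one per sample.
#' @export
score_samples <- function(d, snps, subset = seq_len(nrow(snps))) {
  stopifnot_snp_map(snps)
  if (ncol(d) != nrow(snps) || !identical(colnames(d), snps$snp_id)) {
    stop("dosage columns must align with the SNP map (same ids, same order)")
  }
  if (length(subset) && (min(subset) < 1 || max(subset) > nrow(snps))) {
    stop("subset out of range of the SNP map")
  }
  ds <- d[, subset, drop = FALSE]
  w <- snps$weight[subset]
  if (anyNA(ds)) {
    nmiss <- colSums(!is.na(ds))
    dead <- nmiss == 0
    if (any(dead)) {
      warning(sum(dead), " SNP(s) with all dosages missing excluded from ",
              "scoring")
      ds <- ds[, !dead, drop = FALSE]
      w <- w[!dead]
    }
    freq <- colMeans(ds, na.rm = TRUE) / 2
    imp <- 2 * freq
    for (j in which(colSums(is.na(ds)) > 0)) {
      ds[is.na(ds[, j]), j] <- imp[j]
    }
  }
  drop(ds %*% w)
}

#' Stratified polygenic scores over partitions
#'
#' One score per (partition, sample): [score_samples()] restricted to each
#' partition's member SNPs. Because the score is a linear sum, stratified
#' scores over any disjoint cover of the SNP map add up exactly to the
#' genome-wide score.
#'
#' @inheritParams score_samples
#' @param partitions a [partition_table] with member-SNP ranges filled (see
#'   [assign_snps()]).
#' @return Numeric matrix partitions x samples, rownames `partition_id`.
#'   Partitions with no member SNPs get a zero row with a warning.
#' @export
stratified_scores <- function(d, snps, partitions) {
  res <- matrix(0, nrow = nrow(partitions), ncol = nrow(d),
                dimnames = list(partitions$partition_id, rownames(d)))
  empty <- is.na(partitions$snp_first)
  if (any(empty)) {
    warning(sum(empty), " partition(s) with no member SNPs scored as 0")
  }
  for (i in which(!empty)) {
    res[i, ] <- score_samples(d, snps,
                              partition_snp_indices(partitions[i, ], snps))
  }
  res
}

#' Harmonize SNP maps across cohorts
#'
#' Intersects several cohorts' SNP maps by id so stratified scores are built
#' from SNPs genotyped in every cohort (avoiding missingness bias across
#' partitions). Weights and effect alleles are taken from the reference
#' map; a cohort map whose effect allele is swapped relative to the
#' reference has the affected SNP ids recorded so its dosages can be
#' reoriented (`2 - dosage`) with [flip_dosages()] before scoring.
#'
#' @param maps list of two or more [snp_map()] objects; the first is the
#'   reference unless `reference` says otherwise.
#' @param reference index of the map supplying weights.
#' @return A `snp_map` restricted to the common SNPs, with attribute
#'   `"flips"`: a list (one element per input map) of SNP ids whose dosages
#'   must be flipped relative to that map's orientation.
#' @export
harmonize_snps <- function(maps, reference = 1) {
  if (length(maps) < 2) stop("need at least two SNP maps")
  lapply(maps, stopifnot_snp_map)
  ref <- maps[[reference]]
  common <- Reduce(intersect, lapply(maps, function(m) m$snp_id))
  out <- ref[ref$snp_id %in% common, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_map", "data.frame")
  flips <- lapply(maps, function(m) {
    mm <- m[match(out$snp_id, m$snp_id), ]
    if (any(mm$pos != out$pos | as.character(mm$chrom) !=
            as.character(out$chrom))) {
      stop("conflicting positions for shared SNP ids across maps")
    }
    out$snp_id[mm$effect_allele != out$effect_allele]
  })
  attr(out, "flips") <- flips
  out
}

#' Reorient dosages for flipped effect alleles
#'
#' @param d dosage matrix (samples x SNPs).
#' @param snp_ids columns to flip (`dosage <- 2 - dosage`), e.g. one element
#'   of the `"flips"` attribute of [harmonize_snps()].
#' @return The reoriented dosage matrix.
#' @export
flip_dosages <- function(d, snp_ids) {
  j <- colnames(d) %in% snp_ids
  d[, j] <- 2 - d[, j, drop = FALSE]
  d
}
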