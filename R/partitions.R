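#' Genome partitions
#'
#' Partitions are contiguous genomic blocks over which stratified polygenic
#' scores and all regional statistics are computed. They are represented as
#' a `data.frame` of class `partition_table` with columns:
#' `partition_id`, `chrom`, `start`, `end` (0-based half-open base pairs),
#' `snp_first`, `snp_last` (row range into a [snp_map()], `NA` when the
#' partition holds no scoring SNP) and `n_snps`.
#'
#' Coordinate conventions: interval columns are 0-based half-open (BED);
#' SNP positions are 1-based (VCF), so the SNP at position `p` occupies the
#' 0-based base `p - 1` and belongs to a partition when
#' `start <= p - 1 < end`.
#'
#' @name partition_table
NULL

new_partition_table <- function(partition_id, chrom, start, end,
                                snp_first = NA_integer_,
                                snp_last = NA_integer_) {
  n_snps <- ifelse(is.na(snp_first), 0L, snp_last - snp_first + 1L)
  x <- data.frame(
    partition_id = as.character(partition_id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    snp_first = as.integer(snp_first), snp_last = as.integer(snp_last),
    n_snps = as.integer(n_snps), stringsAsFactors = FALSE
  )
  if (nrow(x) && any(x$start >= x$end)) stop("partition start must be < end")
  class(x) <- c("partition_table", "data.frame")
  x
}

empty_partition_table <- function() {
  new_partition_table(character(), character(), numeric(), numeric(),
                      integer(), integer())
}

#' Partition SNPs into equal-count blocks
#'
#' Walks each chromosome from the anchored end, cutting consecutive disjoint
#' blocks of exactly `block_size` scoring SNPs. Leftover SNPs (fewer than
#' `block_size`) at the non-anchored end are left unassigned. Partition
#' bounds span the first and last member SNP (0-based half-open, i.e.
#' `[first_pos - 1, last_pos)`).
#'
#' @param snps a [snp_map()].
#' @param block_size number of SNPs per partition (>= 1).
#' @param anchor `"start"` to count from the chromosome start, `"end"` to
#'   count from the chromosome end.
#' @return A [partition_table] in genomic order.
#' @export
make_snp_count_partitions <- function(snps, block_size,
                                      anchor = c("start", "end")) {
  stopifnot_snp_map(snps)
  anchor <- match.arg(anchor)
  if (length(block_size) != 1 || is.na(block_size) || block_size < 1) {
    stop("block_size must be a positive integer")
  }
  block_size <- as.integer(block_size)
  out <- list()
  for (ch in levels(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    n <- length(idx)
    k <- n %/% block_size
    if (k == 0) next
    if (anchor == "start") {
      firsts <- idx[1L + (seq_len(k) - 1L) * block_size]
    } else {
      firsts <- idx[n - (k - seq_len(k) + 1L) * block_size + 1L]
    }
    lasts <- firsts + block_size - 1L
    out[[ch]] <- new_partition_table(
      partition_id = sprintf("%s_n%d_%s_%02d", ch, block_size, anchor,
                             seq_len(k)),
      chrom = ch,
      start = snps$pos[firsts] - 1,
      end = snps$pos[lasts],
      snp_first = firsts, snp_last = lasts
    )
  }
  if (!length(out)) return(empty_partition_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("partition_table", "data.frame")
  res
}

#' Partition the genome into fixed-length windows
#'
#' Cuts adjacent disjoint windows of exactly `length` base pairs from the
#' start of each chromosome; a trailing remainder shorter than `length` is
#' discarded. Used for length-matched control partitions (e.g. 33-Mb
#' windows).
#'
#' @param bounds a `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open chromosome extents).
#' @param length window length in base pairs (> 0).
#' @param snps optional [snp_map()]; when given, member-SNP ranges are
#'   filled in via [assign_snps()].
#' @return A [partition_table].
#' @export
make_fixed_length_partitions <- function(bounds, length, snps = NULL) {
  if (length <= 0) stop("length must be positive")
  stopifnot(all(c("chrom", "start", "end") %in% names(bounds)))
  if (any(bounds$end <= bounds$start)) stop("bounds must satisfy end > start")
  out <- list()
  for (i in seq_len(nrow(bounds))) {
    k <- floor((bounds$end[i] - bounds$start[i]) / length)
    if (k < 1) next
    starts <- bounds$start[i] + (seq_len(k) - 1) * length
    out[[i]] <- new_partition_table(
      partition_id = sprintf("%s_w%02d", bounds$chrom[i], seq_len(k)),
      chrom = bounds$chrom[i], start = starts, end = starts + length
    )
  }
  if (!length(out)) return(empty_partition_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("partition_table", "data.frame")
  if (!is.null(snps)) res <- assign_snps(res, snps)
  res
}

#' Fill member-SNP ranges of partitions
#'
#' Assigns each partition the contiguous run of SNPs whose 0-based position
#' (`pos - 1`) falls inside its half-open interval.
#'
#' @param partitions a [partition_table].
#' @param snps a [snp_map()].
#' @return The partition table with `snp_first`, `snp_last`, `n_snps`
#'   updated.
#' @export
assign_snps <- function(partitions, snps) {
  stopifnot_snp_map(snps)
  for (i in seq_len(nrow(partitions))) {
    idx <- which(snps$chrom == partitions$chrom[i] &
                   snps$pos - 1 >= partitions$start[i] &
                   snps$pos - 1 < partitions$end[i])
    if (length(idx)) {
      partitions$snp_first[i] <- min(idx)
      partitions$snp_last[i] <- max(idx)
      partitions$n_snps[i] <- length(idx)
    } else {
      partitions$snp_first[i] <- NA_integer_
      partitions$snp_last[i] <- NA_integer_
      partitions$n_snps[i] <- 0L
    }
  }
  partitions
}

partition_snp_indices <- function(partition_row, snps) {
  if (is.na(partition_row$snp_first)) return(integer())
  seq.int(partition_row$snp_first, partition_row$snp_last)
}

#' Gap-capped effective length of partitions
#'
#' The effective length of a partition is the sum over consecutive
#' member-SNP gaps of `min(gap, gap_cap)`. Capping long gaps (default 1 Mb)
#' keeps SNP deserts from inflating the length covariate used in the
#' transmission model, while the raw span is retained for reporting. The
#' leading and trailing flanks (before the first and after the last member
#' SNP) contribute nothing.
#'
#' @param partitions a [partition_table] with member-SNP ranges filled.
#' @param snps a [snp_map()].
#' @param gap_cap maximum contribution of one inter-SNP gap, base pairs.
#' @return Numeric vector of effective lengths, one per partition. A
#'   partition with a single member SNP has effective length 0; a partition
#'   with no member SNPs is an error (undefined).
#' @export
effective_length <- function(partitions, snps, gap_cap = 1e6) {
  stopifnot_snp_map(snps)
  vapply(seq_len(nrow(partitions)), function(i) {
    idx <- partition_snp_indices(partitions[i, ], snps)
    if (!length(idx)) {
      stop("effective_length undefined for partition with no member SNPs: ",
           partitions$partition_id[i])
    }
    if (length(idx) == 1) return(0)
    sum(pmin(diff(snps$pos[idx]), gap_cap))
  }, numeric(1))
}

partitions_as_granges <- function(partitions) {
  GenomicRanges::GRanges(
    seqnames = partitions$chrom,
    ranges = IRanges::IRanges(start = partitions$start + 1,
                              end = partitions$end)
  )
}

intervals_as_granges <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  GenomicRanges::GRanges(
    seqnames = as.character(intervals$chrom),
    ranges = IRanges::IRanges(start = intervals$start + 1,
                              end = intervals$end)
  )
}

#' Assign genes to partitions by body midpoint
#'
#' A gene belongs to the unique partition whose half-open interval contains
#' its body midpoint `floor((start + end) / 2)` (0-based). Genes whose
#' midpoint falls in no partition are unassigned.
#'
#' @param genes a `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param partitions a [partition_table]; must be non-overlapping unless
#'   `multi = TRUE`.
#' @param multi allow a gene midpoint to match several (overlapping)
#'   partitions.
#' @return Named list mapping `partition_id` to a character vector of gene
#'   ids; unassigned gene ids are attached as attribute `"unassigned"`.
#' @export
assign_genes <- function(genes, partitions, multi = FALSE) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  pg <- partitions_as_granges(partitions)
  if (!multi) {
    hits <- GenomicRanges::findOverlaps(pg, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits)) stop("partitions overlap; pass multi = TRUE for ",
                           "multi-assignment")
  }
  mid <- floor((genes$start + genes$end) / 2)
  gg <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = mid + 1, width = 1)
  )
  ov <- GenomicRanges::findOverlaps(gg, pg)
  res <- lapply(seq_len(nrow(partitions)), function(i) {
    genes$gene_id[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i]]
  })
  names(res) <- partitions$partition_id
  attr(res, "unassigned") <-
    genes$gene_id[!seq_len(nrow(genes)) %in% S4Vectors::queryHits(ov)]
  res
}

#' Drop partitions overlapping an interval set
#'
#' Removes every partition that overlaps any interval (e.g. centromeres, so
#' contact statistics are not computed across them); input order is
#' preserved.
#'
#' @param partitions a [partition_table].
#' @param intervals `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @param mode only `"drop_overlapping"` is defined.
#' @return The filtered [partition_table].
#' @export
filter_partitions_by_intervals <- function(partitions, intervals,
                                           mode = "drop_overlapping") {
  mode <- match.arg(mode, "drop_overlapping")
  if (!nrow(intervals)) return(partitions)
  ov <- GenomicRanges::findOverlaps(partitions_as_granges(partitions),
                                    intervals_as_granges(intervals))
  keep <- !seq_len(nrow(partitions)) %in% S4Vectors::queryHits(ov)
  res <- partitions[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
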