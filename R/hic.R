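#' Hi-C contact matrices
#'
#' A contact matrix is a symmetric bins x bins matrix of (raw or
#' normalized) contact values for one chromosome at a stated bin
#' resolution. Bin `b` (1-based) covers the half-open interval
#' `[(b - 1) * resolution, b * resolution)`. The `zero_semantics` flag
#' records whether zero entries are true zeros or masked (e.g. zeroed-out
#' hard-to-map, segmental-duplication-rich bins).
#'
#' @param mat square numeric matrix, symmetric within tolerance.
#' @param resolution bin size in base pairs (> 0).
#' @param chrom chromosome label.
#' @param zero_semantics `"true_zero"` or `"masked"`.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(mat, resolution, chrom = "chr",
                           zero_semantics = c("true_zero", "masked")) {
  zero_semantics <- match.arg(zero_semantics)
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    stop("contact matrix must be square")
  }
  if (resolution <= 0) stop("resolution must be positive")
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat)))) {
    stop("contact matrix must be symmetric")
  }
  structure(list(mat = mat, resolution = resolution, chrom = chrom,
                 zero_semantics = zero_semantics),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("Hi-C contact matrix: %s, %d bins at %g bp (%s zeros)\n",
              x$chrom, nrow(x$mat), x$resolution, x$zero_semantics))
  invisible(x)
}

#' Read / write contact matrices
#'
#' Dense form: TSV of the full square matrix, no header. Triplet (COO)
#' form: three columns `bin_i`, `bin_j`, `value` with 0-based bin indices
#' and a header; unlisted entries are zero, and symmetry is enforced by
#' mirroring.
#'
#' @param file path.
#' @param resolution bin size in base pairs.
#' @param chrom chromosome label.
#' @param n_bins for the COO form, the matrix dimension.
#' @param ... passed to [contact_matrix()].
#' @return A `contact_matrix`.
#' @export
read_contact_dense <- function(file, resolution, chrom = "chr", ...) {
  m <- as.matrix(utils::read.table(file, sep = "\t"))
  dimnames(m) <- NULL
  contact_matrix(m, resolution, chrom, ...)
}

#' @rdname read_contact_dense
#' @export
read_contact_coo <- function(file, resolution, n_bins, chrom = "chr", ...) {
  x <- utils::read.delim(file)
  stopifnot(all(c("bin_i", "bin_j", "value") %in% names(x)))
  m <- matrix(0, n_bins, n_bins)
  m[cbind(x$bin_i + 1, x$bin_j + 1)] <- x$value
  m[cbind(x$bin_j + 1, x$bin_i + 1)] <- x$value
  contact_matrix(m, resolution, chrom, ...)
}

#' @param m a `contact_matrix`.
#' @rdname read_contact_dense
#' @export
write_contact_coo <- function(m, file) {
  idx <- which(upper.tri(m$mat, diag = TRUE) & m$mat != 0, arr.ind = TRUE)
  out <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                    value = m$mat[idx])
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Snap a genomic interval to matrix bins
#'
#' Rounds the interval's start and end to the nearest bin boundary and
#' returns the covered 1-based bin indices; at least one bin is always
#' returned. Errors if the interval lies outside the matrix extent.
#'
#' @param region numeric `c(start, end)` in base pairs (0-based half-open),
#'   or one row of a [partition_table].
#' @param m a `contact_matrix`.
#' @return Integer vector of bin indices.
#' @export
snap_to_bins <- function(region, m) {
  if (is.data.frame(region)) region <- c(region$start[1], region$end[1])
  b0 <- round(region[1] / m$resolution)
  b1 <- round(region[2] / m$resolution)
  if (b1 <= b0) b1 <- b0 + 1
  if (b0 < 0 || b1 > nrow(m$mat)) stop("region outside contact matrix extent")
  seq.int(b0 + 1L, b1)
}

#' Mean within-region contact
#'
#' Mean contact over a square sub-matrix of bins. Mode `"off_diagonal"`
#' averages the off-diagonal elements only (raw count matrices, where the
#' diagonal is dominated by self-ligation); mode `"all_elements"` averages
#' every element (matrices whose diagonal has been zeroed out upstream).
#'
#' @param m a `contact_matrix`.
#' @param bins integer vector of bin indices (e.g. [snap_to_bins()]); at
#'   least 2 bins in `"off_diagonal"` mode.
#' @param mode element set to average.
#' @return Mean contact value.
#' @export
within_region_contact <- function(m, bins,
                                  mode = c("off_diagonal", "all_elements")) {
  mode <- match.arg(mode)
  sub <- m$mat[bins, bins, drop = FALSE]
  if (mode == "off_diagonal") {
    if (length(bins) < 2) stop("off_diagonal mode needs >= 2 bins")
    mean(sub[row(sub) != col(sub)])
  } else {
    mean(sub)
  }
}

#' Contact residual z-scores
#'
#' Regresses per-partition mean contact on gene count and segmental
#' duplication coverage (OLS with intercept) and standardizes the
#' residuals, yielding a per-partition z-score of contact corrected for
#' these genomic features (both inflate raw contact estimates through
#' mapping artifacts and genomic activity).
#'
#' @param contacts per-partition mean contact (e.g. from
#'   [within_region_contact()]).
#' @param gene_counts,segdup_fractions per-partition covariates.
#' @return Numeric vector of residual z-scores (mean 0, s.d. 1).
#' @export
contact_residual_z <- function(contacts, gene_counts, segdup_fractions) {
  if (length(contacts) < 4) stop("need at least 4 partitions")
  tab <- data.frame(estimate = contacts, gene_count = gene_counts,
                    segdup = segdup_fractions)
  X <- cbind(1, gene_counts, segdup_fractions)
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")
  residual_zscores(tab, covariates = c("gene_count", "segdup"))$residual_z
}

#' Edge distance range of a bin-pair rectangle
#'
#' The minimum and maximum genomic separations spanned by contacts between
#' two disjoint intervals on one chromosome: nearest-edge and farthest-edge
#' distances in base pairs. These bounds define the distance band from
#' which matched control contacts are drawn.
#'
#' @param region_a,region_b numeric `c(start, end)` intervals (0-based
#'   half-open, disjoint).
#' @return List with `min_distance` and `max_distance`.
#' @export
rectangle_distance_range <- function(region_a, region_b) {
  if (region_a[1] < region_b[2] && region_b[1] < region_a[2]) {
    stop("intervals overlap; distance range undefined")
  }
  if (region_a[1] >= region_b[2]) {
    list(min_distance = region_a[1] - region_b[2],
         max_distance = region_a[2] - region_b[1])
  } else {
    list(min_distance = region_b[1] - region_a[2],
         max_distance = region_b[2] - region_a[1])
  }
}

#' Distal contact enrichment against distance-matched controls
#'
#' Tests whether contacts between two distal regions (the target
#' rectangle, e.g. a CNV locus x a telomeric gene cluster) are more
#' frequent than same-chromosome contacts at matched genomic separation.
#' The control set is every bin pair whose separation (between bin starts)
#' lies inside the rectangle's `[min, max]` edge-distance band (inclusive)
#' but is not itself in the rectangle. Zero entries, which typically mark
#' masked hard-to-map bins, are dropped from both sets under the default
#' policy; `zero_policy = "include"` keeps them as a robustness re-run.
#'
#' @param m a `contact_matrix`.
#' @param region_a,region_b numeric `c(start, end)` target intervals in
#'   base pairs.
#' @param zero_policy `"exclude"` (default) or `"include"`.
#' @return List: `fold` (mean target / mean control), `target_n`,
#'   `control_n` (pair counts after zero filtering), `two_sample_p`
#'   (two-sided Welch t-test), `min_distance`, `max_distance`.
#' @export
distal_enrichment <- function(m, region_a, region_b,
                              zero_policy = c("exclude", "include")) {
  zero_policy <- match.arg(zero_policy)
  bins_a <- snap_to_bins(region_a, m)
  bins_b <- snap_to_bins(region_b, m)
  dr <- rectangle_distance_range(region_a, region_b)
  res <- m$resolution
  n <- nrow(m$mat)
  pairs_t <- expand.grid(i = bins_a, j = bins_b)
  target <- m$mat[cbind(pairs_t$i, pairs_t$j)]
  in_rect <- matrix(FALSE, n, n)
  in_rect[cbind(pairs_t$i, pairs_t$j)] <- TRUE
  in_rect[cbind(pairs_t$j, pairs_t$i)] <- TRUE
  k_lo <- ceiling(dr$min_distance / res)
  k_hi <- floor(dr$max_distance / res)
  if (k_hi < k_lo) stop("empty control distance band")
  control <- numeric(0)
  for (k in seq.int(k_lo, k_hi)) {
    if (k >= n) break
    i <- seq_len(n - k)
    j <- i + k
    keep <- !in_rect[cbind(i, j)]
    control <- c(control, m$mat[cbind(i[keep], j[keep])])
  }
  if (!length(control)) stop("empty control set")
  if (zero_policy == "exclude") {
    target <- target[target != 0]
    control <- control[control != 0]
    if (!length(target) || !length(control)) {
      stop("no nonzero contacts left under zero_policy = 'exclude'")
    }
  }
  if (mean(control) == 0) stop("control mean is zero; fold undefined")
  tt <- stats::t.test(target, control, var.equal = FALSE)
  list(fold = mean(target) / mean(control),
       target_n = length(target), control_n = length(control),
       two_sample_p = tt$p.value,
       min_distance = dr$min_distance, max_distance = dr$max_distance)
}
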