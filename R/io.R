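#' Read / write BED interval sets
#'
#' Minimal 3+-column BED: `chrom`, `start`, `end`, 0-based half-open, no
#' header. Extra columns are kept with their names on write and read back
#' positionally as `name`, `score`, ... on read.
#'
#' @param file path.
#' @return `data.frame` with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(file) {
  x <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  x$chrom <- as.character(x$chrom)
  if (ncol(x) >= 4) names(x)[4] <- "name"
  if (ncol(x) >= 5) names(x)[5] <- "score"
  x
}

#' @param x interval `data.frame` (`chrom`, `start`, `end`, ...).
#' @rdname read_bed
#' @export
write_bed <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Read / write partition tables
#'
#' Partitions travel as BED plus named extra columns (`partition_id`,
#' `n_snps`, and any annotation such as `effective_length`), with a header.
#'
#' @param file path to a TSV file.
#' @return A [partition_table].
#' @export
read_partitions <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "partition_id")
  if (!all(need %in% names(x))) {
    stop("partition file must have columns: ", paste(need, collapse = ", "))
  }
  if (!"snp_first" %in% names(x)) x$snp_first <- NA_integer_
  if (!"snp_last" %in% names(x)) x$snp_last <- NA_integer_
  if (!"n_snps" %in% names(x)) {
    x$n_snps <- ifelse(is.na(x$snp_first), 0L, x$snp_last - x$snp_first + 1L)
  }
  class(x) <- c("partition_table", "data.frame")
  x
}

#' @param x a [partition_table].
#' @rdname read_partitions
#' @export
write_partitions <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a dosage matrix
#'
#' Effect-allele dosages in `[0, 2]`, one row per sample, one column per
#' SNP; first column `sample_id`, remaining column names are SNP ids.
#' Missing genotypes are `NA`.
#'
#' @param file path to a TSV file.
#' @return Numeric matrix samples x SNPs with dimnames.
#' @export
read_dosage_tsv <- function(file) {
  x <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  validate_dosages(m)
}

#' @param d dosage matrix (samples x SNPs, dimnames required).
#' @rdname read_dosage_tsv
#' @export
write_dosage_tsv <- function(d, file) {
  out <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}

validate_dosages <- function(d) {
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    stop("dosage matrix needs sample ids as rownames and SNP ids as colnames")
  }
  rng <- range(d, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  d
}

#' Read effect-allele dosages from a VCF
#'
#' Extracts per-sample dosages for the SNPs of a [snp_map()] from a VCF.
#' With `field = "GT"` the dosage is the count of the map's effect allele
#' among the two called alleles (assumed REF/ALT biallelic; the effect
#' allele must match REF or ALT, otherwise the SNP is dropped with a
#' warning). With `field = "DS"` the genotype dosage of the ALT allele is
#' used, flipped to `2 - DS` when the effect allele is REF.
#'
#' @param file path to an (uncompressed or bgzipped) VCF.
#' @param snps a [snp_map()]; matching is by SNP id.
#' @param field `"GT"` (default) or `"DS"`.
#' @return Dosage matrix samples x SNPs, columns in `snps` order (dropped
#'   SNPs omitted), `NA` for missing genotypes.
#' @export
read_dosage_vcf <- function(file, snps, field = c("GT", "DS")) {
  stopifnot_snp_map(snps)
  field <- match.arg(field)
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- match(snps$snp_id, fix$ID)
  found <- !is.na(keep)
  if (!any(found)) stop("no SNP map ids found in VCF")
  if (field == "GT") {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[keep[found], , drop = FALSE]
    ref <- fix$REF[keep[found]]
    alt <- fix$ALT[keep[found]]
    eff <- snps$effect_allele[found]
    use <- eff == ref | eff == alt
    if (!all(use)) {
      warning(sum(!use), " SNP(s) dropped: effect allele matches neither ",
              "REF nor ALT")
      gt <- gt[use, , drop = FALSE]
      ref <- ref[use]; alt <- alt[use]; eff <- eff[use]
    }
    alt_count <- function(g) {
      out <- vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"),
                    numeric(1))
      out[is.na(g) | grepl("\\.", g)] <- NA_real_
      out
    }
    m <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
    for (j in seq_len(nrow(gt))) m[, j] <- alt_count(gt[j, ])
    flip <- eff == ref
    m[, flip] <- 2 - m[, flip]
  } else {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    ds <- ds[keep[found], , drop = FALSE]
    ref <- fix$REF[keep[found]]
    eff <- snps$effect_allele[found]
    m <- t(ds)
    flip <- eff == ref
    m[, flip] <- 2 - m[, flip]
  }
  validate_dosages(m)
}

#' Read / write a pedigree table
#'
#' TSV with header columns `family_id`, `child_id`, `father_id`,
#' `mother_id` and optional `role` (`"proband"` or `"sibling"`, default
#' proband).
#'
#' @param file path.
#' @return `data.frame` with the columns above.
#' @export
read_pedigree <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("family_id", "child_id", "father_id", "mother_id")
  if (!all(need %in% names(x))) {
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  }
  if (!"role" %in% names(x)) x$role <- "proband"
  x
}

#' @param x pedigree `data.frame`.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a gene table
#'
#' TSV with header; requires `gene_id`, `chrom`, `start`, `end` (0-based
#' half-open) and keeps optional statistics (`specificity_t`) and flag
#' columns.
#'
#' @param file path.
#' @return `data.frame`.
#' @export
read_gene_table <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  x
}
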