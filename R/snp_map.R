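#' Construct a SNP map
#'
#' A SNP map is the backbone of every polygenic score: an ordered table of
#' scoring SNPs with their genomic location, effect allele and per-dose
#' weight. Rows are sorted by chromosome (in the order given by
#' `chrom_levels`) and by position within chromosome; positions are 1-based
#' (VCF convention).
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome label per SNP.
#' @param pos 1-based base-pair position per SNP.
#' @param effect_allele effect (scored) allele per SNP.
#' @param weight score weight per effect-allele dose; must be finite.
#' @param chrom_levels chromosome ordering; defaults to order of first
#'   appearance in `chrom`.
#' @return A `data.frame` of class `snp_map` with columns `snp_id`, `chrom`
#'   (factor), `pos`, `effect_allele`, `weight`, sorted genomically.
#' @export
snp_map <- function(snp_id, chrom, pos, effect_allele, weight,
                    chrom_levels = unique(as.character(chrom))) {
  if (anyDuplicated(snp_id)) stop("snp_id values must be unique")
  if (!all(is.finite(weight))) stop("weights must be finite")
  if (!all(pos >= 1)) stop("positions are 1-based and must be >= 1")
  chrom <- factor(as.character(chrom), levels = chrom_levels)
  if (anyNA(chrom)) stop("chromosome label not in chrom_levels")
  x <- data.frame(
    snp_id = as.character(snp_id), chrom = chrom, pos = as.numeric(pos),
    effect_allele = as.character(effect_allele), weight = as.numeric(weight),
    stringsAsFactors = FALSE
  )
  x <- x[order(as.integer(x$chrom), x$pos), , drop = FALSE]
  rownames(x) <- NULL
  for (ch in levels(chrom)) {
    p <- x$pos[x$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  class(x) <- c("snp_map", "data.frame")
  x
}

#' @export
print.snp_map <- function(x, ...) {
  cat("SNP map:", nrow(x), "SNPs on", nlevels(x$chrom), "chromosome(s)\n")
  NextMethod()
}

is_snp_map <- function(x) inherits(x, "snp_map")

stopifnot_snp_map <- function(x) {
  if (!is_snp_map(x)) stop("expected a 'snp_map' (see snp_map())")
  invisible(x)
}

#' Read / write a SNP map as TSV
#'
#' Tab-separated with header columns `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `weight` (PLINK `--score` style plus location).
#'
#' @param file path to a TSV file.
#' @param ... passed to [snp_map()] (e.g. `chrom_levels`).
#' @return [read_snp_map()] returns a `snp_map`; [write_snp_map()] its input,
#'   invisibly.
#' @export
read_snp_map <- function(file, ...) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "effect_allele", "weight")
  if (!all(need %in% names(x))) {
    stop("SNP map file must have columns: ", paste(need, collapse = ", "))
  }
  snp_map(x$snp_id, x$chrom, x$pos, x$effect_allele, x$weight, ...)
}

#' @param x a `snp_map`.
#' @rdname read_snp_map
#' @export
write_snp_map <- function(x, file) {
  stopifnot_snp_map(x)
  out <- as.data.frame(x)
  out$chrom <- as.character(out$chrom)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
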