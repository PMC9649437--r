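# Small in-code fixtures and independent oracles shared across tests.

# A random SNP map: n SNPs per chromosome, positions uniform then sorted.
random_snp_map <- function(n_per_chrom, chroms = c("1", "2", "3"),
                           span = 5e7, seed = 1) {
  set.seed(seed)
  rows <- lapply(chroms, function(ch) {
    pos <- sort(sample.int(span, n_per_chrom))
    data.frame(snp_id = sprintf("rs_%s_%d", ch, seq_len(n_per_chrom)),
               chrom = ch, pos = pos, effect_allele = "A",
               weight = rnorm(n_per_chrom), stringsAsFactors = FALSE)
  })
  x <- do.call(rbind, rows)
  snp_map(x$snp_id, x$chrom, x$pos, x$effect_allele, x$weight,
          chrom_levels = chroms)
}

# Random dosage matrix aligned to a SNP map.
random_dosages <- function(n_samples, snps, miss_rate = 0, seed = 1) {
  set.seed(seed)
  m <- nrow(snps)
  d <- matrix(sample(0:2, n_samples * m, replace = TRUE), n_samples, m,
              dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                              snps$snp_id))
  storage.mode(d) <- "double"
  if (miss_rate > 0) d[runif(length(d)) < miss_rate] <- NA
  d
}

# Independent normal-equations OLS: coefficients, residuals, focal t.
ols_oracle <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% b
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(sigma2 * diag(solve(t(X) %*% X)))
  list(beta = drop(b), resid = drop(res), se = se, t = drop(b) / se)
}

# One-line recomputation of pTDT deviations, independent of the package.
deviations_oracle <- function(child, mother, father) {
  mp <- (mother + father) / 2
  (child - mp) / sd(mp)
}

# Direct simulation of unascertained trio scores (no genotypes needed for
# null calibration of the test itself).
toy_trio_table <- function(n, seed) {
  set.seed(seed)
  mo <- rnorm(n); fa <- rnorm(n)
  ch <- (mo + fa) / 2 + rnorm(n, sd = sqrt(0.5))
  data.frame(family_id = sprintf("f%d", seq_len(n)), child_score = ch,
             mother_score = mo, father_score = fa)
}
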