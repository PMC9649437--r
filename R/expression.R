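#' Filter to well-expressed genes
#'
#' Keeps genes whose mean expression across donors strictly exceeds the
#' across-gene median of those means. With distinct means and an even gene
#' count this keeps exactly half of the genes (the "above-median" rule used
#' to restrict regional association to well-expressed genes); under ties
#' the strict inequality can keep fewer, and an all-equal matrix keeps
#' none, with a warning.
#'
#' @param expr expression matrix, genes x donors (rownames = gene ids).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(expr) {
  if (nrow(expr) < 2) stop("need at least 2 genes")
  m <- rowMeans(expr)
  keep <- m > stats::median(m)
  if (!any(keep)) warning("no gene exceeds the median; empty set returned")
  rownames(expr)[keep]
}

#' Standardize values within cohorts
#'
#' Centers and scales to unit sample s.d. within each cohort, feature by
#' feature: per-gene expression and per-partition polygenic scores are
#' standardized this way before cohorts are concatenated for a combined
#' association, so that cohort-specific location and scale (assay depth,
#' score offset) cannot masquerade as signal.
#'
#' @param x numeric vector (one value per donor) or matrix (features x
#'   donors).
#' @param cohort cohort label per donor.
#' @return Object of the same shape, standardized within cohort. A feature
#'   constant within some cohort is an error.
#' @export
scale_within_cohort <- function(x, cohort) {
  scale_vec <- function(v) {
    out <- v
    for (ch in unique(cohort)) {
      i <- cohort == ch
      if (sum(i) < 2) stop("need at least 2 donors per cohort")
      s <- stats::sd(v[i])
      if (!is.finite(s) || s == 0) {
        stop("zero variance within cohort ", ch)
      }
      out[i] <- (v[i] - mean(v[i])) / s
    }
    out
  }
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(cohort))
    out <- t(apply(x, 1, scale_vec))
    dimnames(out) <- dimnames(x)
    out
  } else {
    stopifnot(length(x) == length(cohort))
    scale_vec(x)
  }
}

build_design <- function(pgs, covariates) {
  X <- cbind(`(Intercept)` = 1, pgs = pgs)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    X <- cbind(X, as.matrix(as.data.frame(covariates)))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

# Multi-response OLS: per-gene coefficient and t for one focal column.
ols_focal_t <- function(X, Y, focal = "pgs") {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, t(Y))          # p x genes
  res <- t(Y) - X %*% B                       # n x genes
  sigma2 <- colSums(res^2) / (n - p)
  j <- match(focal, colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  list(beta = B[j, ], se = se, t = B[j, ] / se, df = n - p)
}

#' Per-gene association of expression with a regional polygenic score
#'
#' Fits, for every gene, the linear model
#' `expression ~ regional PGS + covariates` (OLS) and returns the PGS
#' coefficient and its t-statistic. Expression and PGS are expected to be
#' standardized within cohort first ([scale_within_cohort()]) when cohorts
#' are combined; the covariates are then the binary indicators actually in
#' the model (diagnosis, ancestry group, single-cell vs bulk assay).
#'
#' @param expr expression matrix, genes x donors.
#' @param pgs numeric vector, one regional PGS per donor (constant PGS is a
#'   rank-deficiency error).
#' @param covariates optional `data.frame` of numeric covariate columns
#'   (one row per donor).
#' @return `data.frame`: `gene_id`, `beta`, `se`, `t_statistic`, `p_value`.
#' @export
per_gene_assoc <- function(expr, pgs, covariates = NULL) {
  stopifnot(ncol(expr) == length(pgs))
  X <- build_design(pgs, covariates)
  f <- ols_focal_t(X, expr)
  data.frame(gene_id = rownames(expr), beta = unname(f$beta),
             se = unname(f$se), t_statistic = unname(f$t),
             p_value = 2 * stats::pt(-abs(unname(f$t)), df = f$df),
             stringsAsFactors = FALSE)
}

#' Mean regional expression association
#'
#' Averages the (standardized) expression of a regional gene set per donor
#' and fits the same covariate model as [per_gene_assoc()] on the average.
#' This is the higher-power "average gene" regional association.
#'
#' @inheritParams per_gene_assoc
#' @param gene_set character vector of gene ids (non-empty subset of
#'   `rownames(expr)`).
#' @return List: `beta`, `se`, `t_statistic`, `p_value`, `n_genes`.
#' @export
mean_region_assoc <- function(expr, pgs, gene_set, covariates = NULL) {
  gene_set <- intersect(gene_set, rownames(expr))
  if (!length(gene_set)) stop("empty gene set")
  y <- colMeans(expr[gene_set, , drop = FALSE])
  X <- build_design(pgs, covariates)
  f <- ols_focal_t(X, matrix(y, nrow = 1))
  list(beta = unname(f$beta), se = unname(f$se),
       t_statistic = unname(f$t),
       p_value = 2 * stats::pt(-abs(unname(f$t)), df = f$df),
       n_genes = length(gene_set))
}

#' Permutation test for the mean regional association t-statistic
#'
#' The observed statistic is the mean of the per-gene PGS t-statistics over
#' a regional gene set. The null is built by shuffling the PGS-to-donor
#' assignment independently within each cohort (expression and covariates
#' stay fixed), which preserves the within-cohort PGS distribution exactly
#' while breaking the genotype link. The one-sided empirical p-value for a
#' depletion signal uses the add-one convention:
#' `p = (1 + #\{null <= observed\}) / (1 + n_perm)`.
#'
#' @inheritParams per_gene_assoc
#' @param gene_set regional gene ids.
#' @param cohort cohort label per donor (single label = global shuffle).
#' @param n_perm number of permutations (>= 1; default 1000).
#' @param seed integer seed for the permutation stream.
#' @return List: `observed_mean_t`, `empirical_p`, `null_mean_t` (vector of
#'   length `n_perm`), `n_perm`.
#' @export
permutation_mean_t <- function(expr, pgs, gene_set, covariates = NULL,
                               cohort = rep("all", length(pgs)),
                               n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  gene_set <- intersect(gene_set, rownames(expr))
  if (!length(gene_set)) stop("empty gene set")
  sub <- expr[gene_set, , drop = FALSE]
  mean_t <- function(p) {
    f <- ols_focal_t(build_design(p, covariates), sub)
    mean(f$t)
  }
  observed <- mean_t(pgs)
  groups <- split(seq_along(pgs), cohort)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    perm <- pgs
    for (g in groups) perm[g] <- pgs[sample(g)]
    mean_t(perm)
  }, numeric(1))
  list(observed_mean_t = observed,
       empirical_p = (1 + sum(null <= observed)) / (1 + n_perm),
       null_mean_t = null, n_perm = n_perm)
}

#' Cross-cohort consistency statistic
#'
#' The most positive of the per-cohort regional association coefficients.
#' A region whose association is consistently negative across cohorts has a
#' negative consistency statistic; one cohort with a positive coefficient
#' is enough to push it above zero.
#'
#' @param betas numeric vector of per-cohort coefficients (>= 1).
#' @return The maximum coefficient.
#' @export
consistency_stat <- function(betas) {
  if (!length(betas)) stop("need at least one cohort")
  max(betas)
}

#' Regional differential-expression contrast around a CNV
#'
#' Compares per-gene differential-expression statistics of a regional gene
#' set against all other genes, after dropping every gene whose body
#' overlaps the CNV window widened by an exclusion flank (default 100 kb;
#' the cis-regulatory neighborhood of those genes may be perturbed by the
#' deletion itself). Reports the region's mean t with a one-sample
#' two-sided t-test against 0, the mean log2 fold-change with its
#' one-sample test, and a two-sided two-sample t-test of region versus
#' background t-statistics.
#'
#' @param de `data.frame` with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open gene bodies), `log2fc`, `t_statistic`.
#' @param region_genes gene ids forming the regional set.
#' @param cnv_window `NULL`, or `list(chrom =, start =, end =)` for the
#'   deletion locus.
#' @param exclusion flank in base pairs added to each side of the window.
#' @return List: `mean_t_region`, `one_sample_p`, `mean_log2fc_region`,
#'   `one_sample_p_lfc`, `mean_t_background`, `two_sample_p`, `n_region`,
#'   `n_background`.
#' @export
region_de_contrast <- function(de, region_genes, cnv_window = NULL,
                               exclusion = 1e5) {
  keep <- rep(TRUE, nrow(de))
  if (!is.null(cnv_window)) {
    lo <- cnv_window$start - exclusion
    hi <- cnv_window$end + exclusion
    keep <- !(de$chrom == cnv_window$chrom & de$start < hi & de$end > lo)
  }
  de <- de[keep, , drop = FALSE]
  in_region <- de$gene_id %in% region_genes
  if (!any(in_region)) stop("empty region set after exclusion")
  if (!any(!in_region)) stop("empty background set")
  t_r <- de$t_statistic[in_region]
  t_b <- de$t_statistic[!in_region]
  one <- stats::t.test(t_r, mu = 0)
  one_lfc <- stats::t.test(de$log2fc[in_region], mu = 0)
  two <- stats::t.test(t_r, t_b, var.equal = FALSE)
  list(mean_t_region = mean(t_r), one_sample_p = one$p.value,
       mean_log2fc_region = mean(de$log2fc[in_region]),
       one_sample_p_lfc = one_lfc$p.value,
       mean_t_background = mean(t_b), two_sample_p = two$p.value,
       n_region = sum(in_region), n_background = sum(!in_region))
}

#' Correlation of per-gene effects across two analyses
#'
#' Pearson correlation of per-gene statistics (e.g. the expression effect
#' of a regional polygenic score and of a CNV deletion) over the
#' intersection of gene sets.
#'
#' @param t_a,t_b named numeric vectors of per-gene statistics (names are
#'   gene ids).
#' @return List: `r`, `p_value`, `n_genes`.
#' @export
cross_effect_correlation <- function(t_a, t_b) {
  shared <- intersect(names(t_a), names(t_b))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  res <- density_correlation(unname(t_a[shared]), unname(t_b[shared]))
  c(res, list(n_genes = length(shared)))
}
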