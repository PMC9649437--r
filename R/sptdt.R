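#' Assemble trio score sets
#'
#' Joins a per-sample score vector with a pedigree into one row per family:
#' child, mother and father scores.
#'
#' @param scores named numeric vector of per-sample scores (e.g. from
#'   [score_samples()] or one row of [stratified_scores()]).
#' @param pedigree `data.frame` with `family_id`, `child_id`, `father_id`,
#'   `mother_id` (see [read_pedigree()]).
#' @return `data.frame` with `family_id`, `child_score`, `mother_score`,
#'   `father_score`.
#' @export
trio_scores <- function(scores, pedigree) {
  ids <- c(pedigree$child_id, pedigree$mother_id, pedigree$father_id)
  missing <- setdiff(ids, names(scores))
  if (length(missing)) {
    stop("samples in pedigree but not scored: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  data.frame(
    family_id = pedigree$family_id,
    child_score = unname(scores[pedigree$child_id]),
    mother_score = unname(scores[pedigree$mother_id]),
    father_score = unname(scores[pedigree$father_id]),
    stringsAsFactors = FALSE
  )
}

#' Per-family polygenic transmission deviations
#'
#' The pTDT deviation of family *i* is
#' `(child_i - midparent_i) / sd(midparent)`, where the midparent score is
#' the average of the two parents and the normalizer is the sample standard
#' deviation (n - 1 denominator) of midparent scores over the analyzed
#' families. Under Mendelian transmission with no ascertainment the
#' deviations have mean zero; ascertained probands over-inherit score,
#' shifting the mean up. The normalization makes deviations invariant to
#' any affine rescaling of the score (adding a constant, or multiplying all
#' weights by c > 0).
#'
#' @param trios `data.frame` from [trio_scores()].
#' @return Numeric vector of deviations, one per family, in s.d.-of-midparent
#'   units.
#' @export
ptdt_deviations <- function(trios) {
  if (nrow(trios) < 2) stop("need at least 2 families")
  mp <- (trios$mother_score + trios$father_score) / 2
  s <- stats::sd(mp)
  if (!is.finite(s) || s == 0) {
    stop("midparent scores have zero variance; deviation undefined")
  }
  (trios$child_score - mp) / s
}

#' One-sample transmission test
#'
#' Tests whether the mean pTDT deviation differs from 0 with a one-sample,
#' two-sided Student's t-test. The mean deviation is the cohort's
#' (S-)pTDT estimate, in s.d.-of-midparent units.
#'
#' @param deviations numeric vector from [ptdt_deviations()].
#' @return `ptdt_result` list: `mean_deviation`, `se`, `t_statistic`,
#'   `p_value`, `n_families`, `ci95` (length-2 vector).
#' @export
ptdt_test <- function(deviations) {
  if (length(deviations) < 2) stop("need at least 2 deviations")
  if (stats::sd(deviations) == 0) {
    stop("deviations are constant; t-test undefined")
  }
  tt <- stats::t.test(deviations, mu = 0, alternative = "two.sided")
  structure(list(
    mean_deviation = unname(tt$estimate),
    se = unname(tt$stderr),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    n_families = length(deviations),
    ci95 = unname(tt$conf.int)
  ), class = "ptdt_result")
}

#' @export
print.ptdt_result <- function(x, ...) {
  cat(sprintf(
    "pTDT: mean deviation %.4f (se %.4f), t = %.3f, p = %.3g, n = %d\n",
    x$mean_deviation, x$se, x$t_statistic, x$p_value, x$n_families))
  invisible(x)
}

#' Stratified pTDT scan over partitions
#'
#' Runs the transmission test partition by partition on stratified scores;
#' the midparent normalizer is recomputed within each partition. Partitions
#' whose stratified scores violate the test preconditions (for instance an
#' empty partition, whose midparent scores are constant at zero) are kept
#' as flagged rows with `NA` statistics and are excluded from downstream
#' residual models.
#'
#' @param strat stratified score matrix (partitions x samples) from
#'   [stratified_scores()].
#' @param pedigree pedigree `data.frame` (see [trio_scores()]).
#' @param partitions the [partition_table] matching `strat` rows; `n_snps`
#'   and, if present, `effective_length` are carried into the result.
#' @return `data.frame` (class `region_stat_table`): `partition_id`,
#'   `estimate`, `se`, `t_statistic`, `p_value`, `n_families`, `n_snps`,
#'   `effective_length` (if available), `ok`.
#' @export
sptdt_scan <- function(strat, pedigree, partitions) {
  stopifnot(identical(rownames(strat), partitions$partition_id))
  rows <- lapply(seq_len(nrow(partitions)), function(i) {
    res <- tryCatch(
      ptdt_test(ptdt_deviations(trio_scores(strat[i, ], pedigree))),
      error = function(e) NULL
    )
    if (is.null(res)) {
      data.frame(partition_id = partitions$partition_id[i],
                 estimate = NA_real_, se = NA_real_, t_statistic = NA_real_,
                 p_value = NA_real_, n_families = nrow(pedigree), ok = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(partition_id = partitions$partition_id[i],
                 estimate = res$mean_deviation, se = res$se,
                 t_statistic = res$t_statistic, p_value = res$p_value,
                 n_families = res$n_families, ok = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$n_snps <- partitions$n_snps
  if ("effective_length" %in% names(partitions)) {
    out$effective_length <- partitions$effective_length
  }
  class(out) <- c("region_stat_table", "data.frame")
  out
}

#' Residual z-scores for regional statistics
#'
#' Regresses a per-partition estimate on composition covariates (ordinary
#' least squares with intercept) and standardizes the residuals by their
#' sample standard deviation. The residual z-score of a partition estimates
#' how many s.d. more (or less) signal it carries than expected from its
#' composition. For SNP-count partitions the covariates are SNP count and
#' gap-capped effective length; for fixed-length windows, SNP count alone
#' (length is constant). Exactly collinear covariates are dropped with a
#' warning.
#'
#' @param table a `region_stat_table` from [sptdt_scan()], or any
#'   `data.frame` with an estimate column and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param estimate name of the column to residualize.
#' @return `table` with a `residual_z` column (`NA` for flagged rows). The
#'   fitted rows satisfy mean(z) = 0, sd(z) = 1.
#' @export
residual_zscores <- function(table,
                             covariates = c("n_snps", "effective_length"),
                             estimate = "estimate") {
  ok <- if ("ok" %in% names(table)) table$ok else rep(TRUE, nrow(table))
  ok <- ok & !is.na(table[[estimate]])
  if (sum(ok) < length(covariates) + 2) {
    stop("need at least ", length(covariates) + 2, " usable partitions")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[ok, covariates, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("dropping collinear covariate(s): ",
            paste(drop_cols, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  res <- qr.resid(qrX, table[[estimate]][ok])
  s <- stats::sd(res)
  # an exact fit has no residual spread; every partition sits on the line
  z <- if (s < max(abs(table[[estimate]][ok]), 1) * 1e-12) res * 0 else res / s
  table$residual_z <- NA_real_
  table$residual_z[ok] <- z
  table
}

#' Quadrant enrichment of annotated partitions
#'
#' Tests whether flagged partitions (e.g. those containing a GWAS locus)
#' are over-represented in the positive-positive quadrant of two cohorts'
#' residual z-scores. Expectation is the number of flagged partitions times
#' the overall fraction of partitions in that quadrant; the p-value is a
#' one-sided (greater) exact binomial test at that fraction.
#'
#' @param z_a,z_b per-partition residual z-scores from two cohorts, same
#'   partition order.
#' @param flags logical vector marking the annotated partitions.
#' @return List: `observed`, `expected`, `baseline` (quadrant fraction),
#'   `n_flagged`, `p_value`.
#' @export
quadrant_enrichment <- function(z_a, z_b, flags) {
  stopifnot(length(z_a) == length(z_b), length(flags) == length(z_a))
  if (!any(flags)) stop("no flagged partitions; enrichment undefined")
  quad <- z_a > 0 & z_b > 0
  baseline <- mean(quad)
  observed <- sum(quad & flags)
  n_flagged <- sum(flags)
  bt <- stats::binom.test(observed, n_flagged, p = baseline,
                          alternative = "greater")
  list(observed = observed, expected = n_flagged * baseline,
       baseline = baseline, n_flagged = n_flagged, p_value = bt$p.value)
}

#' Signal decay under successive block removal
#'
#' Quantifies how diffuse a regional transmission signal is: blocks (e.g.
#' LD-independent sub-blocks of a region) are ranked once from most to
#' least over-transmitted by their per-block estimate (ties broken by
#' genomic order), then the transmission test is repeated on the SNP union
#' of the remaining blocks as the top-ranked remaining block is removed one
#' at a time. A signal driven by a single locus collapses after one
#' removal; a diffuse signal decays gradually.
#'
#' @param strat stratified score matrix (blocks x samples) for the region's
#'   blocks, rows in genomic order.
#' @param pedigree pedigree `data.frame`.
#' @return `data.frame` with one row per step: `n_removed`,
#'   `removed_block` (`NA` at step 0), `n_blocks_left`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `p_value`. Step 0 is the union of all blocks; the
#'   curve has as many rows as blocks.
#' @export
block_removal_decay <- function(strat, pedigree) {
  k <- nrow(strat)
  if (k < 1) stop("need at least one block")
  per_block <- vapply(seq_len(k), function(i) {
    ptdt_test(ptdt_deviations(trio_scores(strat[i, ], pedigree)))$mean_deviation
  }, numeric(1))
  order_removed <- order(-per_block, seq_len(k))
  steps <- lapply(seq_len(k), function(s) {
    remaining <- setdiff(seq_len(k), order_removed[seq_len(s - 1)])
    union_score <- colSums(strat[remaining, , drop = FALSE])
    res <- ptdt_test(ptdt_deviations(trio_scores(union_score, pedigree)))
    data.frame(
      n_removed = s - 1L,
      removed_block = if (s == 1) NA_character_ else
        rownames(strat)[order_removed[s - 1]],
      n_blocks_left = length(remaining),
      estimate = res$mean_deviation, se = res$se,
      ci_lo = res$ci95[1], ci_hi = res$ci95[2], p_value = res$p_value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, steps)
}

#' Drop carrier families from a pedigree
#'
#' Removes families whose proband appears in a carrier list (e.g. carriers
#' of a qualifying CNV), so transmission statistics can be re-run on the
#' filtered cohort. Unknown carrier ids trigger a warning.
#'
#' @param pedigree pedigree `data.frame`.
#' @param carriers character vector of child ids to drop.
#' @return The filtered pedigree.
#' @export
exclude_carrier_families <- function(pedigree, carriers) {
  unknown <- setdiff(carriers, pedigree$child_id)
  if (length(unknown)) {
    warning(length(unknown), " carrier id(s) not found in pedigree")
  }
  pedigree[!pedigree$child_id %in% carriers, , drop = FALSE]
}
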