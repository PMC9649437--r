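test_that("pTDT deviations follow the midparent-normalized formula", {
  trios <- data.frame(family_id = c("f1", "f2"),
                      child_score = c(1, 0),
                      mother_score = c(0.5, -0.5),
                      father_score = c(0.5, -0.5))
  dev <- ptdt_deviations(trios)
  expect_equal(dev, c(1 / sqrt(2), 1 / sqrt(2)), tolerance = 1e-6)
  # children at their midparent expectation deviate by zero
  t0 <- toy_trio_table(50, seed = 1)
  t0$child_score <- (t0$mother_score + t0$father_score) / 2
  expect_true(all(ptdt_deviations(t0) == 0))
  # independent one-line recomputation on 1,000 unascertained trios
  tt <- toy_trio_table(1000, seed = 2)
  dev2 <- ptdt_deviations(tt)
  expect_equal(dev2, deviations_oracle(tt$child_score, tt$mother_score,
                                       tt$father_score))
  res <- ptdt_test(dev2)
  expect_lt(abs(res$mean_deviation), 3 * res$se)
  # zero midparent variance is undefined
  tt$mother_score <- 1; tt$father_score <- 2
  expect_error(ptdt_deviations(tt), "zero variance")
})

test_that("transmission test is a one-sample two-sided t-test", {
  res <- ptdt_test(c(1, -1))
  expect_equal(res$mean_deviation, 0)
  expect_equal(res$p_value, 1)
  # a cohort-scale mean of 0.2 is recovered from jittered deviations
  set.seed(3)
  dev <- 0.2 + rnorm(4335, sd = 1e-3)
  big <- ptdt_test(dev)
  expect_equal(big$mean_deviation, 0.2, tolerance = 1e-3)
  expect_lt(big$p_value, 1e-100)
  expect_equal(big$n_families, 4335)
  expect_error(ptdt_test(rep(0.5, 10)), "constant")
  expect_error(ptdt_test(0.5), "at least 2")
})

test_that("the stratified scan equals a per-partition loop and flags bad rows", {
  cfg <- sim_config(seed = 17, genome = list(n_snps = rep(80L, 6)),
                    trio = list(n_families = 60L,
                                ascertainment_quantile = NULL))
  snps <- simulate_snp_map(cfg)
  tr <- simulate_trios(cfg, snps)
  parts <- make_snp_count_partitions(snps, 25)
  st <- stratified_scores(tr$dosages, snps, parts)
  scan <- sptdt_scan(st, tr$pedigree, parts)
  for (i in seq_len(nrow(parts))) {
    ref <- ptdt_test(ptdt_deviations(trio_scores(st[i, ], tr$pedigree)))
    expect_equal(scan$estimate[i], ref$mean_deviation)
    expect_equal(scan$p_value[i], ref$p_value)
  }
  # an all-zero-weight partition has zero midparent variance -> flagged
  st0 <- rbind(st, 0)
  p0 <- rbind(parts, parts[1, ])
  p0$partition_id[nrow(p0)] <- "dead"
  rownames(st0) <- p0$partition_id
  scan0 <- sptdt_scan(st0, tr$pedigree, p0)
  expect_false(scan0$ok[nrow(p0)])
  expect_true(is.na(scan0$estimate[nrow(p0)]))
  # flagged rows are excluded from the residual model, get NA z
  z0 <- suppressWarnings(residual_zscores(scan0, covariates = "n_snps"))
  expect_true(is.na(z0$residual_z[nrow(p0)]))
  expect_equal(mean(z0$residual_z, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("deviations are invariant to affine rescaling of the score", {
  snps <- random_snp_map(60, seed = 51)
  d <- random_dosages(90, snps, seed = 52)
  ped <- data.frame(family_id = sprintf("f%d", 1:30),
                    child_id = sprintf("s%03d", 1:30),
                    father_id = sprintf("s%03d", 31:60),
                    mother_id = sprintf("s%03d", 61:90))
  base <- ptdt_deviations(trio_scores(score_samples(d, snps), ped))
  # multiply all weights by 10
  w10 <- snps; w10$weight <- w10$weight * 10
  class(w10) <- class(snps)
  dev10 <- ptdt_deviations(trio_scores(score_samples(d, w10), ped))
  expect_equal(dev10, base, tolerance = 1e-12)
  # add a constant to every sample's score
  shifted <- score_samples(d, snps) + 42
  expect_equal(ptdt_deviations(trio_scores(shifted, ped)), base,
               tolerance = 1e-10)
})

test_that("residual z-scores match the normal-equations solution", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 74
    tab <- data.frame(
      partition_id = sprintf("p%02d", 1:n),
      estimate = rnorm(n, 0.1, 0.05),
      n_snps = sample(500:5000, n),
      effective_length = runif(n, 5, 33)  # Mb units keep the oracle stable
    )
    got <- residual_zscores(tab)
    X <- cbind(1, tab$n_snps, tab$effective_length)
    o <- ols_oracle(X, tab$estimate)
    expect_equal(got$residual_z, o$resid / sd(o$resid), tolerance = 1e-8)
    expect_equal(mean(got$residual_z), 0, tolerance = 1e-8)
    expect_equal(sd(got$residual_z), 1, tolerance = 1e-8)
  }
  # row order invariance
  tab <- data.frame(partition_id = sprintf("p%d", 1:20),
                    estimate = rnorm(20), n_snps = sample(100:999, 20),
                    effective_length = runif(20, 1, 30))
  z1 <- residual_zscores(tab)$residual_z
  perm <- sample(20)
  z2 <- residual_zscores(tab[perm, ])$residual_z
  expect_equal(z2, z1[perm], tolerance = 1e-12)
  # degenerate design: constant covariates collapse to standardization
  same <- tab; same$n_snps <- 1000L; same$effective_length <- 2e7
  expect_warning(zd <- residual_zscores(same), "collinear")
  expect_equal(zd$residual_z,
               (same$estimate - mean(same$estimate)) / sd(same$estimate))
  # three points on an exact line have zero residuals everywhere
  lin <- data.frame(partition_id = c("a", "b", "c"),
                    estimate = c(1, 2, 3), n_snps = c(10, 20, 30))
  expect_equal(residual_zscores(lin, covariates = "n_snps")$residual_z,
               c(0, 0, 0))
})

test_that("quadrant enrichment uses the exact binomial tail", {
  # worked example: 29 of 46 flagged at baseline 12/46
  set.seed(71)
  n <- 1000
  z_a <- rnorm(n); z_b <- rnorm(n)
  quad <- z_a > 0 & z_b > 0
  base <- mean(quad)
  # plant flags: 46 flagged, 29 in the quadrant
  flags <- rep(FALSE, n)
  flags[sample(which(quad), 29)] <- TRUE
  flags[sample(which(!quad), 17)] <- TRUE
  got <- quadrant_enrichment(z_a, z_b, flags)
  expect_equal(got$observed, 29)
  expect_equal(got$n_flagged, 46)
  expect_equal(got$expected, 46 * base)
  # independent exact-tail summation at the same baseline
  tail_sum <- sum(choose(46, 29:46) * base^(29:46) * (1 - base)^(46 - 29:46))
  expect_equal(got$p_value, tail_sum, tolerance = 1e-12)
  # all flagged in the quadrant at baseline 1/4 -> p = 0.25^n
  z1 <- c(rep(1, 5), rep(1, 5), rep(-1, 10))
  z2 <- c(rep(1, 5), rep(-1, 5), rep(1, 5), rep(-1, 5))
  flags2 <- c(rep(TRUE, 5), rep(FALSE, 15))
  got2 <- quadrant_enrichment(z1, z2, flags2)
  expect_equal(got2$baseline, 0.25)
  expect_equal(got2$p_value, 0.25^5, tolerance = 1e-12)
  # flags spread uniformly: observed near expected, p large
  flags3 <- seq_len(n) %% 10 == 0
  got3 <- quadrant_enrichment(z_a, z_b, flags3)
  expect_gt(got3$p_value, 0.05)
  expect_lt(abs(got3$observed - got3$expected), 10)
  expect_error(quadrant_enrichment(z_a, z_b, rep(FALSE, n)), "no flagged")
})

test_that("block removal follows the static most-transmitted ranking", {
  cfg <- sim_config(seed = 81, genome = list(n_snps = rep(100L, 6)),
                    trio = list(n_families = 80L,
                                ascertainment_quantile = NULL))
  snps <- simulate_snp_map(cfg)
  tr <- simulate_trios(cfg, snps)
  blocks <- make_snp_count_partitions(snps, 60)
  st <- stratified_scores(tr$dosages, snps, blocks)
  curve <- block_removal_decay(st, tr$pedigree)
  expect_equal(nrow(curve), nrow(blocks))
  expect_equal(curve$n_removed, 0:(nrow(blocks) - 1))
  # removal order equals a brute-force per-block ranking
  per_block <- vapply(seq_len(nrow(blocks)), function(i) {
    mean(ptdt_deviations(trio_scores(st[i, ], tr$pedigree)))
  }, numeric(1))
  expect_equal(curve$removed_block[-1],
               rownames(st)[order(-per_block)][-nrow(blocks)])
  # step 0 is the union of all blocks
  union_all <- ptdt_test(ptdt_deviations(trio_scores(colSums(st),
                                                     tr$pedigree)))
  expect_equal(curve$estimate[1], union_all$mean_deviation)
  # single block: length-1 curve equal to that block's test
  c1 <- block_removal_decay(st[1, , drop = FALSE], tr$pedigree)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$estimate,
               ptdt_test(ptdt_deviations(trio_scores(st[1, ],
                                                     tr$pedigree)))$mean_deviation)
})

test_that("carrier families are dropped by proband id", {
  ped <- data.frame(family_id = sprintf("f%d", 1:100),
                    child_id = sprintf("c%d", 1:100),
                    father_id = sprintf("fa%d", 1:100),
                    mother_id = sprintf("mo%d", 1:100))
  expect_equal(exclude_carrier_families(ped, character()), ped)
  set.seed(91)
  carriers <- sample(ped$child_id, 10)
  kept <- exclude_carrier_families(ped, carriers)
  expect_equal(nrow(kept), 90)
  expect_false(any(kept$child_id %in% carriers))
  expect_warning(exclude_carrier_families(ped, c(carriers, "nope")),
                 "not found")
})
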