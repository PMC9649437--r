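test_that("above-median filtering keeps strictly exceeding genes", {
  set.seed(201)
  e <- matrix(rnorm(10 * 6, mean = rep(1:10, 6)), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("d%d", 1:6)))
  kept <- filter_expressed(e)
  expect_length(kept, 5)
  m <- rowMeans(e)
  expect_setequal(kept, names(sort(m, decreasing = TRUE))[1:5])
  # all-equal matrix keeps nothing (strict inequality), warns
  flat <- matrix(1, 4, 3, dimnames = list(letters[1:4], NULL))
  expect_warning(k0 <- filter_expressed(flat), "empty set")
  expect_length(k0, 0)
})

test_that("within-cohort scaling standardizes each cohort separately", {
  set.seed(211)
  cohort <- rep(c("a", "b"), c(30, 50))
  x <- c(rnorm(30, 5, 2), rnorm(50, -3, 0.5))
  s <- scale_within_cohort(x, cohort)
  for (ch in c("a", "b")) {
    expect_equal(mean(s[cohort == ch]), 0, tolerance = 1e-12)
    expect_equal(sd(s[cohort == ch]), 1, tolerance = 1e-12)
  }
  # two-pass oracle
  oracle <- x
  for (ch in c("a", "b")) {
    i <- cohort == ch
    oracle[i] <- (x[i] - mean(x[i])) / sd(x[i])
  }
  expect_equal(s, oracle)
  # single cohort reduces to global standardization
  expect_equal(scale_within_cohort(x, rep("z", 80)),
               drop(scale(x)), ignore_attr = TRUE)
  # matrix form scales every row
  m <- matrix(rnorm(5 * 80), 5, 80, dimnames = list(letters[1:5], NULL))
  sm <- scale_within_cohort(m, cohort)
  expect_equal(rowMeans(sm[, cohort == "a"]), rep(0, 5),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(scale_within_cohort(rep(1, 80), cohort), "zero variance")
})

test_that("per-gene association matches the normal-equations oracle", {
  set.seed(221)
  n <- 200
  pgs <- rnorm(n)
  covs <- data.frame(diagnosis = rbinom(n, 1, 0.5),
                     ancestry_afr = rbinom(n, 1, 0.3))
  X <- cbind(1, pgs, covs$diagnosis, covs$ancestry_afr)
  e <- matrix(rnorm(5 * n), 5, n, dimnames = list(letters[1:5], NULL))
  e[1, ] <- e[1, ] - 0.3 * pgs  # planted effect on gene 1
  got <- per_gene_assoc(e, pgs, covs)
  for (g in 1:5) {
    o <- ols_oracle(X, e[g, ])
    expect_equal(got$beta[g], unname(o$beta[2]), tolerance = 1e-8)
    expect_equal(got$t_statistic[g], unname(o$t[2]), tolerance = 1e-8)
  }
  # planted beta recovered within 3 standard errors
  expect_lt(abs(got$beta[1] - (-0.3)), 3 * got$se[1])
  # constant PGS is rank deficient
  expect_error(per_gene_assoc(e, rep(1, n), covs), "collinear")
  # t-statistics invariant to within-cohort rescaling of expression
  cohort <- rep(c("x", "y"), each = n / 2)
  se1 <- per_gene_assoc(scale_within_cohort(e, cohort), pgs, covs)
  e_resc <- e * 7 + 3
  se2 <- per_gene_assoc(scale_within_cohort(e_resc, cohort), pgs, covs)
  expect_equal(se1$t_statistic, se2$t_statistic, tolerance = 1e-8)
})

test_that("mean regional association averages then fits the same model", {
  set.seed(231)
  n <- 150
  pgs <- rnorm(n)
  covs <- data.frame(diagnosis = rbinom(n, 1, 0.5))
  e <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  # single-gene set equals the per-gene fit
  one <- mean_region_assoc(e, pgs, "g01", covs)
  pg <- per_gene_assoc(e, pgs, covs)
  expect_equal(one$beta, pg$beta[1], tolerance = 1e-12)
  expect_equal(one$t_statistic, pg$t_statistic[1], tolerance = 1e-12)
  # equals the oracle on the averaged matrix
  gs <- sprintf("g%02d", 1:8)
  got <- mean_region_assoc(e, pgs, gs, covs)
  o <- ols_oracle(cbind(1, pgs, covs$diagnosis), colMeans(e[gs, ]))
  expect_equal(got$beta, unname(o$beta[2]), tolerance = 1e-10)
  expect_equal(got$t_statistic, unname(o$t[2]), tolerance = 1e-10)
  expect_error(mean_region_assoc(e, pgs, character(), covs), "empty")
  # planted regional shift: negative sign recovered reliably
  hits <- 0
  for (r in 1:40) {
    set.seed(300 + r)
    p2 <- rnorm(n)
    e2 <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
    e2[1:5, ] <- e2[1:5, ] + outer(rep(-0.3, 5), p2)
    f <- mean_region_assoc(e2, p2, sprintf("g%02d", 1:5))
    if (f$beta < 0) hits <- hits + 1
  }
  expect_gte(hits, 38)
})

test_that("permutation null shuffles scores within cohort, add-one p", {
  set.seed(241)
  n <- 80
  cohort <- rep(c("a", "b"), each = n / 2)
  pgs <- rnorm(n)
  e <- matrix(rnorm(12 * n), 12, n,
              dimnames = list(sprintf("g%02d", 1:12), NULL))
  gs <- sprintf("g%02d", 1:6)
  # strong planted depletion: observed beats every permutation
  e[1:6, ] <- e[1:6, ] - outer(rep(2, 6), pgs)
  got <- permutation_mean_t(e, pgs, gs, cohort = cohort, n_perm = 50,
                            seed = 9)
  expect_equal(got$empirical_p, 1 / 51)
  expect_length(got$null_mean_t, 50)
  # determinism: identical seed, identical result
  again <- permutation_mean_t(e, pgs, gs, cohort = cohort, n_perm = 50,
                              seed = 9)
  expect_identical(got, again)
  # a different seed moves the null draws but not the observed statistic
  other <- permutation_mean_t(e, pgs, gs, cohort = cohort, n_perm = 50,
                              seed = 10)
  expect_identical(other$observed_mean_t, got$observed_mean_t)
  expect_false(identical(other$null_mean_t, got$null_mean_t))
  expect_error(permutation_mean_t(e, pgs, gs, n_perm = 0), "n_perm")
})

test_that("consistency statistic is the most positive cohort coefficient", {
  expect_equal(consistency_stat(c(-0.1, -0.05, -0.2)), -0.05)
  expect_equal(consistency_stat(-0.3), -0.3)
  set.seed(251)
  b <- rnorm(10)
  expect_equal(consistency_stat(b), max(b))
  expect_error(consistency_stat(numeric()), "at least one")
})

test_that("regional DE contrast excludes the widened CNV window", {
  set.seed(261)
  n <- 60
  de <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "16",
                   start = seq(0, by = 5e5, length.out = n))
  de$end <- de$start + 4e4
  de$t_statistic <- rnorm(n)
  de$log2fc <- rnorm(n, sd = 0.1)
  win <- list(chrom = "16", start = 10e6, end = 11e6)
  region <- de$gene_id[de$start < 20e6]
  got <- region_de_contrast(de, region, win, exclusion = 1e5)
  # genes overlapping [9.9, 11.1) Mb are dropped: a gene starting 50 kb
  # beyond the window end is still excluded
  boundary <- de$gene_id[de$start == 11e6 + 0]  # starts at 11.0 Mb < 11.1
  dropped <- de$gene_id[de$start < 11.1e6 & de$end > 9.9e6]
  expect_equal(got$n_region + got$n_background, n - length(dropped))
  # symmetric group statistics: two-sample t of 0
  de2 <- de[1:6, ]
  de2$t_statistic <- c(-1, 0, 1, -1, 0, 1)
  got2 <- region_de_contrast(de2, de2$gene_id[1:3], cnv_window = NULL)
  expect_equal(got2$mean_t_region, 0)
  expect_equal(got2$two_sample_p, 1)
  # with no window the contrast reduces to plain two-sample t-tests
  got3 <- region_de_contrast(de, region, cnv_window = NULL)
  in_r <- de$gene_id %in% region
  expect_equal(got3$two_sample_p,
               t.test(de$t_statistic[in_r], de$t_statistic[!in_r])$p.value)
  expect_equal(got3$one_sample_p, t.test(de$t_statistic[in_r])$p.value)
  expect_error(region_de_contrast(de, "nope", cnv_window = NULL),
               "empty region")
})

test_that("cross-analysis effects correlate over shared genes", {
  set.seed(271)
  ta <- rnorm(50); names(ta) <- sprintf("g%02d", 1:50)
  got <- cross_effect_correlation(ta, ta)
  expect_equal(got$r, 1)
  tb <- rnorm(40); names(tb) <- sprintf("g%02d", 11:50)
  got2 <- cross_effect_correlation(ta, tb)
  expect_equal(got2$n_genes, 40)
  ref <- density_correlation(unname(ta[names(tb)]), unname(tb))
  expect_equal(got2$r, ref$r)
  expect_equal(got2$p_value, ref$p_value)
  expect_error(cross_effect_correlation(ta[1:2], ta[1:2]), "3 shared")
})
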