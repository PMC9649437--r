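#' Simulation configuration
#'
#' One configuration object drives every generator, so a full synthetic
#' study is a pure function of `(config, seed)`. The default genome is a
#' desk-scale emulation of an autosomal genome: five background
#' chromosomes of 132 Mb and one 90-Mb chromosome labelled "16" whose
#' first 33 Mb (the p-arm analogue) is the designated effect region.
#' Trio defaults emulate a large ascertained trio collection: 5,048
#' families, a polygenic score carrying 1.5\% of liability variance, and
#' proband ascertainment at the top 2\% of liability — under the liability
#' threshold model these imply a cohort-level over-transmission of about
#' 0.2 s.d. of the midparent score distribution. Expression defaults
#' emulate three cohorts of 122 single-cell, 229 bulk European-ancestry
#' and 193 bulk African-ancestry donors with a regional effect of -0.3
#' s.d. expression per s.d. regional score. Hi-C defaults produce a
#' 330-bin, 100-kb distance-decay matrix with a 3x boosted distal
#' rectangle between a 0.7-Mb locus (29.5-30.2 Mb) and the first 5.2 Mb.
#'
#' @param seed integer master seed; every generator derives its stream
#'   from it.
#' @param ... named overrides, either top-level (`seed`) or nested lists
#'   (`genome`, `effect_region`, `trio`, `expression`, `annotation`,
#'   `hic`) merged into the defaults element-wise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(
      chromosomes = c("1", "2", "3", "4", "5", "16"),
      lengths = c(rep(132e6, 5), 90e6),
      n_snps = c(rep(1200L, 5), 1200L),
      af_range = c(0.05, 0.5),
      weight_sd = 1,
      big_gap_prob = 0.01,
      big_gap_range = c(1.2e6, 3e6)
    ),
    effect_region = list(chrom = "16", start = 0, end = 33e6,
                         weight_multiplier = 4),
    trio = list(
      n_families = 5048L,
      pgs_liability_share = 0.015,
      ascertainment_quantile = 0.98,
      include_siblings = FALSE,
      batch_size = 1000L,
      max_batches = 5000L
    ),
    expression = list(
      n_region_genes = 40L,
      n_background_genes = 160L,
      region_beta = -0.3,
      noise_sd = 1,
      cohort_sizes = c(sn = 122L, bulk_eur = 229L, bulk_afr = 193L),
      assay_single_cell = c(sn = 1, bulk_eur = 0, bulk_afr = 0),
      ancestry_afr = c(sn = 0, bulk_eur = 0, bulk_afr = 1),
      diagnosis_effect = 0.2,
      ancestry_effect = 0.2,
      assay_effect = 0.3,
      cohort_mean_sd = 0.5,
      cohort_scales = c(sn = 1, bulk_eur = 1.5, bulk_afr = 0.75)
    ),
    annotation = list(
      n_genes = 2000L,
      density_multiplier = 2,
      specificity_excess = 0.5,
      n_segdups = 300L,
      segdup_length_range = c(2e4, 2e5),
      centromere_halfwidth = 1.5e6,
      de_shift = -0.2,
      de_noise_sd = 1
    ),
    hic = list(
      n_bins = 330L,
      resolution = 1e5,
      decay = 1,
      scale = 100,
      noise_sdlog = 0.2,
      block_bins = NULL,
      block_boost = 1,
      rect_a = c(29.5e6, 30.2e6),
      rect_b = c(0, 5.2e6),
      rectangle_boost = 3,
      zero_fraction = 0
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  stopifnot(cfg$trio$pgs_liability_share >= 0,
            cfg$trio$pgs_liability_share <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Chromosome bounds of a simulated genome
#'
#' @param cfg a [sim_config()].
#' @return `data.frame` with `chrom`, `start` (0), `end`.
#' @export
genome_bounds <- function(cfg) {
  data.frame(chrom = cfg$genome$chromosomes, start = 0,
             end = cfg$genome$lengths, stringsAsFactors = FALSE)
}

in_effect_region <- function(cfg, chrom, pos0) {
  er <- cfg$effect_region
  chrom == er$chrom & pos0 >= er$start & pos0 < er$end
}

#' Simulate a SNP map
#'
#' Positions are laid down by cumulative inter-SNP gaps (exponential, with
#' occasional gaps larger than 1 Mb so that gap capping is exercised);
#' weights are drawn centered at zero and inflated by the configured
#' multiplier inside the effect region, concentrating score variance
#' there.
#'
#' @param cfg a [sim_config()].
#' @return A [snp_map()].
#' @export
simulate_snp_map <- function(cfg) {
  set.seed(cfg$seed + 101L)
  g <- cfg$genome
  out <- list()
  for (i in seq_along(g$chromosomes)) {
    n <- g$n_snps[i]
    mean_gap <- 0.9 * g$lengths[i] / n
    gaps <- stats::rexp(n, rate = 1 / mean_gap)
    big <- stats::runif(n) < g$big_gap_prob
    gaps[big] <- stats::runif(sum(big), g$big_gap_range[1],
                              g$big_gap_range[2])
    pos <- round(cumsum(pmax(gaps, 1)))
    pos <- pos[pos <= g$lengths[i] - 1]
    pos <- pos[!duplicated(pos)]
    n <- length(pos)
    w <- stats::rnorm(n, 0, g$weight_sd)
    boost <- in_effect_region(cfg, g$chromosomes[i], pos - 1)
    w[boost] <- w[boost] * cfg$effect_region$weight_multiplier
    out[[i]] <- data.frame(
      snp_id = sprintf("snp_%s_%06d", g$chromosomes[i], seq_len(n)),
      chrom = g$chromosomes[i], pos = pos, effect_allele = "A", weight = w,
      stringsAsFactors = FALSE
    )
  }
  x <- do.call(rbind, out)
  snp_map(x$snp_id, x$chrom, x$pos, x$effect_allele, x$weight,
          chrom_levels = g$chromosomes)
}

#' Simulate ascertained trios
#'
#' Parent genotypes are drawn per SNP as binomial(2, allele frequency)
#' with frequencies uniform over the configured range (independent sites,
#' no linkage disequilibrium); each child allele is a fair Mendelian draw
#' from its parent's two alleles. Proband status follows the liability
#' threshold model: liability `L = sqrt(h2) * Z + sqrt(1 - h2) * e`, where
#' `Z` is the child's polygenic score standardized by its theoretical
#' moments (`sum 2pw`, `sum 2p(1-p)w^2`) and `e` is standard normal
#' environment; a family is ascertained when `L` exceeds the configured
#' liability quantile. Over-transmission in ascertained probands is
#' therefore emergent from the model, not injected. Families are generated
#' in batches until the target count of probands is reached. Optionally an
#' unascertained sibling (an independent Mendelian draw from the same
#' parents) is generated per ascertained family.
#'
#' @param cfg a [sim_config()]; `trio$ascertainment_quantile = NULL`
#'   disables ascertainment (every simulated family is kept).
#' @param snps a [snp_map()] from [simulate_snp_map()].
#' @return List: `dosages` (samples x SNPs matrix; ids `famNNNN_p/_m/_f`
#'   and `_s` for siblings), `pedigree` (one proband row per family, plus
#'   sibling rows when requested), `allele_freq`.
#' @export
simulate_trios <- function(cfg, snps) {
  stopifnot_snp_map(snps)
  set.seed(cfg$seed + 202L)
  tr <- cfg$trio
  m <- nrow(snps)
  f <- stats::runif(m, cfg$genome$af_range[1], cfg$genome$af_range[2])
  w <- snps$weight
  mu <- sum(2 * f * w)
  sg <- sqrt(sum(2 * f * (1 - f) * w^2))
  thr <- if (is.null(tr$ascertainment_quantile)) -Inf else
    stats::qnorm(tr$ascertainment_quantile)
  h2 <- tr$pgs_liability_share
  n_target <- tr$n_families
  bs <- if (is.finite(thr)) tr$batch_size else n_target
  keep_mo <- keep_fa <- keep_ch <- keep_sib <- list()
  got <- 0L
  for (b in seq_len(tr$max_batches)) {
    fp <- rep(f, each = bs)
    mo <- matrix(stats::rbinom(bs * m, 2, fp), bs, m)
    fa <- matrix(stats::rbinom(bs * m, 2, fp), bs, m)
    ch <- matrix(stats::rbinom(bs * m, 1, mo / 2) +
                   stats::rbinom(bs * m, 1, fa / 2), bs, m)
    z <- (drop(ch %*% w) - mu) / sg
    liab <- sqrt(h2) * z + sqrt(1 - h2) * stats::rnorm(bs)
    acc <- which(liab > thr)
    if (length(acc)) {
      take <- acc[seq_len(min(length(acc), n_target - got))]
      keep_mo[[b]] <- mo[take, , drop = FALSE]
      keep_fa[[b]] <- fa[take, , drop = FALSE]
      keep_ch[[b]] <- ch[take, , drop = FALSE]
      if (isTRUE(tr$include_siblings)) {
        keep_sib[[b]] <- matrix(
          stats::rbinom(length(take) * m, 1, keep_mo[[b]] / 2) +
            stats::rbinom(length(take) * m, 1, keep_fa[[b]] / 2),
          length(take), m)
      }
      got <- got + length(take)
    }
    if (got >= n_target) break
  }
  if (got < n_target) {
    stop("ascertainment stalled: only ", got, " of ", n_target,
         " probands after ", tr$max_batches, " batches")
  }
  mo <- do.call(rbind, keep_mo)
  fa <- do.call(rbind, keep_fa)
  ch <- do.call(rbind, keep_ch)
  fam <- sprintf("fam%04d", seq_len(n_target))
  blocks <- list(ch, mo, fa)
  ids <- c(paste0(fam, "_p"), paste0(fam, "_m"), paste0(fam, "_f"))
  if (isTRUE(tr$include_siblings)) {
    blocks <- c(blocks, list(do.call(rbind, keep_sib)))
    ids <- c(ids, paste0(fam, "_s"))
  }
  d <- do.call(rbind, blocks)
  dimnames(d) <- list(ids, snps$snp_id)
  ped <- data.frame(family_id = fam, child_id = paste0(fam, "_p"),
                    father_id = paste0(fam, "_f"),
                    mother_id = paste0(fam, "_m"), role = "proband",
                    stringsAsFactors = FALSE)
  if (isTRUE(tr$include_siblings)) {
    ped <- rbind(ped, data.frame(
      family_id = fam, child_id = paste0(fam, "_s"),
      father_id = paste0(fam, "_f"), mother_id = paste0(fam, "_m"),
      role = "sibling", stringsAsFactors = FALSE))
  }
  list(dosages = d, pedigree = ped, allele_freq = f)
}

#' Simulate a regional expression study
#'
#' Region genes respond linearly to the donors' regional polygenic score
#' (standardized within cohort); background genes carry no score effect.
#' All genes receive diagnosis, ancestry-group and assay-type covariate
#' effects, a per-gene baseline, cohort-specific mean offsets and
#' cohort-specific noise scales — the latter two exist solely so that
#' within-cohort standardization has real work to do.
#'
#' @param cfg a [sim_config()].
#' @param pgs optional named regional score per donor; default standard
#'   normal draws for `sum(cohort_sizes)` donors.
#' @return List: `expr` (genes x donors), `covariates` (`donor_id`,
#'   `cohort`, `diagnosis`, `ancestry_afr`, `assay_single_cell`, `pgs`),
#'   `genes` (gene table with region genes inside the effect region).
#' @export
simulate_expression <- function(cfg, pgs = NULL) {
  set.seed(cfg$seed + 303L)
  ex <- cfg$expression
  sizes <- ex$cohort_sizes
  cohort <- rep(names(sizes), sizes)
  n_d <- length(cohort)
  if (is.null(pgs)) {
    pgs <- stats::rnorm(n_d)
    names(pgs) <- sprintf("donor%04d", seq_len(n_d))
  } else {
    if (length(pgs) < n_d) {
      stop("need at least ", n_d, " donor scores for the configured cohorts")
    }
    pgs <- pgs[seq_len(n_d)]
  }
  # per-cohort parameters match cohorts by name; a renamed cohort set
  # falls back to positional recycling
  by_cohort <- function(v) {
    if (all(names(sizes) %in% names(v))) return(v[names(sizes)])
    stats::setNames(rep_len(unname(v), length(sizes)), names(sizes))
  }
  diagnosis <- stats::rbinom(n_d, 1, 0.5)
  ancestry <- unname(by_cohort(ex$ancestry_afr)[cohort])
  assay <- unname(by_cohort(ex$assay_single_cell)[cohort])
  zpgs <- scale_within_cohort(unname(pgs), cohort)
  er <- cfg$effect_region
  n_r <- ex$n_region_genes
  n_b <- ex$n_background_genes
  bg_chrom <- sample(setdiff(cfg$genome$chromosomes, er$chrom), n_b,
                     replace = TRUE)
  bg_len <- cfg$genome$lengths[match(bg_chrom, cfg$genome$chromosomes)]
  starts_r <- sort(round(stats::runif(n_r, er$start, er$end - 6e4)))
  starts_b <- round(stats::runif(n_b, 0, bg_len - 6e4))
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_r + n_b)),
    chrom = c(rep(er$chrom, n_r), bg_chrom),
    start = c(starts_r, starts_b),
    end = c(starts_r, starts_b) + 5e4,
    region = c(rep(TRUE, n_r), rep(FALSE, n_b)),
    stringsAsFactors = FALSE
  )
  base <- stats::rnorm(n_r + n_b, 0, 0.5)
  cmeans <- matrix(stats::rnorm((n_r + n_b) * length(sizes), 0,
                                ex$cohort_mean_sd),
                   n_r + n_b, length(sizes),
                   dimnames = list(NULL, names(sizes)))
  beta_g <- ifelse(genes$region, ex$region_beta, 0)
  fixed <- ex$diagnosis_effect * diagnosis + ex$ancestry_effect * ancestry +
    ex$assay_effect * assay
  noise_scale <- unname(by_cohort(ex$cohort_scales)[cohort])
  expr <- outer(beta_g, zpgs) +
    matrix(fixed, n_r + n_b, n_d, byrow = TRUE) +
    base + cmeans[, cohort] +
    matrix(stats::rnorm((n_r + n_b) * n_d, 0, ex$noise_sd), n_r + n_b, n_d) *
      matrix(noise_scale, n_r + n_b, n_d, byrow = TRUE)
  dimnames(expr) <- list(genes$gene_id, names(pgs))
  covariates <- data.frame(
    donor_id = names(pgs), cohort = cohort, diagnosis = diagnosis,
    ancestry_afr = ancestry, assay_single_cell = assay, pgs = unname(pgs),
    stringsAsFactors = FALSE
  )
  list(expr = expr, covariates = covariates, genes = genes)
}

#' Simulate a Hi-C contact matrix
#'
#' Entries follow a power-law distance decay,
#' `scale * (|i - j| * resolution)^(-decay)`, under multiplicative
#' log-normal noise, symmetrized; the diagonal uses an effective distance
#' of half a bin. A designated bin block can be boosted (elevated
#' within-region contact) and a designated off-diagonal rectangle between
#' two genomic intervals can be boosted (elevated distal contact).
#' Optionally a fraction of bins is zero-masked, emulating zeroed
#' hard-to-map rows.
#'
#' @param cfg a [sim_config()]; `hic$decay` must be positive.
#' @return A [contact_matrix()].
#' @export
simulate_contact_matrix <- function(cfg) {
  set.seed(cfg$seed + 404L)
  h <- cfg$hic
  if (h$decay <= 0) stop("decay exponent must be positive")
  n <- h$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-")) * h$resolution
  diag(d) <- h$resolution / 2
  noise <- matrix(0, n, n)
  up <- upper.tri(noise, diag = TRUE)
  noise[up] <- stats::rnorm(sum(up), 0, h$noise_sdlog)
  noise <- noise + t(noise) - diag(diag(noise))
  mat <- h$scale * d^(-h$decay) * exp(noise)
  if (!is.null(h$block_bins) && h$block_boost != 1) {
    b <- h$block_bins
    mat[b, b] <- mat[b, b] * h$block_boost
  }
  zs <- "true_zero"
  if (h$rectangle_boost != 1 && !is.null(h$rect_a)) {
    cm <- contact_matrix(mat, h$resolution)
    ba <- snap_to_bins(h$rect_a, cm)
    bb <- snap_to_bins(h$rect_b, cm)
    mat[ba, bb] <- mat[ba, bb] * h$rectangle_boost
    mat[bb, ba] <- t(mat[ba, bb])
  }
  if (h$zero_fraction > 0) {
    masked <- sample(n, round(h$zero_fraction * n))
    mat[masked, ] <- 0
    mat[, masked] <- 0
    zs <- "masked"
  }
  contact_matrix(mat, h$resolution, chrom = cfg$effect_region$chrom,
                 zero_semantics = zs)
}

#' Simulate gene and interval annotations
#'
#' Genes are placed uniformly, with the configured density multiplier
#' concentrating extra genes in the effect region; specificity statistics
#' are standard normal plus a regional excess. Segmental-duplication-like
#' intervals are scattered genome wide; one centromere interval sits at
#' the middle of each chromosome. A per-gene differential-expression table
#' carries a configurable regional shift in the t-statistics and log2
#' fold-changes.
#'
#' @param cfg a [sim_config()].
#' @return List: `genes` (with `specificity_t`), `segdups`, `centromeres`,
#'   `de` (gene table with `log2fc`, `t_statistic`).
#' @export
simulate_annotations <- function(cfg) {
  set.seed(cfg$seed + 505L)
  an <- cfg$annotation
  g <- cfg$genome
  er <- cfg$effect_region
  len_weight <- g$lengths / sum(g$lengths)
  chrom <- sample(g$chromosomes, an$n_genes, replace = TRUE,
                  prob = len_weight)
  lens <- g$lengths[match(chrom, g$chromosomes)]
  start <- round(stats::runif(an$n_genes, 0, lens - 6e4))
  if (an$density_multiplier > 1) {
    base_rate <- an$n_genes * (er$end - er$start) / sum(g$lengths)
    n_extra <- round((an$density_multiplier - 1) * base_rate)
    chrom <- c(chrom, rep(er$chrom, n_extra))
    start <- c(start, round(stats::runif(n_extra, er$start, er$end - 6e4)))
  }
  n <- length(chrom)
  genes <- data.frame(
    gene_id = sprintf("ann%05d", seq_len(n)), chrom = chrom, start = start,
    end = start + 5e4, stringsAsFactors = FALSE
  )
  region <- in_effect_region(cfg, genes$chrom,
                             floor((genes$start + genes$end) / 2))
  genes$specificity_t <- stats::rnorm(n) + an$specificity_excess * region
  sd_chrom <- sample(g$chromosomes, an$n_segdups, replace = TRUE,
                     prob = len_weight)
  sd_len <- stats::runif(an$n_segdups, an$segdup_length_range[1],
                         an$segdup_length_range[2])
  sd_start <- round(stats::runif(
    an$n_segdups, 0, g$lengths[match(sd_chrom, g$chromosomes)] - sd_len))
  segdups <- data.frame(chrom = sd_chrom, start = sd_start,
                        end = round(sd_start + sd_len),
                        stringsAsFactors = FALSE)
  centromeres <- data.frame(
    chrom = g$chromosomes,
    start = round(g$lengths / 2 - an$centromere_halfwidth),
    end = round(g$lengths / 2 + an$centromere_halfwidth),
    stringsAsFactors = FALSE
  )
  de <- genes[, c("gene_id", "chrom", "start", "end")]
  de$t_statistic <- stats::rnorm(n, 0, an$de_noise_sd) + an$de_shift * region
  de$log2fc <- 0.1 * de$t_statistic + stats::rnorm(n, 0, 0.02)
  list(genes = genes, segdups = segdups, centromeres = centromeres, de = de)
}
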