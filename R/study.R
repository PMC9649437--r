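#' Configuration for the convergence demonstration scenario
#'
#' A seeded scenario in which a weight-concentrated effect region, a
#' liability-ascertained trio cohort, a negative regional
#' score-expression effect and a boosted Hi-C contact block all point at
#' the same region, so the qualitative convergence of the three analysis
#' arms (transmission residual z, expression beta sign, contact residual
#' z) can be demonstrated in one run. Sizes and shares are reduced from
#' the generator defaults to desk scale: 600 families, a polygenic score
#' carrying 15\% of liability at top-5\% ascertainment, so that the
#' regional rankings are stable at this cohort size.
#'
#' @param seed integer master seed.
#' @param n_families number of ascertained families.
#' @param ... further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
convergence_config <- function(seed = 1, n_families = 600L, ...) {
  sim_config(
    seed = seed,
    trio = list(n_families = as.integer(n_families),
                pgs_liability_share = 0.15,
                ascertainment_quantile = 0.95,
                batch_size = 2000L),
    ...
  )
}

#' Simulate a complete regional-convergence study
#'
#' Runs every generator under one configuration and assembles the analysis
#' inputs: SNP map, ascertained trios, 33-Mb partitions with member SNPs
#' and effective lengths, annotations, an expression study whose donors
#' are the trio probands (their regional stratified score is the exposure)
#' and one Hi-C matrix per chromosome at 1-Mb bins with the effect
#' region's contact block boosted.
#'
#' @param cfg a [sim_config()], e.g. [convergence_config()].
#' @return List: `cfg`, `snps`, `trios`, `partitions`, `strat` (partition x
#'   sample stratified scores), `region_id` (partition containing the
#'   effect region), `annotations`, `expression`, `hic` (named list of
#'   [contact_matrix()] per chromosome).
#' @export
simulate_study <- function(cfg) {
  snps <- simulate_snp_map(cfg)
  trios <- simulate_trios(cfg, snps)
  partitions <- make_fixed_length_partitions(genome_bounds(cfg), 33e6, snps)
  partitions$effective_length <- effective_length(partitions, snps)
  strat <- stratified_scores(trios$dosages, snps, partitions)
  er <- cfg$effect_region
  region_id <- partitions$partition_id[
    partitions$chrom == er$chrom & partitions$start <= er$start &
      partitions$end >= er$end][1]
  ann <- simulate_annotations(cfg)
  n_donors <- sum(cfg$expression$cohort_sizes)
  if (nrow(trios$pedigree) < n_donors) {
    stop("scenario needs at least ", n_donors, " families for donors")
  }
  donor_pgs <- strat[region_id, trios$pedigree$child_id[seq_len(n_donors)]]
  expression <- simulate_expression(cfg, pgs = donor_pgs)
  hic <- lapply(seq_along(cfg$genome$chromosomes), function(i) {
    ch <- cfg$genome$chromosomes[i]
    hcfg <- sim_config(
      seed = cfg$seed + i,
      genome = cfg$genome, effect_region = cfg$effect_region,
      hic = utils::modifyList(cfg$hic, list(
        n_bins = as.integer(cfg$genome$lengths[i] / 1e6),
        resolution = 1e6,
        rectangle_boost = 1,
        block_bins = if (ch == er$chrom) {
          seq.int(er$start / 1e6 + 1, er$end / 1e6)
        },
        block_boost = if (ch == er$chrom) 2 else 1
      ))
    )
    m <- simulate_contact_matrix(hcfg)
    m$chrom <- ch
    m
  })
  names(hic) <- cfg$genome$chromosomes
  list(cfg = cfg, snps = snps, trios = trios, partitions = partitions,
       strat = strat, region_id = region_id, annotations = ann,
       expression = expression, hic = hic)
}

#' Analyze a simulated study end to end
#'
#' The three analysis arms on a [simulate_study()] result: (1) stratified
#' transmission scan over the 33-Mb partitions with SNP-count residual
#' z-scores; (2) mean regional expression association of the region's
#' genes on the donors' regional score, with diagnosis, ancestry and assay
#' covariates, after within-cohort standardization; (3) per-partition
#' within-region contact (off-diagonal mean at 1-Mb bins) residualized on
#' gene count and segmental duplication coverage.
#'
#' @param study result of [simulate_study()].
#' @return List: `sptdt` (region stat table with `residual_z`),
#'   `sptdt_rank` (rank of the effect region, 1 = most over-transmitted),
#'   `expr_beta`, `expr_p`, `contact` (per-partition table with
#'   `contact_z`), `contact_rank`, `region_id`.
#' @export
analyze_study <- function(study) {
  scan <- sptdt_scan(study$strat, study$trios$pedigree, study$partitions)
  scan <- residual_zscores(scan, covariates = "n_snps")
  sptdt_rank <- rank(-scan$residual_z)[scan$partition_id == study$region_id]

  ex <- study$expression
  cohort <- ex$covariates$cohort
  sexpr <- scale_within_cohort(ex$expr, cohort)
  spgs <- scale_within_cohort(ex$covariates$pgs, cohort)
  covs <- ex$covariates[, c("diagnosis", "ancestry_afr",
                            "assay_single_cell")]
  fit <- mean_region_assoc(sexpr, spgs,
                           ex$genes$gene_id[ex$genes$region],
                           covariates = covs)

  parts <- study$partitions
  contacts <- vapply(seq_len(nrow(parts)), function(i) {
    m <- study$hic[[parts$chrom[i]]]
    within_region_contact(m, snap_to_bins(parts[i, ], m),
                          mode = "off_diagonal")
  }, numeric(1))
  gene_counts <- lengths(assign_genes(study$annotations$genes, parts))
  segdup <- segdup_fraction(parts, study$annotations$segdups)
  cz <- contact_residual_z(contacts, gene_counts, segdup)
  contact_tab <- data.frame(partition_id = parts$partition_id,
                            contact = contacts, gene_count = gene_counts,
                            segdup_fraction = segdup, contact_z = cz,
                            stringsAsFactors = FALSE)
  list(sptdt = scan, sptdt_rank = unname(sptdt_rank),
       expr_beta = fit$beta, expr_p = fit$p_value,
       contact = contact_tab,
       contact_rank = unname(rank(-cz)[parts$partition_id ==
                                         study$region_id]),
       region_id = study$region_id)
}
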