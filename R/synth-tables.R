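#' Generate annotation tables with planted truth
#'
#' Emits the per-SNV side tables the deletion pipeline consumes: allele
#' ages (ancient deletions' companions predate the AMH-archaic split),
#' balancing-selection scores (stdb2), genome-wide-association rows
#' (planted GWAS deletions get a companion below the significance
#' threshold), an exon annotation whose exons overlap planted exonic
#' deletions, the introgressed-SNV (S*) list, and neutral genealogical
#' lineage-count trajectories for the frequency-stability statistic.
#'
#' @param cohort A `synth_cohort` from [generate_cohort()].
#' @param n_trajectories Number of neutral trajectory variants to
#'   simulate (independent of the deletion loci; they calibrate the
#'   stability statistic's null).
#' @param trajectory_model Demographic model for the neutral trajectories.
#' @param time_grid_years Trajectory time grid (must cover 5,000 and
#'   50,000 years).
#' @return List of data.frames: `ages` (snv_id, age_years), `scores`
#'   (snv_id, pop, stdbeta2), `gwas` (snv_id, trait, p), `exons` (chrom,
#'   start, end, gene; 0-based half-open), `sstar` (snv_id),
#'   `trajectories` (variant, time_years, derived_lineages,
#'   total_lineages, n_present, present_freq) and `trait_categories`
#'   (trait, category).
#' @export
generate_annotation_tables <- function(cohort, n_trajectories = 500,
                                       trajectory_model = NULL,
                                       time_grid_years = c(5000, 50000)) {
  stopifnot(inherits(cohort, "synth_cohort"))
  config <- cohort$config
  truth <- cohort$truth
  snvs <- cohort$sites[cohort$sites$type == "snv", ]
  if (!all(c(5000, 50000) %in% time_grid_years))
    stop("time grid must include 5,000 and 50,000 years")

  with_seed(substream_seed(config$seed, "tables"), {
    ancient_ids <- truth$id[truth$category == "ancient"]
    anc_comp <- unlist(strsplit(truth$companions[truth$id %in% ancient_ids],
                                ","))
    # ages: companions of ancient deletions predate the split
    age <- ifelse(snvs$id %in% anc_comp,
                  runif(nrow(snvs), 750000, 2000000),
                  runif(nrow(snvs), 10000, 500000))
    ages <- data.frame(snv_id = snvs$id, age_years = round(age))

    scores <- do.call(rbind, lapply(c("YRI", "CEU", "CHB"), function(p)
      data.frame(snv_id = snvs$id, pop = p,
                 stdbeta2 = round(exp(rnorm(nrow(snvs), 0, 1)), 4))))

    # GWAS: planted associated deletions get one companion below 1e-8
    traits <- sprintf("trait_%02d", 1:40)
    categories <- sprintf("category_%02d", 1:18)
    trait_categories <- data.frame(
      trait = traits, category = sample(categories, 40, replace = TRUE))
    gwas_rows <- list()
    for (i in seq_len(nrow(truth))) {
      comp <- strsplit(truth$companions[i], ",")[[1]]
      if (truth$gwas[i]) {
        hit <- sample(comp, 1)
        gwas_rows[[length(gwas_rows) + 1L]] <- data.frame(
          snv_id = hit, trait = sample(traits, 1),
          p = 10^runif(1, -20, -9))
      }
      # sub-threshold associations that must be ignored downstream
      if (runif(1) < 0.3) {
        gwas_rows[[length(gwas_rows) + 1L]] <- data.frame(
          snv_id = sample(comp, 1), trait = sample(traits, 1),
          p = 10^runif(1, -7, -3))
      }
    }
    gwas <- if (length(gwas_rows)) do.call(rbind, gwas_rows) else
      data.frame(snv_id = character(), trait = character(), p = numeric())

    # exons: one exon inside each planted exonic deletion, plus decoys
    exon_rows <- list()
    for (i in seq_len(nrow(truth))) {
      d <- cohort$deletions[cohort$deletions$id == truth$id[i], ]
      if (truth$exonic[i]) {
        es <- d$start + (d$end - d$start) %/% 4L
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          chrom = d$chrom, start = es,
          end = es + max(50L, (d$end - d$start) %/% 4L),
          gene = sprintf("GENE_%s", toupper(d$id)))
      } else {
        # decoy exon well away from the deletion window
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          chrom = d$chrom, start = LOCUS_BP - 5000L, end = LOCUS_BP - 4800L,
          gene = sprintf("DECOY_%s", toupper(d$id)))
      }
    }
    exons <- do.call(rbind, exon_rows)

    sstar <- data.frame(snv_id = cohort$sstar_snvs)

    trajectories <- simulate_neutral_trajectories(
      n_trajectories, model = trajectory_model,
      time_grid_years = time_grid_years,
      seed = substream_seed(config$seed, "trajectories"))

    list(ages = ages, scores = scores, gwas = gwas, exons = exons,
         sstar = sstar, trajectories = trajectories,
         trait_categories = trait_categories)
  })
}

#' Neutral genealogical lineage-count trajectories
#'
#' Simulates unlinked variants under a neutral demographic model and
#' reports, at each grid time, the number of sample-genealogy lineages
#' remaining and the number of those carrying the derived allele --
#' the input format of the frequency-stability statistic, emulating what a
#' genealogy-inference method reports for real variants.
#'
#' @param n_variants Number of unlinked variants.
#' @param model A [demographic_model()]; default is the realistic
#'   constant-size model sampled at present.
#' @param time_grid_years Grid times, years before present.
#' @param seed Integer seed.
#' @param n_yri YRI haploid sample size.
#' @return Long data.frame: `variant`, `time_years`, `derived_lineages`,
#'   `total_lineages`, `n_present`, `present_freq`.
#' @export
simulate_neutral_trajectories <- function(n_variants, model = NULL,
                                          time_grid_years = c(5000, 50000),
                                          seed = 1L, n_yri = 216) {
  if (is.null(model))
    model <- demographic_model(archaic_sampling_times = "present")
  res <- run_engine(model, n_variants, seed, n_yri = n_yri,
                    query_times_years = time_grid_years,
                    return_matrix = FALSE, archaic_haploids = 0L)
  d0 <- res$group_counts[, 1L]
  data.frame(
    variant = rep(sprintf("var_%05d", seq_len(n_variants)),
                  each = length(time_grid_years)),
    time_years = rep(time_grid_years, n_variants),
    derived_lineages = as.integer(t(res$lineages_derived)),
    total_lineages = as.integer(t(res$lineages_total)),
    n_present = n_yri,
    present_freq = rep(d0 / n_yri, each = length(time_grid_years)))
}
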