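#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions for a synthetic three-population phased
#' cohort with planted deletion polymorphisms, LD-tagging SNVs, archaic
#' genomes, and annotation tables.  Defaults mirror the empirical setting:
#' 1000-Genomes-sized samples (YRI 108, CEU 103, CHB 99 diploids), four
#' high-coverage archaic genomes, and a category mix matching the
#' empirically observed partition of deletions (88.2% AMH-specific, 1.1%
#' recurrent, 1.9% introgressed, 8.8% ancient).
#'
#' @param n_deletions Number of deletion loci.
#' @param category_mix Named proportions over `human_specific`,
#'   `recurrent`, `introgressed`, `ancient`; must sum to 1.
#' @param n_snvs_per_locus SNVs generated per deletion locus (half are
#'   planted LD companions, the rest unlinked noise).
#' @param populations Named diploid sample sizes.
#' @param archaic_genomes Names of the four archaic genomes.
#' @param mean_depth Archaic sequencing depth (reads covering a bp).
#' @param window_size_range Deletion length range, bp (log-uniform draw).
#' @param ld_target_r2 Minimum haplotypic r-squared planted between a
#'   deletion and its companions.
#' @param flip_rate Per-haplotype flip probability used to decay planted
#'   LD away from r-squared = 1.
#' @param read_length Archaic read length, bp.
#' @param residual_depth_fraction Residual depth over deleted windows as a
#'   fraction of `mean_depth` (0 = homozygous deletion, no reads).
#' @param p_exonic,p_gwas Probability that a deletion is planted as
#'   exonic / GWAS-associated.
#' @param functional_ancient_fold Multiplier on those probabilities for
#'   ancient deletions (1 = no planted enrichment).
#' @param seed Root seed; every generator draws from a named substream.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_deletions = 200,
                         category_mix = c(human_specific = 0.882,
                                          recurrent = 0.011,
                                          introgressed = 0.019,
                                          ancient = 0.088),
                         n_snvs_per_locus = 8,
                         populations = c(YRI = 108, CEU = 103, CHB = 99),
                         archaic_genomes = c("vindija", "chagyrskaya",
                                             "altai", "denisovan"),
                         mean_depth = 30,
                         window_size_range = c(500, 10000),
                         ld_target_r2 = 0.9,
                         flip_rate = 0.01,
                         read_length = 100,
                         residual_depth_fraction = 0,
                         p_exonic = 0.10,
                         p_gwas = 0.15,
                         functional_ancient_fold = 1,
                         seed = 1L) {
  cats <- c("human_specific", "recurrent", "introgressed", "ancient")
  if (!setequal(names(category_mix), cats))
    stop("category_mix must name exactly: ", paste(cats, collapse = ", "))
  category_mix <- category_mix[cats]
  if (abs(sum(category_mix) - 1) > 1e-8) stop("category_mix must sum to 1")
  if (any(category_mix < 0)) stop("category_mix proportions must be >= 0")
  stopifnot_scalar(n_deletions, "n_deletions")
  stopifnot_scalar(n_snvs_per_locus, "n_snvs_per_locus")
  stopifnot_scalar(mean_depth, "mean_depth")
  if (any(populations <= 0)) stop("population sizes must be positive")
  if (length(archaic_genomes) != 4L) stop("expected four archaic genomes")
  if (ld_target_r2 < 0 || ld_target_r2 >= 1)
    stop("ld_target_r2 must be in [0, 1)")
  structure(list(n_deletions = as.integer(n_deletions),
                 category_mix = category_mix,
                 n_snvs_per_locus = as.integer(n_snvs_per_locus),
                 populations = populations,
                 archaic_genomes = archaic_genomes,
                 mean_depth = mean_depth,
                 window_size_range = window_size_range,
                 ld_target_r2 = ld_target_r2,
                 flip_rate = flip_rate,
                 read_length = as.integer(read_length),
                 residual_depth_fraction = residual_depth_fraction,
                 p_exonic = p_exonic, p_gwas = p_gwas,
                 functional_ancient_fold = functional_ancient_fold,
                 seed = as.integer(seed)),
            class = "synth_config")
}

LOCUS_BP <- 150000L  # each deletion sits on its own synthetic contig

# Draw carrier indicators at frequency f until the pooled minor allele
# count exceeds 1 (singletons would be invisible to the LD machinery).
draw_carriers <- function(n_hap, f) {
  for (i in 1:50) {
    x <- rbinom(n_hap, 1L, f)
    if (sum(x) >= 2L && sum(1L - x) >= 2L) return(x)
  }
  stop("could not draw a mac>1 carrier configuration at frequency ", f)
}

# Copy the deletion haplotype onto a companion SNV, decaying LD with a
# per-haplotype flip, and insist on the planted r-squared target.
plant_companion <- function(del_hap, flip_rate, target_r2, locus_id) {
  rate <- flip_rate
  for (attempt in 1:80) {
    flip <- runif(length(del_hap)) < rate
    snv <- ifelse(flip, 1L - del_hap, del_hap)
    r2 <- haplotype_r2(del_hap, snv)
    if (!is.na(r2) && r2 > target_r2 && sum(snv) >= 2L &&
        sum(1L - snv) >= 2L) return(snv)
    if (attempt %% 10 == 0) rate <- rate / 2
  }
  stop(sprintf("unsatisfiable LD target %.3f at locus %s for this sample size",
               target_r2, locus_id))
}

#' Generate a synthetic phased cohort with planted truth
#'
#' Builds phased haplotypes for three AMH populations plus 2 haploids per
#' archaic genome.  Every deletion receives planted LD companions within
#' 50 kb.  Planted categories are realized generatively: ancient deletions
#' put deletion and companion derived alleles on at least one archaic
#' genome; recurrent deletions put the deletion on an archaic genome with
#' no companion derived allele anywhere in the archaics; introgressed
#' deletions have zero YRI copies, an accompanied archaic carrier, and
#' their companions appear in the emitted S* (introgressed-SNV) list.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_cohort`: `variants` (a [variant_matrix()]
#'   over AMH and archaic haplotypes; columns are deletions then SNVs),
#'   `sites` (per-column metadata), `deletions` (interval table), `truth`
#'   (planted category, carriers, companions, functional flags) and
#'   `sstar_snvs`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(substream_seed(config$seed, "cohort"), {
    pops <- config$populations
    n_amh <- sum(pops) * 2L
    amh_pop <- rep(names(pops), times = pops * 2L)
    genomes <- config$archaic_genomes
    n_arch <- 2L * length(genomes)
    arch_pop <- rep(genomes, each = 2L)
    pop <- c(amh_pop, arch_pop)
    n_hap <- n_amh + n_arch
    yri_idx <- which(pop == "YRI")

    cats <- names(config$category_mix)
    category <- sample(cats, config$n_deletions, replace = TRUE,
                       prob = config$category_mix)

    n_del <- config$n_deletions
    n_snv <- config$n_snvs_per_locus
    n_comp <- max(1L, n_snv %/% 2L)
    site_cols <- list(); site_meta <- list()
    deletions <- vector("list", n_del)
    truth <- vector("list", n_del)
    sstar <- character(0)

    wr <- config$window_size_range
    for (i in seq_len(n_del)) {
      id <- sprintf("del_%03d", i)
      chrom <- sprintf("locus_%03d", i)
      len <- round(exp(runif(1, log(wr[1]), log(wr[2]))))
      start <- as.integer(LOCUS_BP / 2 - len %/% 2)
      end <- as.integer(start + len)
      cat_i <- category[i]

      # AMH deletion haplotypes
      del_hap <- integer(n_hap)
      if (cat_i == "introgressed") {
        f <- runif(1, 0.05, 0.3)
        non_yri <- setdiff(seq_len(n_amh), yri_idx)
        del_hap[non_yri] <- draw_carriers(length(non_yri), f)
      } else {
        f <- switch(cat_i,
                    ancient = runif(1, 0.15, 0.6),
                    recurrent = runif(1, 0.05, 0.4),
                    human_specific = runif(1, 0.03, 0.35))
        del_hap[seq_len(n_amh)] <- draw_carriers(n_amh, f)
      }

      # archaic deletion carriers (both haploids: the caller sees presence)
      carrier_genomes <- character(0)
      if (cat_i %in% c("ancient", "recurrent", "introgressed")) {
        k <- sample(1:3, 1)
        carrier_genomes <- sample(genomes, k)
        for (g in carrier_genomes)
          del_hap[n_amh + which(arch_pop == g)] <- 1L
      }

      # companion SNVs: tight LD in AMHs; archaic state set per category
      comp_ids <- sprintf("snv_%03d_c%d", i, seq_len(n_comp))
      flank <- 45000
      comp_pos <- as.integer(sample(c(
        seq(max(0, start - flank), start - 1),
        seq(end, min(LOCUS_BP - 1, end + flank))), n_comp))
      for (k in seq_len(n_comp)) {
        snv <- integer(n_hap)
        snv[seq_len(n_amh)] <-
          plant_companion(del_hap[seq_len(n_amh)], config$flip_rate,
                          config$ld_target_r2, id)
        if (cat_i %in% c("ancient", "introgressed")) {
          # identical by descent: companions ride along on the carriers
          for (g in carrier_genomes)
            snv[n_amh + which(arch_pop == g)] <- 1L
        }
        # recurrent and human_specific: companions absent from archaics
        site_cols[[length(site_cols) + 1L]] <- snv
        site_meta[[length(site_meta) + 1L]] <-
          data.frame(id = comp_ids[k], chrom = chrom, pos = comp_pos[k],
                     type = "snv", locus = id, companion = TRUE,
                     stringsAsFactors = FALSE)
      }
      if (cat_i == "introgressed") sstar <- c(sstar, comp_ids)

      # unlinked noise SNVs, some beyond the 50 kb search radius
      n_noise <- n_snv - n_comp
      if (n_noise > 0) {
        noise_pos <- as.integer(runif(n_noise, 0, LOCUS_BP))
        for (k in seq_len(n_noise)) {
          snv <- integer(n_hap)
          snv[seq_len(n_amh)] <- draw_carriers(n_amh, runif(1, 0.05, 0.9))
          snv[n_amh + seq_len(n_arch)] <- rbinom(n_arch, 1L, 0.2)
          site_cols[[length(site_cols) + 1L]] <- snv
          site_meta[[length(site_meta) + 1L]] <-
            data.frame(id = sprintf("snv_%03d_n%d", i, k), chrom = chrom,
                       pos = noise_pos[k], type = "snv", locus = id,
                       companion = FALSE, stringsAsFactors = FALSE)
        }
      }

      # functional flags
      fold <- if (cat_i == "ancient") config$functional_ancient_fold else 1
      exonic <- runif(1) < min(1, config$p_exonic * fold)
      gwas <- runif(1) < min(1, config$p_gwas * fold)

      deletions[[i]] <- data.frame(id = id, chrom = chrom, start = start,
                                   end = end, length = len,
                                   stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        id = id, category = cat_i,
        archaic_carriers = paste(sort(carrier_genomes), collapse = ","),
        companions = paste(comp_ids, collapse = ","),
        exonic = exonic, gwas = gwas, length = len,
        stringsAsFactors = FALSE)

      site_cols[[length(site_cols) + 1L]] <- del_hap
      site_meta[[length(site_meta) + 1L]] <-
        data.frame(id = id, chrom = chrom, pos = start, type = "del",
                   locus = id, companion = FALSE, stringsAsFactors = FALSE)
    }

    sites <- do.call(rbind, site_meta)
    mat <- do.call(cbind, site_cols)
    colnames(mat) <- sites$id
    ord <- order(sites$type == "snv", sites$chrom, sites$pos)  # dels first
    sites <- sites[ord, ]
    mat <- mat[, ord, drop = FALSE]
    vm <- variant_matrix(mat, pop, positions = sites$pos)

    structure(list(variants = vm, sites = sites,
                   deletions = do.call(rbind, deletions),
                   truth = do.call(rbind, truth),
                   sstar_snvs = unique(sstar),
                   config = config),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d deletions, %d SNVs, %d haplotypes\n",
              nrow(x$deletions), sum(x$sites$type == "snv"),
              nrow(x$variants$mat)))
  print(table(x$truth$category))
  invisible(x)
}

#' Companion tables and archaic SNV presence for a synthetic cohort
#'
#' Convenience bridge from a [generate_cohort()] object to the inputs of
#' [classify_all()]: runs [find_companions()] for every deletion on the
#' pooled AMH haplotypes and extracts the genome-level SNV presence matrix.
#'
#' @param cohort A `synth_cohort`.
#' @param radius,r2_min Passed to [find_companions()].
#' @return List with `companions_list`, `archaic_snv_presence`,
#'   `yri_allele_counts`.
#' @export
cohort_ld_inputs <- function(cohort, radius = 50000, r2_min = 0.9) {
  vm <- cohort$variants
  amh <- vm$pop %in% c("YRI", "CEU", "CHB")
  snv_sel <- cohort$sites$type == "snv"
  snv_mat <- vm$mat[amh, snv_sel, drop = FALSE]
  snv_sites <- cohort$sites[snv_sel, ]
  yri <- vm$pop == "YRI"
  genomes <- cohort$config$archaic_genomes
  arch_pres <- t(vapply(genomes, function(g) {
    colSums(vm$mat[vm$pop == g, snv_sel, drop = FALSE]) > 0
  }, logical(sum(snv_sel))))
  colnames(arch_pres) <- snv_sites$id

  companions_list <- list()
  yri_counts <- integer(0)
  for (i in seq_len(nrow(cohort$deletions))) {
    d <- cohort$deletions[i, ]
    on_locus <- snv_sites$chrom == d$chrom
    companions_list[[d$id]] <- find_companions(
      vm$mat[amh, cohort$sites$id == d$id], d$start, d$end,
      snv_mat[, on_locus, drop = FALSE], snv_sites$pos[on_locus],
      snv_sites$id[on_locus], radius = radius, r2_min = r2_min)
    yri_counts[d$id] <- sum(vm$mat[yri, cohort$sites$id == d$id])
  }
  list(companions_list = companions_list,
       archaic_snv_presence = arch_pres,
       yri_allele_counts = yri_counts)
}
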