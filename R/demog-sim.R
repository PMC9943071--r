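#' Haplotype-by-site variant matrix
#'
#' Container for phased binary haplotypes (1 = derived allele) with a
#' population label and a sampling time per haplotype.  Sites are columns;
#' each column is one independent, freely recombining variant.
#'
#' @param mat Binary matrix, haplotypes in rows, sites in columns.
#' @param pop Character vector of population labels, one per haplotype
#'   (archaic haplotypes use the genome name, e.g. `"altai"`).
#' @param sample_time Sampling time in years before present per haplotype.
#' @param positions Optional site positions (bp) for cohort-style matrices.
#' @return An object of class `variant_matrix`.
#' @export
variant_matrix <- function(mat, pop, sample_time = rep(0, nrow(mat)),
                           positions = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  stopifnot(nrow(mat) == length(pop), nrow(mat) == length(sample_time))
  if (!all(mat %in% c(0L, 1L))) stop("variant matrix must be binary")
  structure(list(mat = mat, pop = as.character(pop),
                 sample_time = as.numeric(sample_time),
                 positions = positions),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("<variant_matrix> %d haplotypes x %d sites\n",
              nrow(x$mat), ncol(x$mat)))
  cat("  populations:",
      paste(sprintf("%s=%d", names(table(x$pop)), table(x$pop)),
            collapse = ", "), "\n")
  invisible(x)
}

# One engine run; returns the raw C++ result.
run_engine <- function(model, n_loci, seed, n_yri = 216,
                       query_times_years = numeric(), return_matrix = FALSE,
                       archaic_haploids = 2L) {
  a <- engine_args(model, n_yri = n_yri, archaic_haploids = archaic_haploids)
  base <- if (inherits(model, "structured_ancestry_model")) model$base else model
  qt <- query_times_years / base$generation_time
  with_seed(seed, {
    cpp_sim_loci(a$tip_pop, a$tip_time, a$pop_sizes, a$ev_time, a$ev_src,
                 a$ev_dst, a$mig_time, a$mig_demes, a$mig_rate,
                 as.integer(n_loci), qt, return_matrix, a$tip_group,
                 a$n_groups)
  })
}

#' Simulate unlinked variants under a demographic model
#'
#' Simulates one genealogy per locus for 216 YRI haploid genomes (by
#' default) plus 2 haploid genomes per archaic hominin, places a single
#' mutation on each genealogy with probability proportional to branch
#' length, and records the derived state of every haplotype.
#'
#' @param model A [demographic_model()] or [structured_ancestry_model()].
#' @param n_loci Number of independent variants.
#' @param seed Integer seed.
#' @param n_yri Number of YRI haploid genomes.
#' @return A [variant_matrix()] whose archaic haplotypes are labelled by
#'   genome name.
#' @export
simulate_variant_matrix <- function(model, n_loci, seed, n_yri = 216) {
  if (n_loci < 1) stop("'n_loci' must be at least 1")
  base <- if (inherits(model, "structured_ancestry_model")) model$base else model
  res <- run_engine(model, n_loci, seed, n_yri = n_yri, return_matrix = TRUE)
  mat <- t(res$derived)          # engine returns loci x haplotypes
  storage.mode(mat) <- "integer"
  pop <- c(rep("YRI", n_yri), rep(ARCHAIC_GENOMES, each = 2L))
  st <- c(rep(0, n_yri),
          rep(unname(base$archaic_sampling_times[ARCHAIC_GENOMES]), each = 2L))
  variant_matrix(mat, pop, st)
}

# Shared-proportion bookkeeping from per-locus YRI derived counts and an
# any-archaic-derived indicator.  The denominator is YRI polymorphism with
# minor allele count > 1: both the derived and the ancestral allele must
# have at least 2 copies in the YRI sample.
sharing_from_counts <- function(yri_derived, archaic_any, n_yri,
                                n_bins = 10L) {
  in_denom <- yri_derived >= 2L & (n_yri - yri_derived) >= 2L
  denominator <- sum(in_denom)
  numerator <- sum(in_denom & archaic_any)
  freq <- yri_derived[in_denom] / n_yri
  shared <- archaic_any[in_denom]
  bin <- pmin(ceiling(freq * n_bins), n_bins)   # partition of (0, 1]
  n_bin <- tabulate(bin, nbins = n_bins)
  n_shared_bin <- vapply(seq_len(n_bins),
                         function(b) sum(shared[bin == b]), integer(1))
  bins <- data.frame(bin = seq_len(n_bins),
                     lower = (seq_len(n_bins) - 1) / n_bins,
                     upper = seq_len(n_bins) / n_bins,
                     n = n_bin, n_shared = n_shared_bin,
                     proportion = ifelse(n_bin > 0, n_shared_bin / n_bin, NA_real_))
  structure(list(denominator = denominator, numerator = numerator,
                 proportion = if (denominator > 0) numerator / denominator else NA_real_,
                 empty = denominator == 0L, bins = bins, n_yri = n_yri),
            class = "sharing_result")
}

#' @export
print.sharing_result <- function(x, ...) {
  if (x$empty) {
    cat("<sharing_result> empty: no YRI mac>1 variants\n")
  } else {
    cat(sprintf("<sharing_result> %d / %d = %.4f shared with archaic genomes\n",
                x$numerator, x$denominator, x$proportion))
  }
  invisible(x)
}

#' Proportion of variants shared with archaic genomes
#'
#' Among variants polymorphic in YRI with minor allele count > 1, the
#' proportion whose derived allele is carried by at least one archaic
#' haploid genome.  These are the candidate ancient polymorphisms: under
#' common descent a shared derived allele predates the AMH-archaic split.
#'
#' @param matrix A [variant_matrix()] with `"YRI"`-labelled haplotypes and
#'   archaic haplotypes labelled by genome name.
#' @param n_bins Number of uniform derived-frequency bins for the per-bin
#'   breakdown.
#' @return A `sharing_result` with fields `denominator`, `numerator`,
#'   `proportion`, `empty` and a per-bin data.frame `bins`.  When no YRI
#'   variant passes the mac filter, `empty` is `TRUE` and `proportion` is
#'   `NA` (no division by zero is attempted).
#' @export
sharing_proportion <- function(matrix, n_bins = 10L) {
  stopifnot(inherits(matrix, "variant_matrix"))
  yri <- matrix$pop == "YRI"
  arch <- matrix$pop %in% ARCHAIC_GENOMES
  if (!any(yri) || !any(arch))
    stop("variant matrix must carry YRI and archaic haplotypes")
  yri_derived <- colSums(matrix$mat[yri, , drop = FALSE])
  archaic_any <- colSums(matrix$mat[arch, , drop = FALSE]) > 0L
  sharing_from_counts(yri_derived, archaic_any, sum(yri), n_bins)
}

#' Distribution of the sharing proportion over simulation replicates
#'
#' @inheritParams simulate_variant_matrix
#' @param n_reps Number of independent replicates.
#' @param n_loci Unlinked variants per replicate.
#' @return Numeric vector of per-replicate sharing proportions.
#' @export
sharing_distribution <- function(model, n_reps, n_loci, seed, n_yri = 216) {
  if (n_reps < 1) stop("'n_reps' must be at least 1")
  vapply(seq_len(n_reps), function(r) {
    res <- run_engine(model, n_loci, substream_seed(seed, "sharing_rep", r),
                      n_yri = n_yri)
    gc <- res$group_counts
    sharing_from_counts(gc[, 1L], rowSums(gc[, -1L, drop = FALSE]) > 0L,
                        n_yri)$proportion
  }, numeric(1))
}

#' Sharing proportion under ancestral population structure
#'
#' @param model A [structured_ancestry_model()].
#' @inheritParams sharing_distribution
#' @return A `sharing_result`.
#' @export
simulate_structured_ancestry <- function(model, n_loci, seed, n_yri = 216) {
  stopifnot(inherits(model, "structured_ancestry_model"))
  res <- run_engine(model, n_loci, seed, n_yri = n_yri)
  gc <- res$group_counts
  sharing_from_counts(gc[, 1L], rowSums(gc[, -1L, drop = FALSE]) > 0L, n_yri)
}

#' Scan the ancestral migration rate for the critical sharing level
#'
#' Simulates the structured-ancestry model across a grid of symmetric
#' migration fractions and reports the largest grid value whose simulated
#' sharing proportion still reaches `target_proportion`.  Sharing decays
#' toward the panmictic value as migration grows, so this is the threshold
#' below which ancestral structure alone can explain an observed sharing
#' level.
#'
#' @param model_template A [structured_ancestry_model()] whose `m` is
#'   overridden at each grid point (any `m` accepted by the constructor
#'   works as placeholder).
#' @param m_grid Ascending vector of per-generation migrant fractions.
#' @param n_loci_per_point Unlinked variants per grid point.
#' @param target_proportion Sharing proportion to reach (e.g. 0.137).
#' @param seed Integer seed.
#' @return List with `critical_m` (`NA` and status `"none-reached"` when no
#'   grid point reaches the target) and the full `(m, proportion)` `table`.
#' @export
scan_migration <- function(model_template, m_grid, n_loci_per_point,
                           target_proportion, seed) {
  stopifnot(inherits(model_template, "structured_ancestry_model"))
  if (is.unsorted(m_grid, strictly = TRUE))
    stop("'m_grid' must be sorted ascending")
  props <- vapply(seq_along(m_grid), function(i) {
    mod <- structured_ancestry_model(
      base = model_template$base, n_subgroups = model_template$n_subgroups,
      subgroup_ne = model_template$subgroup_ne, m = m_grid[i],
      amh_source_deme = model_template$amh_source_deme,
      archaic_source_deme = model_template$archaic_source_deme,
      scatter_amh = model_template$scatter_amh)
    simulate_structured_ancestry(mod, n_loci_per_point,
                                 substream_seed(seed, "mig_scan", i))$proportion
  }, numeric(1))
  tab <- data.frame(m = m_grid, proportion = props)
  hit <- which(!is.na(props) & props >= target_proportion)
  if (length(hit) == 0L) {
    list(critical_m = NA_real_, status = "none-reached", table = tab)
  } else {
    list(critical_m = m_grid[max(hit)], status = "reached", table = tab)
  }
}

#' Crossing point of the migration-sharing curve
#'
#' The sharing proportion decays monotonically in `m`, but the raw
#' "largest grid point at or above the target" readout of
#' [scan_migration()] is noisy where the curve is flat.  This summary
#' fits a monotone (isotonic, non-increasing) curve to the scan table and
#' interpolates, on the log-`m` scale, the largest `m` at which the
#' fitted sharing still reaches the target.
#'
#' @param scan_table The `table` component of a [scan_migration()] result.
#' @param target_proportion Sharing proportion to reach.
#' @return The crossing `m` (largest migrant fraction whose fitted
#'   proportion is at least the target); `NA` if the fitted curve never
#'   reaches it; the largest grid `m` if even the panmictic end exceeds
#'   it.
#' @export
migration_crossing <- function(scan_table, target_proportion) {
  ok <- !is.na(scan_table$proportion)
  x <- log10(scan_table$m[ok])
  y <- scan_table$proportion[ok]
  fit <- -stats::isoreg(x, -y)$yf          # non-increasing in m
  if (fit[1] < target_proportion) return(NA_real_)
  if (fit[length(fit)] >= target_proportion)
    return(scan_table$m[ok][length(fit)])
  i <- max(which(fit >= target_proportion))
  # linear interpolation in (log10 m, proportion) to the crossing
  frac <- (fit[i] - target_proportion) / (fit[i] - fit[i + 1])
  10^(x[i] + frac * (x[i + 1] - x[i]))
}

#' Sharing proportion by derived-allele frequency bin
#'
#' @inheritParams sharing_proportion
#' @return The `bins` data.frame of [sharing_proportion()]: per bin of YRI
#'   derived frequency (uniform partition of (0, 1]), the number of
#'   YRI mac>1 variants, the number shared with archaics, and the shared
#'   proportion (`NA`, not 0, for empty bins).
#' @export
binned_sharing <- function(matrix, n_bins = 10L) {
  sharing_proportion(matrix, n_bins = n_bins)$bins
}

# Derived-allele-count spectrum on the YRI sample (counts 1 .. n_yri - 1).
yri_sfs <- function(x) {
  if (inherits(x, "variant_matrix")) {
    yri <- x$pop == "YRI"
    d <- colSums(x$mat[yri, , drop = FALSE])
    n <- sum(yri)
    tabulate(d[d >= 1 & d <= n - 1], nbins = n - 1)
  } else {
    as.numeric(x)
  }
}

#' Compare site-frequency spectra by chi-square goodness of fit
#'
#' Summarizes both inputs to derived-allele-count spectra on the YRI sample
#' and tests the observed spectrum against the simulated-expected one.
#' Cells are pooled left to right until each pooled cell has expected count
#' at least 5 before the statistic is formed.
#'
#' @param simulated A [variant_matrix()] or a numeric spectrum (counts by
#'   derived allele count `1 .. n-1`) giving the expected shape.
#' @param observed A [variant_matrix()] or numeric spectrum on the same
#'   sample size.
#' @return List with `statistic`, `df`, `p`, and the pooled observed and
#'   expected counts.
#' @export
sfs_compare <- function(simulated, observed) {
  sim <- yri_sfs(simulated)
  obs <- yri_sfs(observed)
  if (length(sim) != length(obs))
    stop("spectra have mismatched sample sizes")
  expected <- sim / sum(sim) * sum(obs)
  # pool adjacent cells until expected >= 5
  pooled_o <- numeric(0); pooled_e <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expected[i]
    if (ce >= 5) {
      pooled_o <- c(pooled_o, co); pooled_e <- c(pooled_e, ce)
      co <- 0; ce <- 0
    }
  }
  if (ce > 0) {  # fold the remainder into the last cell
    if (length(pooled_e) == 0L) stop("too few variants to form any cell")
    pooled_o[length(pooled_o)] <- pooled_o[length(pooled_o)] + co
    pooled_e[length(pooled_e)] <- pooled_e[length(pooled_e)] + ce
  }
  stat <- sum((pooled_o - pooled_e)^2 / pooled_e)
  df <- length(pooled_e) - 1L
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p,
       observed = pooled_o, expected = pooled_e)
}
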