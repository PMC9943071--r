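#' Allele-frequency stability statistic and deletion-level annotation
#'
#' A variant under balancing selection is expected to hold a near-constant
#' frequency over time.  From genealogical lineage counts, the frequency
#' at a past time t is estimated as the ratio of lineages carrying the
#' derived allele to all lineages remaining at t.  The squared
#' standardized change between 50,000 and 5,000 years before present is
#' approximately chi-squared with one degree of freedom under neutrality;
#' unusually small values flag stable (potentially balanced) trajectories.
#'
#' @name traj_stats
NULL

#' Chi-squared frequency-stability statistic
#'
#' For each variant, computes the lineage-based frequency change
#' `delta = f(t_recent) - f(t_old)` (grid time nearest each target),
#' retains variants whose remaining lineage count at `t_old` exceeds
#' `min_lineage_frac` of the present-day sample size, standardizes
#' `delta` within strata of present-day derived frequency, and squares
#' the result.
#'
#' @param trajectories Long data.frame with columns `variant`,
#'   `time_years`, `derived_lineages`, `total_lineages`, `n_present`,
#'   `present_freq` (see [simulate_neutral_trajectories()]).
#' @param t_recent,t_old Target times, years before present.
#' @param min_lineage_frac Inclusion filter: remaining lineages at
#'   `t_old` must exceed this fraction of the present-day sample size.
#' @param n_strata Number of present-day-frequency strata (quantile
#'   bins).
#' @return data.frame per variant: `variant`, `present_freq`, `delta`,
#'   `z`, `chi2`, `included`, `stratum`.  Variants failing the lineage
#'   filter carry `included = FALSE` and no chi2; strata with fewer than
#'   two members are flagged unstandardizable (`z = NA`).  A stratum with
#'   zero spread gives `z = 0` for all its members.
#' @export
chi2_stability <- function(trajectories, t_recent = 5000, t_old = 50000,
                           min_lineage_frac = 0.10, n_strata = 10) {
  need <- c("variant", "time_years", "derived_lineages", "total_lineages",
            "n_present", "present_freq")
  stopifnot(all(need %in% names(trajectories)))
  grid <- sort(unique(trajectories$time_years))
  tr <- grid[which.min(abs(grid - t_recent))]
  to <- grid[which.min(abs(grid - t_old))]
  at <- function(tt, col) {
    sub <- trajectories[trajectories$time_years == tt, ]
    sub[[col]][match(vars, sub$variant)]
  }
  vars <- unique(trajectories$variant)
  tot_old <- at(to, "total_lineages")
  f_old <- at(to, "derived_lineages") / tot_old
  f_rec <- at(tr, "derived_lineages") / at(tr, "total_lineages")
  n_present <- at(to, "n_present")
  pf <- at(to, "present_freq")

  included <- tot_old > min_lineage_frac * n_present
  delta <- f_rec - f_old
  out <- data.frame(variant = vars, present_freq = pf, delta = delta,
                    z = NA_real_, chi2 = NA_real_, included = included,
                    stratum = NA_integer_, stringsAsFactors = FALSE)

  idx <- which(included)
  if (length(idx)) {
    br <- unique(quantile(pf[idx], probs = seq(0, 1, length.out = n_strata + 1)))
    strat <- if (length(br) < 2L) rep(1L, length(idx)) else
      cut(pf[idx], breaks = br, include.lowest = TRUE, labels = FALSE)
    out$stratum[idx] <- strat
    for (s in unique(strat)) {
      m <- idx[strat == s]
      if (length(m) < 2L) next  # unstandardizable: z stays NA
      mu <- mean(delta[m]); sdv <- sd(delta[m])
      out$z[m] <- if (sdv == 0) 0 else (delta[m] - mu) / sdv
    }
    out$chi2 <- out$z^2
  }
  out
}

#' Deletion age from the highest companion age estimate
#'
#' Assigns each deletion the maximum of the (joint-clock median) age
#' estimates available for its LD companions; the maximum is used because
#' a tagging SNV can be younger, but not older, than the haplotype
#' structure it tags.
#'
#' @param companions Companion data.frame (needs `snv_id`).
#' @param age_table data.frame `snv_id`, `age_years`.
#' @return Age in years, or `NA` when no companion has an age row.
#' @export
assign_age_hgd <- function(companions, age_table) {
  ages <- age_table$age_years[match(companions$snv_id, age_table$snv_id)]
  ages <- ages[!is.na(ages)]
  if (!length(ages)) return(NA_real_)
  max(ages)
}

#' Deletion age as the mean over tightly tagging companions
#'
#' @param companions Companion data.frame (`snv_id`, `r2`).
#' @param age_table data.frame `snv_id`, `age_years`.
#' @param r2_min Only companions tagging at r-squared above this enter
#'   the mean.
#' @return Mean age in years, or `NA`.
#' @export
assign_age_mean <- function(companions, age_table, r2_min = 0.9) {
  keep <- companions$r2 > r2_min
  ages <- age_table$age_years[match(companions$snv_id[keep],
                                    age_table$snv_id)]
  ages <- ages[!is.na(ages)]
  if (!length(ages)) return(NA_real_)
  mean(ages)
}

#' Deletion-level balancing-selection score from companion SNVs
#'
#' `BETAMAX` takes the highest stdb2 among scored companions.
#' `BETAPRIME` restricts to the companions attaining the maximal
#' r-squared with the deletion and takes the score of the one nearest the
#' deletion (distance ties broken by lower position).
#'
#' @param companions Companion data.frame (`snv_id`, `r2`, `distance`,
#'   `position`).
#' @param score_table data.frame `snv_id`, `stdbeta2` (pre-filtered to
#'   one population).
#' @param mode `"BETAMAX"` or `"BETAPRIME"`.
#' @return The assigned score, or `NA` when no companion is scored.
#' @export
assign_beta <- function(companions, score_table,
                        mode = c("BETAMAX", "BETAPRIME")) {
  mode <- match.arg(mode)
  sc <- score_table$stdbeta2[match(companions$snv_id, score_table$snv_id)]
  ok <- !is.na(sc)
  if (!any(ok)) return(NA_real_)
  comp <- companions[ok, , drop = FALSE]
  sc <- sc[ok]
  if (mode == "BETAMAX") return(max(sc))
  top <- comp$r2 == max(comp$r2)
  comp <- comp[top, , drop = FALSE]
  sc <- sc[top]
  pick <- order(comp$distance, comp$position)[1]
  sc[pick]
}

#' Rank-sum comparison of a statistic between two deletion sets
#'
#' Two-sided Wilcoxon rank-sum test used to compare chi2 stability
#' values or stdb2 scores between e.g. ancient and non-ancient deletions.
#'
#' @param values Numeric vector.
#' @param labels Logical or two-level factor splitting `values`.
#' @return List with `p`, `statistic` and the two group medians.
#' @export
group_rank_test <- function(values, labels) {
  labels <- as.logical(labels)
  a <- values[labels & !is.na(values)]
  b <- values[!labels & !is.na(values)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  w <- wilcox.test(a, b, exact = FALSE)
  list(p = w$p.value, statistic = unname(w$statistic),
       median_in = median(a), median_out = median(b))
}
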