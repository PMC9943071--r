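#' Demographic model for archaic allele-sharing simulations
#'
#' Describes the joint demography of anatomically modern humans (AMH,
#' represented by the Yoruba sample) and the four high-coverage archaic
#' hominin genomes: the Vindija, Chagyrskaya and Altai Neanderthals and the
#' Denisovan.  Backward in time the two Neanderthal sister lineages merge
#' first, then Altai joins, then the Denisovan, and finally the archaic stem
#' merges with the AMH lineage at the AMH-archaic divergence time.
#'
#' @param amh_ne Diploid effective size of the AMH lineage.  Either a single
#'   number (constant size) or a two-column data.frame with columns
#'   `time_bp` (years before present, ascending, starting at 0) and `size`
#'   for a piecewise-constant trajectory.
#' @param archaic_ne Constant diploid size of every archaic branch.
#' @param t_split_amh_archaic AMH-archaic divergence time, years.
#' @param t_split_denisovan Denisovan-Neanderthal divergence, years.
#' @param t_split_altai Altai split from the Vindija-Chagyrskaya lineage,
#'   years.
#' @param t_split_vindija_chagyrskaya Vindija-Chagyrskaya split, years.
#' @param generation_time Years per generation.
#' @param archaic_sampling_times Named numeric vector of sampling times
#'   (years before present) for `vindija`, `chagyrskaya`, `altai`,
#'   `denisovan`, or the string `"present"` to sample all four at time 0
#'   (plain-`ms`-style usage).  Each time must predate the relevant split.
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(amh_ne = 14474,
                              archaic_ne = 1000,
                              t_split_amh_archaic = 700000,
                              t_split_denisovan = 400000,
                              t_split_altai = 130000,
                              t_split_vindija_chagyrskaya = 90000,
                              generation_time = 29,
                              archaic_sampling_times = c(vindija = 50000,
                                                         chagyrskaya = 80000,
                                                         altai = 120000,
                                                         denisovan = 70000)) {
  if (is.data.frame(amh_ne)) {
    if (!all(c("time_bp", "size") %in% names(amh_ne)) ||
        nrow(amh_ne) < 1L || amh_ne$time_bp[1] != 0 ||
        is.unsorted(amh_ne$time_bp, strictly = TRUE) || any(amh_ne$size <= 0))
      stop("piecewise 'amh_ne' needs ascending time_bp starting at 0 and positive sizes")
  } else {
    stopifnot_scalar(amh_ne, "amh_ne")
  }
  stopifnot_scalar(archaic_ne, "archaic_ne")
  stopifnot_scalar(generation_time, "generation_time")
  if (!(0 < t_split_vindija_chagyrskaya &&
        t_split_vindija_chagyrskaya < t_split_altai &&
        t_split_altai < t_split_denisovan &&
        t_split_denisovan < t_split_amh_archaic))
    stop("split times must satisfy 0 < vindija-chagyrskaya < altai < denisovan < amh-archaic")
  genomes <- c("vindija", "chagyrskaya", "altai", "denisovan")
  if (identical(archaic_sampling_times, "present"))
    archaic_sampling_times <- setNames(rep(0, 4), genomes)
  if (!all(genomes %in% names(archaic_sampling_times)))
    stop("archaic_sampling_times must name all four genomes")
  st <- archaic_sampling_times[genomes]
  lim <- c(t_split_vindija_chagyrskaya, t_split_vindija_chagyrskaya,
           t_split_altai, t_split_denisovan)
  if (any(st < 0) || any(st >= lim))
    stop("each archaic sampling time must be non-negative and predate its lineage's split")
  structure(list(amh_ne = amh_ne, archaic_ne = archaic_ne,
                 t_split_amh_archaic = t_split_amh_archaic,
                 t_split_denisovan = t_split_denisovan,
                 t_split_altai = t_split_altai,
                 t_split_vindija_chagyrskaya = t_split_vindija_chagyrskaya,
                 generation_time = generation_time,
                 archaic_sampling_times = st),
            class = "demographic_model")
}

#' Structured-ancestry model
#'
#' Extends a constant-size [demographic_model()] by splitting the population
#' ancestral to AMHs and archaic hominins into island-model subgroups that
#' exchange a symmetric per-generation migrant fraction `m` between every
#' pair.  Backward in time, at the AMH-archaic divergence the AMH ancestral
#' lineages enter `amh_source_deme` and the archaic ancestral lineages enter
#' `archaic_source_deme`; remaining demes are unsampled.
#'
#' @param base A [demographic_model()] with constant AMH size.
#' @param n_subgroups Number of ancestral demes.
#' @param subgroup_ne Diploid size of each deme.
#' @param m Per-generation migrant fraction between each ordered pair of
#'   demes (so `M = 4 * subgroup_ne * m` in `ms` units).
#' @param amh_source_deme,archaic_source_deme 1-based deme indices.  When
#'   `scatter_amh = TRUE` (the default) `amh_source_deme` is ignored: each
#'   AMH ancestral lineage enters a uniformly random deme at the split,
#'   which is what makes low migration inflate both archaic sharing and the
#'   intermediate-frequency part of the site frequency spectrum.
#' @param scatter_amh Scatter AMH ancestral lineages across all demes
#'   (default) or place them jointly into `amh_source_deme`.
#' @return An object of class `structured_ancestry_model`.
#' @export
structured_ancestry_model <- function(base = demographic_model(),
                                      n_subgroups = 3,
                                      subgroup_ne = 10000,
                                      m,
                                      amh_source_deme = 1,
                                      archaic_source_deme = 2,
                                      scatter_amh = TRUE) {
  stopifnot(inherits(base, "demographic_model"))
  if (is.data.frame(base$amh_ne))
    stop("the structured-ancestry model requires a constant AMH size")
  stopifnot_scalar(subgroup_ne, "subgroup_ne")
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m >= 1)
    stop("'m' must be a migrant fraction in [0, 1)")
  if (n_subgroups < 2) stop("need at least two ancestral subgroups")
  if (amh_source_deme == archaic_source_deme)
    stop("AMH and archaic source demes must differ")
  if (max(amh_source_deme, archaic_source_deme) > n_subgroups ||
      min(amh_source_deme, archaic_source_deme) < 1)
    stop("source demes out of range")
  if (m == 0)
    warning("m = 0: lineages in distinct demes can never coalesce; ",
            "sharing arises only through within-deme coalescence")
  structure(list(base = base, n_subgroups = n_subgroups,
                 subgroup_ne = subgroup_ne, m = m,
                 M = 4 * subgroup_ne * m,
                 amh_source_deme = amh_source_deme,
                 archaic_source_deme = archaic_source_deme,
                 scatter_amh = isTRUE(scatter_amh)),
            class = "structured_ancestry_model")
}

ARCHAIC_GENOMES <- c("vindija", "chagyrskaya", "altai", "denisovan")

# Translate a model into the argument list of the C++ engine.  Populations
# (0-based): 0 AMH, 1 vindija, 2 chagyrskaya, 3 altai, 4 denisovan; demes of
# the structured phase, if any, follow.  Times in generations.
engine_args <- function(model, n_yri = 216, archaic_haploids = 2L) {
  structured <- inherits(model, "structured_ancestry_model")
  base <- if (structured) model$base else model
  g <- base$generation_time
  yrs <- function(y) y / g

  amh_sched <- if (is.data.frame(base$amh_ne)) {
    cbind(yrs(base$amh_ne$time_bp), base$amh_ne$size)
  } else cbind(0, base$amh_ne)
  arch <- cbind(0, base$archaic_ne)
  pop_sizes <- list(amh_sched, arch, arch, arch, arch)

  ev <- data.frame(time = numeric(), src = integer(), dst = integer())
  add_ev <- function(time, src, dst)
    rbind(ev, data.frame(time = time, src = src, dst = dst))
  ev <- add_ev(yrs(base$t_split_vindija_chagyrskaya), 2L, 1L)
  ev <- add_ev(yrs(base$t_split_altai), 3L, 1L)
  ev <- add_ev(yrs(base$t_split_denisovan), 4L, 1L)

  t_split <- yrs(base$t_split_amh_archaic)
  if (structured) {
    demes <- seq_len(model$n_subgroups) + 4L          # 0-based ids
    for (d in demes) pop_sizes[[d + 1L]] <- cbind(0, model$subgroup_ne)
    amh_dst <- if (model$scatter_amh) -1L else 4L + model$amh_source_deme
    ev <- add_ev(t_split, 0L, amh_dst)
    ev <- add_ev(t_split, 1L, 4L + model$archaic_source_deme)
    mig_time <- t_split
    mig_demes <- demes
    mig_rate <- model$m
  } else {
    ev <- add_ev(t_split, 1L, 0L)
    mig_time <- Inf
    mig_demes <- integer()
    mig_rate <- 0
  }
  ev <- ev[order(ev$time), , drop = FALSE]

  st <- yrs(base$archaic_sampling_times[ARCHAIC_GENOMES])
  nh <- as.integer(archaic_haploids)
  tip_pop <- c(rep(0L, n_yri), rep(1:4, each = nh))
  tip_time <- c(rep(0, n_yri), rep(unname(st), each = nh))
  tip_group <- c(rep(0L, n_yri), rep(1:4, each = nh))

  list(tip_pop = tip_pop, tip_time = tip_time, pop_sizes = pop_sizes,
       ev_time = ev$time, ev_src = ev$src, ev_dst = ev$dst,
       mig_time = mig_time, mig_demes = mig_demes, mig_rate = mig_rate,
       tip_group = tip_group, n_groups = 5L, n_yri = n_yri)
}
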