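#' Overdominance simulators and the classical summary-statistic panel
#'
#' Forward Wright-Fisher trajectories with viability selection, the
#' trajectory-conditioned structured coalescent of the derived and
#' ancestral allelic classes linked by recombination, frequency-band
#' conditioned neutral coalescent samples, and the standard panel of
#' neutrality statistics.  Under overdominance the heterozygote is the
#' fittest genotype and the allele is attracted to the internal
#' equilibrium h / (2h - 1).
#'
#' @name overdom
NULL

#' Genotype fitnesses under the (s, h) parameterization
#'
#' @param s Selection coefficient.
#' @param h Dominance coefficient; `h > 1` (with `s > 0`) gives
#'   overdominance, `h = 0.5` codominance.
#' @return Named vector `(w_aa, w_Aa, w_AA) = (1, 1 + s*h, 1 + s)`.
#' @export
genotype_fitness <- function(s, h) {
  c(w_aa = 1, w_Aa = 1 + s * h, w_AA = 1 + s)
}

#' Simulate an allele-frequency trajectory conditioned on its age
#'
#' Forward Wright-Fisher binomial resampling with viability weights,
#' starting from a single copy, rejected until a run is still segregating
#' `age_gens` generations after the mutation arose (and, optionally, ends
#' inside `freq_range`).  The acceptance rate is reported because neutral
#' segregation over tens of thousands of generations is rare.
#'
#' @param N Diploid population size.
#' @param s,h Selection and dominance coefficients (`s = 0` is neutral).
#' @param age_gens Age of the mutation in generations.
#' @param seed Integer seed.
#' @param freq_range Optional present-day frequency band `c(lo, hi)`.
#' @param max_tries Rejection budget.
#' @return Object of class `wf_trajectory`: `freq` (length
#'   `age_gens + 1`, `freq[1] = 1/(2N)` at origin), `N`, `s`, `h`,
#'   `tries`, `acceptance_rate`.
#' @export
simulate_trajectory <- function(N, s = 0, h = 0.5, age_gens, seed,
                                freq_range = NULL, max_tries = 2e6) {
  if (age_gens < 1) stop("'age_gens' must be at least 1")
  if (N < 50) stop("'N' must be at least 50")
  band <- if (is.null(freq_range)) c(0, 1) else freq_range
  res <- with_seed(seed, cpp_wf_trajectory(as.integer(N), s, h,
                                           as.integer(age_gens),
                                           as.integer(max_tries),
                                           band[1], band[2]))
  if (!res$accepted)
    stop(sprintf(paste0("rejection budget exhausted after %d tries ",
                        "(acceptance rate < %.2e); segregation at this ",
                        "age/band is too rare"),
                 as.integer(res$tries), 1 / res$tries))
  structure(list(freq = res$trajectory, N = N, s = s, h = h,
                 tries = res$tries, acceptance_rate = 1 / res$tries),
            class = "wf_trajectory")
}

#' Post-equilibration variance of trajectories
#'
#' Variance of the allele frequency over the final `window` generations;
#' overdominant trajectories hover at their equilibrium and show smaller
#' variance than neutral trajectories conditioned to the same present-day
#' frequency band.
#'
#' @param trajectories A `wf_trajectory` or list of them.
#' @param window Number of trailing generations.
#' @return Numeric vector of variances.
#' @export
trajectory_variability <- function(trajectories, window) {
  if (inherits(trajectories, "wf_trajectory"))
    trajectories <- list(trajectories)
  vapply(trajectories, function(tr) {
    x <- tr$freq
    if (length(x) <= window) stop("trajectory shorter than the window")
    xs <- x[(length(x) - window + 1):length(x)]
    mean((xs - mean(xs))^2)
  }, numeric(1))
}

#' Coalescent sample conditioned on an allele-frequency trajectory
#'
#' The sample is split into the derived-allele and ancestral-allele
#' classes, treated as two populations whose sizes track the trajectory
#' and which exchange neutral-locus lineages by recombination; at the
#' allele's origin the derived class collapses into the ancestral
#' background.  Neutral mutations are dropped on the genealogy at rate
#' `theta = 4*N*mu` for the locus.
#'
#' @param trajectory A `wf_trajectory` covering back to the allele's
#'   origin.
#' @param n Sample size (haplotypes).
#' @param theta,rho Population-scaled mutation and recombination rates of
#'   the surveyed locus.
#' @param seed Integer seed.
#' @param n_derived Number of derived-class haplotypes in the sample;
#'   default draws Binomial(n, present frequency) conditioned on
#'   segregation in the sample.
#' @return Object of class `haplotype_sample`: `mat` (n x S binary, the
#'   focal site first), `focal_index` (1), `n_derived`, `derived_count`
#'   per site.
#' @export
structured_coalescent_sample <- function(trajectory, n, theta, rho, seed,
                                         n_derived = NULL) {
  stopifnot(inherits(trajectory, "wf_trajectory"))
  x_now <- trajectory$freq[length(trajectory$freq)]
  with_seed(seed, {
    if (is.null(n_derived)) {
      repeat {
        n_derived <- rbinom(1, n, x_now)
        if (n_derived > 0 && n_derived < n) break
      }
    }
    res <- cpp_traj_coalescent(trajectory$freq, as.integer(trajectory$N),
                               as.integer(n), as.integer(n_derived),
                               theta, rho)
    focal <- c(rep(1L, n_derived), rep(0L, n - n_derived))
    mat <- cbind(focal, res$haplotypes)
    colnames(mat) <- NULL
    haplotype_sample(mat, focal_index = 1L, n_derived = n_derived)
  })
}

#' Haplotype sample container
#'
#' @param mat n x S binary matrix (haplotypes x segregating sites).
#' @param focal_index Column index of the focal (selected or conditioned)
#'   site, or `NA`.
#' @param n_derived Derived-class size at the focal site.
#' @return Object of class `haplotype_sample`.
#' @export
haplotype_sample <- function(mat, focal_index = NA_integer_,
                             n_derived = NA_integer_) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  dc <- colSums(mat)
  if (ncol(mat) && any(dc == 0 | dc == nrow(mat)))
    stop("every site must segregate in the sample")
  structure(list(mat = mat, focal_index = focal_index,
                 n_derived = n_derived, derived_count = dc),
            class = "haplotype_sample")
}

#' Neutral coalescent sample conditioned on an intermediate-frequency site
#'
#' Plain neutral coalescent samples are rejected until at least one site
#' has derived count inside `count_range`; one qualifying site (chosen
#' uniformly) is marked focal.  This conditions on the presence of an
#' approximately 50%-frequency SNV without any selection.
#'
#' @param n Sample size (default 50 haplotypes).
#' @param count_range Inclusive derived-count window (default 22--28).
#' @param theta Population-scaled mutation rate.
#' @param seed Integer seed.
#' @param max_tries Rejection budget; the sampler aborts with acceptance
#'   diagnostics if the acceptance rate falls below 1e-4.
#' @return A `haplotype_sample` with `focal_index` set.
#' @export
psecoal_sample <- function(n = 50, count_range = c(22, 28), theta, seed,
                           max_tries = 20000) {
  lo <- count_range[1]; hi <- count_range[2]
  if (!(1 <= lo && lo <= hi && hi < n)) stop("invalid count_range")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      mat <- cpp_kingman_sample(as.integer(n), theta)
      dc <- colSums(mat)
      hit <- which(dc >= lo & dc <= hi)
      if (length(hit)) {
        focal <- if (length(hit) == 1L) hit else sample(hit, 1L)
        return(haplotype_sample(mat, focal_index = focal,
                                n_derived = dc[focal]))
      }
      if (try >= 1e4) break  # zero acceptances: rate provably < 1e-4
    }
    stop(sprintf("acceptance rate below 1e-4 after %d tries (n=%d, theta=%g, range [%d,%d])",
                 try, n, theta, lo, hi))
  })
}
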