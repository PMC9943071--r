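# Overdominance simulators and the summary-statistic panel.

test_that("genotype fitness map is (1, 1+sh, 1+s)", {
  w <- genotype_fitness(0.005, 10)
  expect_identical(unname(w), c(1, 1.05, 1.005))
  expect_equal(unname(genotype_fitness(0.005, 0.5)["w_Aa"]), 1.0025)
  expect_identical(unname(genotype_fitness(0, 7)), c(1, 1, 1))
})

test_that("overdominant trajectories settle at the h/(2h-1) equilibrium", {
  means <- vapply(1:50, function(i) {
    tr <- simulate_trajectory(10000, 0.005, 10, 6000, seed = 100 + i)
    mean(tail(tr$freq, 2000))
  }, numeric(1))
  expect_lt(abs(mean(means) - 10 / 19), 0.05)
})

test_that("neutral increments are mean-zero away from the boundaries", {
  # short horizon and interior frequencies keep the segregation
  # conditioning from biasing the drift increments
  incs <- unlist(lapply(1:30, function(i) {
    tr <- simulate_trajectory(2000, 0, 0.5, 1000, seed = 300 + i,
                              max_tries = 5e6)
    x <- tr$freq
    d <- diff(x)
    d[x[-length(x)] > 0.1 & x[-length(x)] < 0.9]
  }))
  expect_gt(length(incs), 1000)
  expect_gt(t.test(incs)$p.value, 0.01)
})

test_that("trajectory simulation is seed-reproducible and validates input", {
  a <- simulate_trajectory(5000, 0.005, 10, 2000, seed = 9)
  b <- simulate_trajectory(5000, 0.005, 10, 2000, seed = 9)
  expect_identical(a$freq, b$freq)
  expect_equal(a$freq[1], 1 / 10000)
  expect_true(all(a$freq > 0 & a$freq < 1))
  expect_error(simulate_trajectory(10, 0, 0.5, 100, seed = 1), "at least 50")
  expect_error(simulate_trajectory(1000, 0, 0.5, 0, seed = 1), "age_gens")
  # rejection budget exhaustion is reported with the acceptance rate
  expect_error(simulate_trajectory(10000, 0, 0.5, 40000, seed = 1,
                                   max_tries = 10),
               "rejection budget")
})

test_that("overdominant trajectories are more stable than matched neutral ones", {
  band <- c(0.44, 0.56)
  ov <- lapply(1:50, function(i)
    simulate_trajectory(10000, 0.005, 10, 10000, seed = 400 + i,
                        freq_range = band, max_tries = 5e6))
  ne <- lapply(1:50, function(i)
    simulate_trajectory(10000, 0, 0.5, 10000, seed = 800 + i,
                        freq_range = band, max_tries = 5e6))
  vo <- trajectory_variability(ov, 5000)
  vn <- trajectory_variability(ne, 5000)
  expect_true(all(vo >= 0))
  expect_lt(median(vo), median(vn))
  expect_lt(wilcox.test(vo, vn, exact = FALSE)$p.value, 0.01)
  # constant trajectory has zero variability
  const <- structure(list(freq = rep(0.5, 1000), N = 1000, s = 0, h = 0),
                     class = "wf_trajectory")
  expect_equal(trajectory_variability(const, 500), 0)
})

test_that("structured coalescent recovers the neutral panmictic limit", {
  # frequency pinned near 1 with rho = 0: the derived class is simply a
  # neutral sample from a population of size ~2N, so E[pi] = theta * x
  N <- 2000
  traj <- rep(1 - 1 / (2 * N), 12 * 2 * N)
  set.seed(9)
  pis <- vapply(1:150, function(i) {
    m <- ancientdel:::cpp_traj_coalescent(traj, N, 10L, 10L, 5, 0)$haplotypes
    n <- nrow(m); d <- colSums(m)
    sum(2 * d * (n - d)) / (n * (n - 1))
  }, numeric(1))
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 5 * (1 - 1 / (2 * N))), 2.5 * se)
})

test_that("structured coalescent samples are seeded and reject bad input", {
  tr <- simulate_trajectory(5000, 0.005, 10, 3000, seed = 15)
  a <- structured_coalescent_sample(tr, 20, theta = 5, rho = 5, seed = 3)
  b <- structured_coalescent_sample(tr, 20, theta = 5, rho = 5, seed = 3)
  expect_identical(a$mat, b$mat)
  expect_equal(a$focal_index, 1L)
  expect_equal(sum(a$mat[, 1]), a$n_derived)
  bad <- structure(list(freq = c(0.5, 0, 0.5), N = 1000, s = 0, h = 0),
                   class = "wf_trajectory")
  expect_error(structured_coalescent_sample(bad, 10, 1, 0, seed = 1),
               "absorbing")
})

test_that("pseCoal conditions on an intermediate-frequency site", {
  for (i in 1:5) {
    s <- psecoal_sample(50, c(22, 28), theta = 10, seed = i)
    dc <- s$derived_count[s$focal_index]
    expect_gte(dc, 22); expect_lte(dc, 28)
    expect_gte(dc / 50, 0.44); expect_lte(dc / 50, 0.56)
  }
  # a full-width window accepts (almost) immediately
  s <- psecoal_sample(20, c(1, 19), theta = 8, seed = 99)
  expect_s3_class(s, "haplotype_sample")
  expect_error(psecoal_sample(10, c(0, 5), theta = 1, seed = 1), "count_range")
})

test_that("summary statistics equal an independent brute-force oracle", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(4:8, 1); S <- sample(1:10, 1)
    m <- random_sample_matrix(n, S)
    got <- summary_stats(m)
    want <- brute_stats(m)
    expect_identical(got[["S"]], want[["S"]])
    expect_identical(got[["dvk"]], want[["dvk"]])
    for (nm in c("theta_w", "pi", "tajima_d", "zns", "fay_wu_h", "dvh"))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
  }
})

test_that("summary statistics handle canonical closed-form cases", {
  n <- 6
  single <- matrix(0L, n, 1); single[1, 1] <- 1L
  st <- summary_stats(single)
  expect_equal(st[["pi"]], 2 / n)             # one singleton site
  expect_lt(st[["tajima_d"]], 0)
  # two perfectly correlated sites
  m <- cbind(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0))
  expect_equal(summary_stats(m)[["zns"]], 1)
  # no variation: D, ZnS, H undefined; haplotype stats still defined
  st0 <- summary_stats(matrix(integer(0), nrow = 5, ncol = 0))
  expect_equal(st0[["S"]], 0)
  expect_true(is.na(st0[["tajima_d"]]))
  expect_equal(st0[["dvk"]], 1)
})

test_that("Fay and Wu's H centers on zero under neutrality", {
  set.seed(123)
  hs <- vapply(1:500, function(i) {
    m <- ancientdel:::cpp_kingman_sample(20L, 5)
    if (ncol(m) == 0) return(NA_real_)
    summary_stats(m)[["fay_wu_h"]]
  }, numeric(1))
  hs <- hs[!is.na(hs)]
  expect_lt(abs(mean(hs)), 2 * sd(hs) / sqrt(length(hs)))
})

test_that("PCA separability reports a null result for identical scenarios", {
  set.seed(31)
  mk <- function(seed0) t(vapply(1:30, function(i) {
    m <- ancientdel:::cpp_kingman_sample(30L, 8)
    summary_stats(m)
  }, numeric(8)))
  res <- pca_separation(list(a = mk(1), b = mk(2)))
  expect_true(all(res$stat_p > 0.05 / length(res$stat_p) |
                    is.na(res$stat_p)))
  expect_gt(res$overlap[["PC1"]], 0.5)
  expect_error(pca_separation(list(a = mk(1)[1:5, ], b = mk(2)[1:5, ])),
               "20 replicates")
})
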