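# Neutral expectation of derived-allele sharing with archaic genomes.

make_matrix <- function(mat, n_yri) {
  n_arch <- nrow(mat) - n_yri
  variant_matrix(mat, c(rep("YRI", n_yri),
                        rep(ARCHAIC <- c("vindija", "chagyrskaya", "altai",
                                         "denisovan"),
                            length.out = n_arch)))
}

test_that("sharing proportion matches hand enumeration on a 5-site matrix", {
  n_yri <- 216
  mat <- matrix(0L, n_yri + 8, 5)
  yri_counts <- c(1, 2, 3, 216, 4)
  for (s in 1:5) mat[seq_len(yri_counts[s]), s] <- 1L
  mat[n_yri + 1, 2] <- 1L   # archaic derived at sites 2 and 4
  mat[n_yri + 5, 4] <- 1L
  res <- sharing_proportion(make_matrix(mat, n_yri))
  # mac>1 needs both alleles >= 2 copies: counts 2, 3, 4 qualify;
  # the fixed-in-YRI site (216) has ancestral count 0 and is excluded
  expect_equal(res$denominator, 3)
  expect_equal(res$numerator, 1)
  expect_equal(res$proportion, 1 / 3)
})

test_that("sharing proportion hits its 0 and 1 limits", {
  set.seed(1)
  n_yri <- 30
  mat <- matrix(rbinom(38 * 40, 1, 0.3), 38, 40)
  mat[31:38, ] <- 0L   # archaics all ancestral
  keep <- colSums(mat[1:n_yri, , drop = FALSE]) >= 2 &
    colSums(1L - mat[1:n_yri, , drop = FALSE]) >= 2
  mat <- mat[, keep, drop = FALSE]
  expect_equal(sharing_proportion(make_matrix(mat, n_yri))$proportion, 0)
  # archaic rows identical to a YRI carrier: every mac>1 site that carrier
  # holds is shared; restrict to those sites
  carried <- mat[, mat[1, ] == 1, drop = FALSE]
  for (r in 31:38) carried[r, ] <- carried[1, ]
  expect_equal(sharing_proportion(make_matrix(carried, n_yri))$proportion, 1)
})

test_that("zero denominator yields an explicit empty result", {
  mat <- matrix(0L, 24, 2)
  mat[1, 1] <- 1L                          # singleton: excluded
  mat[1:15, 2] <- 1L                       # ancestral count 1: excluded
  vm <- variant_matrix(mat, c(rep("YRI", 16), rep(c("vindija", "chagyrskaya",
                                                    "altai", "denisovan"), 2)))
  res <- sharing_proportion(vm)
  expect_true(res$empty)
  expect_true(is.na(res$proportion))
})

test_that("bins partition the denominator and inherit the overall proportion", {
  m <- demographic_model(archaic_sampling_times = "present")
  vm <- simulate_variant_matrix(m, 800, seed = 21)
  res <- sharing_proportion(vm)
  expect_equal(sum(res$bins$n), res$denominator)
  expect_equal(sum(res$bins$n_shared), res$numerator)
  expect_true(all(is.na(res$bins$proportion[res$bins$n == 0])))
  # collapse to a single bin: its proportion is the overall one
  one <- binned_sharing(vm, n_bins = 1)
  expect_equal(one$proportion, res$proportion)
})

test_that("sharing decreases as the AMH-archaic split deepens", {
  props <- vapply(c(500e3, 1e6, 2e6), function(ts) {
    m <- demographic_model(t_split_amh_archaic = ts,
                           archaic_sampling_times = "present")
    mean(sharing_distribution(m, 1, 2000, seed = 33))
  }, numeric(1))
  expect_true(all(diff(props) < 0))
})

test_that("replicate machinery is deterministic and consistent across seeds", {
  m <- demographic_model(archaic_sampling_times = "present")
  a <- sharing_distribution(m, 3, 500, seed = 5)
  b <- sharing_distribution(m, 3, 500, seed = 5)
  expect_identical(a, b)
  # disjoint seeds agree within Monte-Carlo error (2 SE of the difference)
  x <- sharing_distribution(m, 12, 2000, seed = 101)
  y <- sharing_distribution(m, 12, 2000, seed = 202)
  se <- sqrt(var(x) / 12 + var(y) / 12)
  expect_lt(abs(mean(x) - mean(y)), 2.5 * se)
})

test_that("engine agrees with an independent coalescent implementation", {
  oracle <- system.file("oracle", "sharing_oracle.py", package = "ancientdel")
  # panmictic control: one population, Ne 10,000, 224 haploids
  out <- system2("python", c(oracle, "single", "4000", "12", "10000", "216"),
                 stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  m <- demographic_model(amh_ne = 10000, archaic_ne = 10000,
                         t_split_amh_archaic = 4, t_split_denisovan = 3,
                         t_split_altai = 2, t_split_vindija_chagyrskaya = 1,
                         archaic_sampling_times = "present")
  mine <- sharing_distribution(m, 1, 4000, seed = 55)
  se <- sqrt(vals[2]^2 + mine * (1 - mine) / (0.67 * 4000))
  expect_lt(abs(mine - vals[1]), 2.5 * se)

  # full five-lineage demography
  out <- system2("python", c(oracle, "full", "6000", "13"), stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  m <- demographic_model(archaic_sampling_times = "present")
  mine <- sharing_distribution(m, 2, 3000, seed = 77)
  se <- sqrt(vals[2]^2 + var(mine) / 2 + 1e-6)
  expect_lt(abs(mean(mine) - vals[1]), 2.5 * se)
})

test_that("structured ancestry: sharing decays with migration toward panmixia", {
  base <- demographic_model(archaic_sampling_times = "present")
  props <- vapply(c(2.5e-7, 7.5e-6, 2.5e-4), function(mm) {
    sm <- structured_ancestry_model(m = mm, base = base)
    simulate_structured_ancestry(sm, 2000, seed = 91)$proportion
  }, numeric(1))
  expect_true(all(diff(props) < 0))
  # deep structure inflates sharing well beyond the unstructured model
  unstr <- mean(sharing_distribution(base, 1, 2000, seed = 92))
  expect_gt(props[1], unstr)
})

test_that("migration scan handles trivial and unreachable targets", {
  base <- demographic_model(archaic_sampling_times = "present")
  tmpl <- structured_ancestry_model(m = 1e-5, base = base)
  grid <- c(1e-6, 1e-5, 1e-4)
  sc0 <- scan_migration(tmpl, grid, 200, target_proportion = 0, seed = 1)
  expect_equal(sc0$critical_m, 1e-4)     # always reached -> largest grid m
  sc1 <- scan_migration(tmpl, grid, 200, target_proportion = 1.01, seed = 1)
  expect_equal(sc1$status, "none-reached")
  expect_true(is.na(sc1$critical_m))
  expect_equal(nrow(sc1$table), 3)
})

test_that("SFS comparison: identity, null calibration, and structure detection", {
  expect_error(sfs_compare(c(5, 3, 2), c(5, 3)), "mismatch")
  self <- sfs_compare(c(50, 30, 20, 10), c(50, 30, 20, 10))
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)

  # null calibration: the reference (simulated-expected) spectrum is
  # estimated from a much larger draw so its sampling noise is negligible
  m <- demographic_model(archaic_sampling_times = "present")
  ref <- simulate_variant_matrix(m, 12000, seed = 3000, n_yri = 30)
  ps <- vapply(1:150, function(i) {
    b <- simulate_variant_matrix(m, 600, seed = 7000 + i, n_yri = 30)
    sfs_compare(ref, b)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # strong ancestral structure inflates intermediate frequencies
  sm <- structured_ancestry_model(m = 2.5e-8,
                                  base = demographic_model(
                                    archaic_sampling_times = "present"))
  a <- simulate_variant_matrix(sm, 6000, seed = 41)
  b <- simulate_variant_matrix(m, 6000, seed = 42)
  expect_lt(sfs_compare(b, a)$p, 0.05)
})
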