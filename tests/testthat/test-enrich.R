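# Functional annotation and permutation enrichment.

test_that("exon intersection uses half-open semantics and dedupes genes", {
  dels <- data.frame(chrom = "c1", start = c(100, 500), end = c(200, 900),
                     id = c("d1", "d2"))
  exons <- data.frame(chrom = "c1",
                      start = c(200, 550, 600, 700, 950),
                      end = c(300, 560, 610, 710, 990),
                      gene = c("gA", "gB", "gB", "gB", "gB"))
  res <- intersect_exons(dels, exons)
  # adjacency [100,200) vs [200,300) is not overlap
  expect_equal(res$flags$exonic, c(FALSE, TRUE))
  # three exons of one gene: listed once with count 3
  expect_equal(nrow(res$genes), 1)
  expect_equal(res$genes$n_exons, 3)
  expect_error(intersect_exons(
    data.frame(chrom = "c1", start = 5, end = 5, id = "x"), exons), "line")
})

test_that("exon flags equal the brute-force all-pairs oracle", {
  set.seed(19)
  dels <- data.frame(chrom = sample(c("c1", "c2"), 50, TRUE),
                     start = sample.int(5000, 50))
  dels$end <- dels$start + sample(50:500, 50, TRUE)
  dels$id <- paste0("d", 1:50)
  exons <- data.frame(chrom = sample(c("c1", "c2"), 80, TRUE),
                      start = sample.int(5000, 80))
  exons$end <- exons$start + sample(30:200, 80, TRUE)
  exons$gene <- paste0("g", 1:80)
  brute <- vapply(seq_len(nrow(dels)), function(i)
    any(exons$chrom == dels$chrom[i] & exons$start < dels$end[i] &
          exons$end > dels$start[i]), logical(1))
  expect_equal(intersect_exons(dels, exons)$flags$exonic, brute)
})

test_that("GWAS assignment uses a strict threshold and the lowest p", {
  gw <- data.frame(snv_id = c("s1", "s2", "s2"),
                   trait = c("traitC", "traitA", "traitB"),
                   p = c(1e-7, 1e-9, 1e-12))
  expect_false(assign_gwas("s1", gw)$associated)     # 1e-7 misses 1e-8
  hit <- assign_gwas(c("s1", "s2"), gw)
  expect_true(hit$associated)
  expect_equal(hit$trait, "traitB")
  expect_equal(hit$p, 1e-12)
  expect_false(assign_gwas("absent", gw)$associated)
})

test_that("permutation enrichment matches exhaustive enumeration on a toy", {
  # 8 deletions, 4 ancient; exact null from all C(8,4) label placements
  feature <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  labels <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  obs <- mean(feature[labels]) - mean(feature[!labels])
  combs <- combn(8, 4)
  exact <- mean(apply(combs, 2, function(ix) {
    lab <- seq_len(8) %in% ix
    abs(mean(feature[lab]) - mean(feature[!lab])) >= abs(obs)
  }))
  res <- permutation_enrichment(labels, feature, n_perm = 20000, seed = 5)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(res$p - exact), 2.5 * se + 2 / 20000)
  expect_gte(res$p, 1 / 20001)
  expect_lte(res$p, 1)
})

test_that("permutation enrichment hits its degenerate limits", {
  # identical proportions in both classes
  labels <- rep(c(TRUE, FALSE), each = 50)
  feature <- rep(c(TRUE, FALSE), 50)
  res <- permutation_enrichment(labels, feature, n_perm = 500, seed = 2)
  expect_equal(res$fold, 1)
  expect_gt(res$p, 0.9)
  # perfect association: no permutation can beat the observed difference
  labels <- rep(c(TRUE, FALSE), each = 100)
  res2 <- permutation_enrichment(labels, labels, n_perm = 2000, seed = 3)
  expect_equal(res2$p, 1 / 2001)
  expect_error(permutation_enrichment(rep(TRUE, 10), rep(TRUE, 10), 10, 1),
               "non-empty")
  # reproducible given seed
  res3 <- permutation_enrichment(labels, labels, n_perm = 2000, seed = 3)
  expect_identical(res2$p, res3$p)
})

test_that("category enrichment detects a planted 5x effect and skips empties", {
  set.seed(23)
  n <- 300
  labels <- rep(c(TRUE, FALSE), length.out = n)
  ids <- paste0("d", seq_len(n))
  inX <- ifelse(labels, runif(n) < 0.5, runif(n) < 0.1)
  mem <- rbind(data.frame(id = ids[inX], category = "catX"),
               data.frame(id = sample(ids, 40), category = "catY"))
  res <- category_enrichment(labels, mem, ids, c("catX", "catY", "catZ"),
                             n_perm = 2000, seed = 7)
  x <- res[res$category == "catX", ]
  expect_gt(x$fold, 1)
  expect_lt(x$p, 0.05)
  expect_equal(res$n_members[res$category == "catZ"], 0)
  expect_true(is.na(res$p[res$category == "catZ"]))
  expect_error(category_enrichment(labels, data.frame(id = "d1",
                                                      category = "mystery"),
                                   ids, c("catX"), 100, 1), "unknown")
  # a category covering everything cannot be enriched
  all_mem <- data.frame(id = ids, category = "catX")
  res_all <- category_enrichment(labels, all_mem, ids, "catX",
                                 n_perm = 500, seed = 9)
  expect_equal(res_all$fold, 1)
  expect_gt(res_all$p, 0.9)
})

test_that("length percentile test has exact degenerate behaviour", {
  set.seed(29)
  base <- rlnorm(150, log(2000), 0.8)
  lengths <- c(2 * base, base)
  labels <- rep(c(TRUE, FALSE), each = 150)
  res <- percentile_length_test(lengths, labels, n_perm = 1000, seed = 4)
  expect_true(all(abs(res$ratio - 2) < 1e-12))
  expect_true(all(res$p < 0.05))
  # identical multisets: all ratios 1
  res2 <- percentile_length_test(c(base, base), labels, n_perm = 200,
                                 seed = 5)
  expect_true(all(abs(res2$ratio - 1) < 1e-12))
  expect_error(percentile_length_test(base[1:15], rep(c(TRUE, FALSE),
                                                      c(5, 10)),
                                      n_perm = 100, seed = 1), "10 members")
})

test_that("length percentile p-values are uniform under the null", {
  set.seed(31)
  lens <- rlnorm(60, log(2000), 0.7)
  ps <- unlist(lapply(1:60, function(i) {
    percentile_length_test(lens, sample(rep(c(TRUE, FALSE), 30)),
                           percentiles = c(20, 50, 80),
                           n_perm = 400, seed = 100 + i)$p
  }))
  # discrete add-one p-values tie and are slightly conservative; KS is a
  # conservative uniformity screen at alpha = 0.01
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("functionality definitions nest and the frequency filter logs", {
  co <- small_cohort(seed = 67, n = 60)
  tab <- generate_annotation_tables(co, n_trajectories = 10)
  ex <- intersect_exons(co$deletions, tab$exons)
  gwas_flag <- vapply(seq_len(nrow(co$deletions)), function(i) {
    comp <- strsplit(co$truth$companions[i], ",")[[1]]
    assign_gwas(comp, tab$gwas)$associated
  }, logical(1))
  both <- ex$flags$exonic & gwas_flag
  expect_lte(sum(both), min(sum(ex$flags$exonic), sum(gwas_flag)))
  expect_message(filter_pooled_frequency(runif(50)), "kept")
})
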