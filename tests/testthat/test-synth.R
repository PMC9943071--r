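# Synthetic cohort generator: planted truth must be recoverable and the
# generators must be seeded and faithful to their declared distributions.

test_that("config validation rejects malformed study conditions", {
  expect_error(synth_config(category_mix = c(human_specific = 0.5,
                                             recurrent = 0.5)), "name")
  expect_error(synth_config(category_mix = c(human_specific = 0.5,
                                             recurrent = 0.2,
                                             introgressed = 0.2,
                                             ancient = 0.2)), "sum to 1")
  expect_error(synth_config(n_deletions = 0), "positive")
  cfg <- synth_config()
  expect_equal(unname(cfg$populations), c(108, 103, 99))
})

test_that("degenerate mixes honour the category definitions", {
  hs <- generate_cohort(synth_config(
    n_deletions = 25, seed = 3,
    category_mix = c(human_specific = 1, recurrent = 0, introgressed = 0,
                     ancient = 0)))
  expect_true(all(hs$truth$archaic_carriers == ""))
  arch_rows <- hs$variants$pop %in% hs$config$archaic_genomes
  del_cols <- hs$sites$type == "del"
  expect_true(all(hs$variants$mat[arch_rows, del_cols] == 0L))

  intro <- generate_cohort(synth_config(
    n_deletions = 25, seed = 4,
    category_mix = c(human_specific = 0, recurrent = 0, introgressed = 1,
                     ancient = 0)))
  yri <- intro$variants$pop == "YRI"
  del_cols <- intro$sites$type == "del"
  expect_true(all(colSums(intro$variants$mat[yri, del_cols]) == 0L))
})

test_that("generation is byte-identical under a repeated seed", {
  cfg <- synth_config(n_deletions = 15, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(generate_archaic_reads(a$deletions, a$truth, cfg),
                   generate_archaic_reads(b$deletions, b$truth, cfg))
  expect_identical(generate_annotation_tables(a, n_trajectories = 20),
                   generate_annotation_tables(b, n_trajectories = 20))
})

test_that("planted category frequencies match the mix within binomial bounds", {
  mix <- c(human_specific = 0.4, recurrent = 0.2, introgressed = 0.15,
           ancient = 0.25)
  co <- generate_cohort(synth_config(n_deletions = 400, category_mix = mix,
                                     seed = 9))
  counts <- table(factor(co$truth$category, levels = names(mix)))
  for (k in names(mix)) {
    ci <- qbinom(c(0.005, 0.995), 400, mix[[k]])
    expect_gte(counts[[k]], ci[1])
    expect_lte(counts[[k]], ci[2])
  }
})

test_that("every planted companion is in true LD and recoverable", {
  co <- small_cohort(seed = 13, n = 40)
  ldi <- cohort_ld_inputs(co)
  for (i in seq_len(nrow(co$truth))) {
    planted <- strsplit(co$truth$companions[i], ",")[[1]]
    found <- ldi$companions_list[[co$truth$id[i]]]$snv_id
    expect_true(all(planted %in% found),
                label = sprintf("companions of %s recovered", co$truth$id[i]))
  }
})

test_that("read generator follows its Poisson depth model", {
  cfg <- synth_config(n_deletions = 100, window_size_range = c(1000, 1000),
                      mean_depth = 30, seed = 17,
                      category_mix = c(human_specific = 1, recurrent = 0,
                                       introgressed = 0, ancient = 0))
  co <- generate_cohort(cfg)
  reads <- generate_archaic_reads(co$deletions, co$truth, cfg)
  counts <- count_intersecting_reads(reads$vindija, co$deletions)
  # a read intersects a 1 kb window iff its integer start lies in a span
  # of (1000 + readlen - 1) bp; expected count = start rate * span
  expected <- 30 / 100 * (1000 + 100 - 1)
  expect_lt(abs(mean(counts) - expected),
            3 * sqrt(expected / length(counts)))

  # residual fraction 1: deleted and intact windows indistinguishable
  cfg2 <- synth_config(n_deletions = 60, window_size_range = c(1000, 1000),
                       residual_depth_fraction = 1, seed = 19,
                       category_mix = c(human_specific = 0.5, recurrent = 0,
                                        introgressed = 0, ancient = 0.5))
  co2 <- generate_cohort(cfg2)
  reads2 <- generate_archaic_reads(co2$deletions, co2$truth, cfg2)
  prof <- archaic_depth_profile(reads2, co2$deletions)
  deleted_in <- vapply(seq_len(nrow(co2$truth)), function(i)
    grepl("vindija", co2$truth$archaic_carriers[i]), logical(1))
  v <- prof[prof$genome == "vindija", ]
  if (any(deleted_in) && any(!deleted_in)) {
    p <- wilcox.test(v$count[deleted_in], v$count[!deleted_in],
                     exact = FALSE)$p.value
    expect_gt(p, 0.001)
  }

  # residual 0: planted deletions drop below the 5% quantile of intact
  cfg3 <- synth_config(n_deletions = 80, seed = 23,
                       category_mix = c(human_specific = 0.5, recurrent = 0,
                                        introgressed = 0, ancient = 0.5))
  co3 <- generate_cohort(cfg3)
  reads3 <- generate_archaic_reads(co3$deletions, co3$truth, cfg3)
  prof3 <- archaic_depth_profile(reads3, co3$deletions)
  v3 <- prof3[prof3$genome == "vindija", ]
  del3 <- grepl("vindija", co3$truth$archaic_carriers)
  q5 <- quantile(v3$r[!del3], 0.05)
  expect_true(all(v3$r[del3] < q5))
})

test_that("annotation tables realize the planted functional truth", {
  co <- small_cohort(seed = 29, n = 50)
  tab <- generate_annotation_tables(co, n_trajectories = 50)
  sig <- tab$gwas$snv_id[tab$gwas$p < 1e-8]
  for (i in which(co$truth$gwas)) {
    comp <- strsplit(co$truth$companions[i], ",")[[1]]
    expect_true(any(comp %in% sig))
  }
  ex <- intersect_exons(co$deletions, tab$exons)
  expect_equal(ex$flags$exonic[match(co$truth$id, ex$flags$id)],
               co$truth$exonic)
  expect_true(all(c(5000, 50000) %in% tab$trajectories$time_years))
  # ancient deletions' companions predate the AMH-archaic split
  anc <- unlist(strsplit(co$truth$companions[co$truth$category == "ancient"],
                         ","))
  expect_true(all(tab$ages$age_years[tab$ages$snv_id %in% anc] > 7e5))
  # introgressed companions are in the emitted S* list
  intro <- unlist(strsplit(
    co$truth$companions[co$truth$category == "introgressed"], ","))
  expect_true(all(intro %in% tab$sstar$snv_id))
})

test_that("emitted VCF round-trips through a standard parser", {
  co <- small_cohort(seed = 31, n = 10)
  dir <- file.path(tempdir(), "synth_vcf_roundtrip")
  paths <- write_cohort(co, dir)
  v <- vcfR::read.vcfR(paths[["vcf"]], verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(co$sites))
  # deletions carry SVTYPE/END info and 1-based positions
  del <- v@fix[v@fix[, "ID"] %in% co$deletions$id, , drop = FALSE]
  expect_true(all(grepl("SVTYPE=DEL", del[, "INFO"])))
  d1 <- co$deletions[match(del[1, "ID"], co$deletions$id), ]
  expect_equal(as.integer(del[1, "POS"]), d1$start + 1L)
  # genotypes reconstruct the haplotype matrix for the first diploid
  gt <- vcfR::extract.gt(v)
  idx <- match(co$sites$id, rownames(gt))
  hap1 <- as.integer(substr(gt[idx, 1], 1, 1))
  hap2 <- as.integer(substr(gt[idx, 1], 3, 3))
  expect_equal(hap1, unname(co$variants$mat[1, ]))
  expect_equal(hap2, unname(co$variants$mat[2, ]))
})
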