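# Shared fixtures, built in code at test time.

small_cohort <- function(seed = 11, n = 60,
                         mix = c(human_specific = 0.4, recurrent = 0.2,
                                 introgressed = 0.2, ancient = 0.2)) {
  generate_cohort(synth_config(n_deletions = n, category_mix = mix,
                               seed = seed))
}

# archaic deletion presence straight from the generated haplotypes
truth_presence <- function(cohort) {
  vm <- cohort$variants
  del_cols <- match(cohort$deletions$id, cohort$sites$id)
  pres <- vapply(cohort$config$archaic_genomes, function(g)
    colSums(vm$mat[vm$pop == g, del_cols, drop = FALSE]) > 0,
    logical(length(del_cols)))
  rownames(pres) <- cohort$deletions$id
  pres
}

# run the planted cohort through depth calling + LD classification and
# return truth vs called categories; presence = "depth" exercises the
# read-depth caller end to end, "truth" isolates the classifier
classify_cohort <- function(cohort, presence = "depth") {
  pm <- if (presence == "truth") {
    list(presence = truth_presence(cohort))
  } else {
    reads <- generate_archaic_reads(cohort$deletions, cohort$truth,
                                    cohort$config)
    presence_matrix(archaic_depth_profile(reads, cohort$deletions))
  }
  ldi <- cohort_ld_inputs(cohort)
  res <- classify_all(cohort$deletions$id, ldi$companions_list, pm$presence,
                      ldi$archaic_snv_presence, cohort$sstar_snvs,
                      ldi$yri_allele_counts)
  called <- res$assignments$category[match(cohort$truth$id,
                                           res$assignments$id)]
  list(truth = cohort$truth$category, called = called, result = res,
       presence = pm)
}

# independent brute-force implementation of the summary-statistic panel,
# written with explicit loops so it shares no code with the package path
brute_stats <- function(mat) {
  n <- nrow(mat); S <- ncol(mat)
  pairs <- 0; diffs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    diffs <- diffs + sum(mat[i, ] != mat[j, ])
  }
  pi <- diffs / pairs
  a1 <- 0; a2 <- 0
  for (i in seq_len(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  theta_w <- S / a1
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  vD <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  tajima_d <- if (S > 0 && vD > 0) (pi - theta_w) / sqrt(vD) else NA_real_
  zns <- NA_real_
  if (S >= 2) {
    tot <- 0; np <- 0
    for (a in seq_len(S - 1)) for (b in (a + 1):S) {
      pa <- sum(mat[, a]) / n; pb <- sum(mat[, b]) / n
      pab <- sum(mat[, a] == 1 & mat[, b] == 1) / n
      D <- pab - pa * pb
      tot <- tot + D^2 / (pa * (1 - pa) * pb * (1 - pb))
      np <- np + 1
    }
    zns <- tot / np
  }
  th <- 0
  for (s in seq_len(S)) th <- th + 2 * sum(mat[, s])^2 / (n * (n - 1))
  fwh <- if (S > 0) pi - th else NA_real_
  haps <- unique(apply(mat, 1, paste, collapse = ""))
  K <- length(haps)
  ph <- sapply(haps, function(h) mean(apply(mat, 1, paste, collapse = "") == h))
  dvh <- n / (n - 1) * (1 - sum(ph^2))
  c(S = S, theta_w = theta_w, pi = pi, tajima_d = tajima_d, zns = zns,
    fay_wu_h = fwh, dvk = K, dvh = dvh)
}

# random segregating haplotype matrix for oracle comparisons
random_sample_matrix <- function(n, S) {
  repeat {
    m <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
    d <- colSums(m)
    if (all(d > 0 & d < n)) return(m)
  }
}
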