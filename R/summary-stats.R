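#' Classical summary statistics of a haplotype sample
#'
#' Computes the standard neutrality panel on a binary haplotype matrix
#' with known ancestral state: number of segregating sites S, Watterson's
#' theta, nucleotide diversity pi, Tajima's D, the ZnS linkage statistic
#' (mean pairwise r-squared), Fay and Wu's H (unnormalized, `pi -
#' theta_H`), the number of distinct haplotypes (dvk) and haplotype
#' diversity (dvh).
#'
#' @param sample A [haplotype_sample()] (or bare binary matrix).
#' @return Named numeric vector with elements `S`, `theta_w`, `pi`,
#'   `tajima_d`, `zns`, `fay_wu_h`, `dvk`, `dvh`.  With no segregating
#'   sites, D, ZnS and H are `NA`; ZnS needs at least two sites.
#' @export
summary_stats <- function(sample) {
  mat <- if (inherits(sample, "haplotype_sample")) sample$mat else
    as.matrix(sample)
  n <- nrow(mat)
  if (n < 4) stop("need at least 4 haplotypes")
  S <- ncol(mat)

  # haplotype-level statistics are defined even without variation
  key <- apply(mat, 1, paste, collapse = "")
  counts <- table(key)
  dvk <- length(counts)
  dvh <- n / (n - 1) * (1 - sum((counts / n)^2))

  if (S == 0L)
    return(c(S = 0, theta_w = 0, pi = 0, tajima_d = NA, zns = NA,
             fay_wu_h = NA, dvk = dvk, dvh = dvh))

  d <- colSums(mat)
  a1 <- sum(1 / seq_len(n - 1))
  theta_w <- S / a1
  pi <- sum(2 * d * (n - d)) / (n * (n - 1))

  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  vD <- e1 * S + e2 * S * (S - 1)
  tajima_d <- if (vD > 0) (pi - theta_w) / sqrt(vD) else NA_real_

  zns <- if (S >= 2) {
    r2 <- cor(mat)^2
    mean(r2[upper.tri(r2)])
  } else NA_real_

  theta_h <- sum(2 * d^2) / (n * (n - 1))
  fay_wu_h <- pi - theta_h

  c(S = S, theta_w = theta_w, pi = pi, tajima_d = tajima_d, zns = zns,
    fay_wu_h = fay_wu_h, dvk = dvk, dvh = dvh)
}

#' PCA separability of summary-statistic panels across scenarios
#'
#' Standardizes the pooled statistic matrix (undefined entries dropped
#' listwise), projects it on principal components of the correlation
#' structure, and reports per-statistic two-sided rank-sum p-values
#' between the first two scenarios together with the PC1/PC2 range
#' overlap.  Used to ask whether overdominant and neutral samples can be
#' told apart at matched focal frequency.
#'
#' @param stat_matrices Named list (one per scenario, >= 2) of
#'   replicate x statistic matrices with identical column names
#'   (>= 20 replicates each).
#' @return List: `projections` (data.frame with `scenario`, `PC1`,
#'   `PC2`), `stat_p` (per-statistic rank-sum p), `overlap` (PC1/PC2
#'   range-overlap coefficients), `loadings`, `dropped` (rows lost to
#'   undefined statistics).
#' @export
pca_separation <- function(stat_matrices) {
  stopifnot(is.list(stat_matrices), length(stat_matrices) >= 2,
            !is.null(names(stat_matrices)))
  if (any(vapply(stat_matrices, nrow, 1L) < 20))
    stop("need at least 20 replicates per scenario")
  scen <- rep(names(stat_matrices), vapply(stat_matrices, nrow, 1L))
  X <- do.call(rbind, stat_matrices)
  keep_col <- colnames(X)[apply(X, 2, function(v) sd(v[is.finite(v)]) > 0)]
  X <- X[, keep_col, drop = FALSE]
  ok <- stats::complete.cases(X) & apply(X, 1, function(v) all(is.finite(v)))
  if (nrow(X) - sum(ok) > 0 && sum(ok) < 2 * ncol(X))
    warning("fewer complete replicates than statistics; PCA may be unstable")
  Xc <- X[ok, , drop = FALSE]
  scen_ok <- scen[ok]

  pc <- prcomp(Xc, center = TRUE, scale. = TRUE)
  proj <- data.frame(scenario = scen_ok, PC1 = pc$x[, 1],
                     PC2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0)

  s1 <- names(stat_matrices)[1]; s2 <- names(stat_matrices)[2]
  stat_p <- vapply(colnames(Xc), function(cn) {
    wilcox.test(Xc[scen_ok == s1, cn], Xc[scen_ok == s2, cn],
                exact = FALSE)$p.value
  }, numeric(1))

  range_overlap <- function(v) {
    r1 <- range(v[scen_ok == s1]); r2 <- range(v[scen_ok == s2])
    num <- min(r1[2], r2[2]) - max(r1[1], r2[1])
    den <- max(r1[2], r2[2]) - min(r1[1], r2[1])
    max(0, num / den)
  }
  list(projections = proj, stat_p = stat_p,
       overlap = c(PC1 = range_overlap(proj$PC1),
                   PC2 = range_overlap(proj$PC2)),
       loadings = pc$rotation, dropped = sum(!ok))
}
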