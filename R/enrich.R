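#' Functional annotation and permutation enrichment tests
#'
#' Deletions receive phenotypic relevance from two sources: direct exon
#' overlap, and genome-wide-association hits carried by their LD
#' companions.  Enrichment of such features (and of length percentiles)
#' among ancient relative to non-ancient deletions is assessed by label
#' permutation.
#'
#' @name enrich
NULL

#' Intersect deletions with exon annotation
#'
#' A deletion is exonic iff it overlaps at least one exon by >= 1 bp
#' (0-based half-open intervals on both sides).
#'
#' @param deletions data.frame `chrom`, `start`, `end`, `id`.
#' @param exons data.frame `chrom`, `start`, `end`, `gene`.
#' @return List: `flags` (data.frame `id`, `exonic`) and `genes`
#'   (data.frame `id`, `gene`, `n_exons`, deduplicated per gene with
#'   overlapped-exon counts).
#' @export
intersect_exons <- function(deletions, exons) {
  check_intervals(deletions, "deletions")
  check_intervals(exons, "exons")
  hits <- list()
  for (ch in unique(deletions$chrom)) {
    di <- which(deletions$chrom == ch)
    ei <- which(exons$chrom == ch)
    if (!length(ei)) next
    dr <- IRanges::IRanges(deletions$start[di] + 1L, deletions$end[di])
    er <- IRanges::IRanges(exons$start[ei] + 1L, exons$end[ei])
    ov <- IRanges::findOverlaps(dr, er)
    if (length(ov))
      hits[[ch]] <- data.frame(
        id = deletions$id[di[S4Vectors::queryHits(ov)]],
        gene = exons$gene[ei[S4Vectors::subjectHits(ov)]],
        stringsAsFactors = FALSE)
  }
  hit_df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(id = character(), gene = character())
  genes <- if (nrow(hit_df)) {
    agg <- stats::aggregate(list(n_exons = hit_df$gene),
                            by = list(id = hit_df$id, gene = hit_df$gene),
                            FUN = length)
    agg[order(agg$id, agg$gene), ]
  } else data.frame(id = character(), gene = character(),
                    n_exons = integer())
  list(flags = data.frame(id = deletions$id,
                          exonic = deletions$id %in% hit_df$id,
                          stringsAsFactors = FALSE),
       genes = genes)
}

#' GWAS assignment for one deletion
#'
#' A deletion is GWAS-associated iff at least one LD companion has an
#' association below `p_threshold` (strict); the assigned trait is the
#' association with the smallest p among all companions.
#'
#' @param companion_ids Character vector of companion SNV ids.
#' @param gwas_table data.frame `snv_id`, `trait`, `p`.
#' @param p_threshold Significance threshold (default 1e-8, strict `<`).
#' @return List `associated`, `trait`, `p` (trait/p are `NA` when not
#'   associated).
#' @export
assign_gwas <- function(companion_ids, gwas_table, p_threshold = 1e-8) {
  rows <- gwas_table[gwas_table$snv_id %in% companion_ids &
                       gwas_table$p < p_threshold, , drop = FALSE]
  if (!nrow(rows))
    return(list(associated = FALSE, trait = NA_character_, p = NA_real_))
  best <- rows[which.min(rows$p), ]
  list(associated = TRUE, trait = best$trait, p = best$p)
}

#' Filter deletions by pooled allele frequency
#'
#' The enrichment analyses use deletions with pooled derived frequency
#' above `threshold` in YRI, CEU and CHB combined; the before/after
#' counts are reported via `message()`.
#'
#' @param freqs Pooled frequencies per deletion.
#' @param threshold Strict lower bound (default 0.05).
#' @return Logical keep vector.
#' @export
filter_pooled_frequency <- function(freqs, threshold = 0.05) {
  keep <- freqs > threshold
  message(sprintf("pooled-frequency filter (> %g): %d of %d deletions kept",
                  threshold, sum(keep), length(keep)))
  keep
}

perm_pvalue <- function(obs, perm) {
  (1 + sum(abs(perm) >= abs(obs))) / (length(perm) + 1)
}

#' Permutation test for feature enrichment among ancient deletions
#'
#' Shuffles ancient/non-ancient labels and compares the difference in
#' feature proportions; the empirical p-value uses the add-one correction
#' and the two-sided more-extreme rule `|diff| >= |observed|`.
#'
#' @param labels Logical: ancient (TRUE) / non-ancient per deletion
#'   (pre-filtered to pooled frequency > 5% by the caller).
#' @param feature Logical feature indicator per deletion.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List of class `enrichment_result`: `fold`
#'   (proportion(ancient) / proportion(non-ancient)), `observed`
#'   (difference in proportions), `p`, `n_perm`.
#' @export
permutation_enrichment <- function(labels, feature, n_perm = 10000, seed) {
  labels <- as.logical(labels); feature <- as.logical(feature)
  stopifnot(length(labels) == length(feature))
  if (!any(labels) || !any(!labels))
    stop("both label classes must be non-empty")
  prop_diff <- function(lab) mean(feature[lab]) - mean(feature[!lab])
  obs <- prop_diff(labels)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    prop_diff(sample(labels)), numeric(1)))
  p_anc <- mean(feature[labels]); p_non <- mean(feature[!labels])
  structure(list(fold = p_anc / p_non, observed = obs,
                 p = perm_pvalue(obs, perm), n_perm = n_perm,
                 prop_ancient = p_anc, prop_non_ancient = p_non),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> fold=%.3g diff=%.3g p=%.4g (%d perms)\n",
              x$fold, x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Per-category permutation enrichment
#'
#' Runs [permutation_enrichment()] on the membership indicator of each
#' phenotype category (the 18-way manual grouping of GWAS traits is
#' consumed as a table, not curated here).
#'
#' @param labels Logical ancient labels.
#' @param memberships data.frame `id`, `category` (a deletion may belong
#'   to several categories); `id` must index `labels` via `deletion_ids`.
#' @param deletion_ids Character ids aligned with `labels`.
#' @param categories Character vector of known category names; membership
#'   rows naming an unknown category raise an error.
#' @param n_perm,seed Passed through.
#' @return data.frame per category: `category`, `n_members`, `fold`,
#'   `observed`, `p` (`NA` rows, reported but skipped, for categories
#'   with zero members).
#' @export
category_enrichment <- function(labels, memberships, deletion_ids,
                                categories, n_perm = 10000, seed) {
  unknown <- setdiff(unique(memberships$category), categories)
  if (length(unknown))
    stop("unknown category label(s): ", paste(unknown, collapse = ", "))
  out <- lapply(categories, function(cat) {
    members <- memberships$id[memberships$category == cat]
    feature <- deletion_ids %in% members
    if (!any(feature))
      return(data.frame(category = cat, n_members = 0L, fold = NA_real_,
                        observed = NA_real_, p = NA_real_))
    r <- permutation_enrichment(labels, feature, n_perm = n_perm,
                                seed = substream_seed(seed, cat))
    data.frame(category = cat, n_members = sum(feature), fold = r$fold,
               observed = r$observed, p = r$p)
  })
  do.call(rbind, out)
}

#' Length-percentile permutation test
#'
#' Compares ancient vs non-ancient deletion length percentiles (linear
#' interpolation between order statistics) with label permutation.
#'
#' @param lengths Deletion lengths (bp).
#' @param labels Logical ancient labels (each class needs >= 10 members).
#' @param percentiles Percentile grid.
#' @param n_perm,seed Passed through.
#' @return data.frame per percentile: `percentile`, `ancient`,
#'   `non_ancient`, `ratio`, `observed` (difference), `p`.
#' @export
percentile_length_test <- function(lengths, labels,
                                   percentiles = c(2, 5, 10, 20, 30, 40, 50,
                                                   60, 70, 80, 90, 95, 98),
                                   n_perm = 10000, seed) {
  labels <- as.logical(labels)
  if (sum(labels) < 10 || sum(!labels) < 10)
    stop("each class needs at least 10 members")
  pr <- percentiles / 100
  qdiff <- function(lab) quantile(lengths[lab], pr, names = FALSE) -
    quantile(lengths[!lab], pr, names = FALSE)
  obs_a <- quantile(lengths[labels], pr, names = FALSE)
  obs_n <- quantile(lengths[!labels], pr, names = FALSE)
  obs <- obs_a - obs_n
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    qdiff(sample(labels)), numeric(length(pr))))
  perm <- matrix(perm, nrow = length(pr))
  p <- vapply(seq_along(pr), function(k)
    perm_pvalue(obs[k], perm[k, ]), numeric(1))
  data.frame(percentile = percentiles, ancient = obs_a, non_ancient = obs_n,
             ratio = obs_a / obs_n, observed = obs, p = p)
}
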