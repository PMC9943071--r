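#' LD companions and evolutionary classification of shared deletions
#'
#' Deletions cannot be genotyped directly in archaic VCFs, so their
#' evolutionary history is read off the SNVs in tight linkage
#' disequilibrium with them.  A deletion called present in an archaic
#' genome is *recurrent* if none of its LD companions accompanies it there
#' (the deletion arose twice), *introgressed* if it is absent from Yoruba
#' and a companion sits on a published S*-significant introgressed
#' haplotype, and *ancient* (shared by common descent, predating the
#' AMH-archaic split) otherwise.
#'
#' @name ld_classify
NULL

#' Haplotype-based r-squared between two biallelic variants
#'
#' `r^2 = D^2 / (p_a (1 - p_a) p_b (1 - p_b))` with
#' `D = freq(1, 1) - p_a p_b` computed on phased haplotypes.
#'
#' @param a,b Binary haplotype vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA` when either input is
#'   monomorphic (LD is undefined there).
#' @export
haplotype_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  pa <- mean(a)
  pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  D <- mean(a == 1 & b == 1) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Find SNVs in LD with a deletion
#'
#' Companions are SNVs within `radius` bp of the deletion whose derived
#' allele has haplotypic r-squared strictly greater than `r2_min` with the
#' deletion allele.  Distance is measured from the nearer deletion
#' breakpoint by default (0 for SNVs inside the deletion).
#'
#' @param del_hap Binary deletion haplotype vector (1 = deletion).
#' @param del_start,del_end Deletion interval, 0-based half-open.
#' @param snv_mat Haplotype x SNV binary matrix on the same haplotypes.
#' @param snv_pos SNV positions (0-based bp).
#' @param snv_ids SNV identifiers.
#' @param radius Search radius in bp.
#' @param r2_min Strict lower bound on r-squared.
#' @param distance_from `"breakpoint"` (default) or `"midpoint"`.
#' @return data.frame `snv_id`, `position`, `r2`, `distance`, ordered by
#'   position; zero rows when the deletion has no companion (such
#'   deletions are excluded from classification and reported separately).
#' @export
find_companions <- function(del_hap, del_start, del_end, snv_mat, snv_pos,
                            snv_ids, radius = 50000, r2_min = 0.9,
                            distance_from = c("breakpoint", "midpoint")) {
  distance_from <- match.arg(distance_from)
  stopifnot(nrow(snv_mat) == length(del_hap))
  dist <- if (distance_from == "breakpoint") {
    pmax(0, del_start - snv_pos, snv_pos - (del_end - 1L))
  } else {
    abs(snv_pos - (del_start + del_end) / 2)
  }
  near <- which(dist <= radius)
  if (!length(near))
    return(data.frame(snv_id = character(), position = integer(),
                      r2 = numeric(), distance = numeric()))
  r2 <- vapply(near, function(j) haplotype_r2(del_hap, snv_mat[, j]),
               numeric(1))
  keep <- !is.na(r2) & r2 > r2_min
  out <- data.frame(snv_id = snv_ids[near][keep],
                    position = snv_pos[near][keep],
                    r2 = r2[keep], distance = dist[near][keep],
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Classify one archaic-shared deletion
#'
#' Precedence: recurrence is tested first, then introgression, then the
#' ancient residual.
#'
#' 1. If no companion derived allele is present in any archaic genome that
#'    carries the deletion, the deletion arose independently in the two
#'    lineages: `recurrent`.
#' 2. Else, if the deletion has zero copies in Yoruba and at least one
#'    companion is among the S*-significant introgressed SNVs:
#'    `introgressed`.
#' 3. Else: `ancient` (shared by common descent).
#'
#' @param companions Companion data.frame from [find_companions()].
#' @param archaic_presence Named logical: deletion call per archaic genome.
#' @param archaic_snv_presence Genome x SNV logical matrix (derived allele
#'   carried by that genome), with SNV ids as column names.
#' @param sstar_snvs Character vector of S*-significant SNV ids.
#' @param yri_allele_count Deletion allele count in the YRI sample.
#' @return One of `"recurrent"`, `"introgressed"`, `"ancient"`.
#' @export
classify_shared_deletion <- function(companions, archaic_presence,
                                     archaic_snv_presence, sstar_snvs,
                                     yri_allele_count) {
  carriers <- names(archaic_presence)[archaic_presence %in% TRUE]
  if (!length(carriers))
    stop("deletion is not shared with any archaic genome; ",
         "non-shared deletions are human_specific upstream")
  if (nrow(companions) == 0L)
    stop("deletion has no LD companions; exclude it before classification")
  comp_ids <- intersect(companions$snv_id, colnames(archaic_snv_presence))
  accompanied <- length(comp_ids) > 0L &&
    any(archaic_snv_presence[carriers, comp_ids, drop = FALSE])
  if (!accompanied) return("recurrent")
  if (yri_allele_count == 0L && any(companions$snv_id %in% sstar_snvs))
    return("introgressed")
  "ancient"
}

#' Classify every deletion of a cohort
#'
#' Deletions not called in any archaic genome are `human_specific`;
#' shared deletions are partitioned by [classify_shared_deletion()].
#' Deletions without LD companions cannot be vetted for recurrence or
#' introgression and are excluded (reported under `excluded`), mirroring
#' the retention of only companion-tagged deletions in the deletion
#' dataset.
#'
#' @param deletion_ids Character vector of deletion ids.
#' @param companions_list Named list of companion data.frames.
#' @param shared Named logical-matrix rows or list: per-deletion named
#'   logical vector of archaic presence calls (deletion x genome matrix).
#' @param archaic_snv_presence Genome x SNV logical matrix.
#' @param sstar_snvs Character vector of S*-significant SNV ids.
#' @param yri_allele_counts Named integer vector of YRI deletion allele
#'   counts.
#' @return List with `assignments` (data.frame `id`, `category`),
#'   `summary` (counts and proportions per category) and `excluded`
#'   (ids without companions).
#' @export
classify_all <- function(deletion_ids, companions_list, shared,
                         archaic_snv_presence, sstar_snvs,
                         yri_allele_counts) {
  stopifnot(is.matrix(shared), all(deletion_ids %in% rownames(shared)))
  excluded <- character(0)
  cat_of <- character(0)
  for (id in deletion_ids) {
    comp <- companions_list[[id]]
    if (is.null(comp) || nrow(comp) == 0L) {
      excluded <- c(excluded, id)
      next
    }
    pres <- shared[id, ]
    cat_of[id] <- if (!any(pres %in% TRUE)) "human_specific" else {
      classify_shared_deletion(comp, pres, archaic_snv_presence,
                               sstar_snvs, yri_allele_counts[[id]])
    }
  }
  levels <- c("human_specific", "recurrent", "introgressed", "ancient")
  counts <- table(factor(cat_of, levels = levels))
  assignments <- data.frame(id = names(cat_of), category = unname(cat_of),
                            stringsAsFactors = FALSE)
  list(assignments = assignments,
       summary = data.frame(category = levels,
                            n = as.integer(counts),
                            proportion = as.numeric(counts) / max(1, sum(counts))),
       excluded = excluded)
}
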