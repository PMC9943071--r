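#' Read-depth genotyping of deletions in archaic genomes
#'
#' A deletion that is present in an archaic genome shows up as a drop in
#' read depth over the deletion window.  Reads (BED-style intervals) are
#' counted per candidate window, normalized by window size, converted to
#' modified Z-scores (median/MAD, robust to the outliers that are the very
#' signal being sought), and windows below a conservative threshold are
#' called deleted.
#'
#' @name archaic_depth
NULL

check_intervals <- function(x, what) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop(sprintf("%s must have columns chrom, start, end", what))
  bad <- which(x$end <= x$start)
  if (length(bad))
    stop(sprintf("%s: end <= start at line%s %s", what,
                 if (length(bad) > 1) "s" else "",
                 paste(head(bad, 5L), collapse = ", ")))
  invisible(x)
}

#' Count reads intersecting deletion windows
#'
#' A read is counted for a window iff their 0-based half-open intervals
#' overlap by at least 1 bp; a read spanning two windows counts in both.
#'
#' @param reads data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param windows data.frame with `chrom`, `start`, `end`, `id`.
#' @return Integer vector of counts, one per window row.
#' @export
count_intersecting_reads <- function(reads, windows) {
  check_intervals(reads, "reads")
  check_intervals(windows, "windows")
  counts <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    ri <- reads$chrom == ch
    if (!any(ri)) next
    # half-open [s, e) becomes the 1-based closed interval [s + 1, e]
    wr <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    rr <- IRanges::IRanges(reads$start[ri] + 1L, reads$end[ri])
    counts[wi] <- IRanges::countOverlaps(wr, rr)
  }
  counts
}

#' Normalized read depth of a window
#'
#' @param count Number of reads intersecting the window.
#' @param window_size_bp Window size in bp.
#' @return `count / window_size_bp`, reads per bp.
#' @export
normalized_depth <- function(count, window_size_bp) {
  if (any(window_size_bp <= 0)) stop("window size must be positive")
  count / window_size_bp
}

#' Modified Z-scores of normalized depths
#'
#' `ModZ_i = (r_i - median(R)) / MAD(R)` with
#' `MAD = median(|r_i - median(R)|)`.  No consistency constant is applied
#' by default; the conservative calling threshold of -5 is calibrated to
#' the unscaled score.  Computed per genome across all candidate windows.
#'
#' @param depths Numeric vector of normalized depths (>= 2 windows).
#' @param scaling_constant Multiply by the conventional 0.6745
#'   normal-consistency factor (off by default).
#' @return List with `modz`, `median`, `mad` and `degenerate`.  When the
#'   MAD is zero the spread is degenerate and all scores are `NA`.
#' @export
modified_z <- function(depths, scaling_constant = FALSE) {
  if (length(depths) < 2L) stop("need at least two windows")
  med <- median(depths)
  mad0 <- median(abs(depths - med))
  if (mad0 == 0) {
    return(list(modz = rep(NA_real_, length(depths)), median = med,
                mad = 0, degenerate = TRUE))
  }
  z <- (depths - med) / mad0
  if (scaling_constant) z <- z * 0.6745
  list(modz = z, median = med, mad = mad0, degenerate = FALSE)
}

#' Call deletions from modified Z-scores
#'
#' A window is called deleted iff its modified Z-score is strictly below
#' `threshold` (default -5, more conservative than the +-3.5 customary for
#' outlier screens).
#'
#' @param modz Numeric vector of modified Z-scores (or the list returned by
#'   [modified_z()]).
#' @param threshold Calling threshold.
#' @return Logical vector; `NA` where the score is degenerate.
#' @export
call_deletions <- function(modz, threshold = -5) {
  if (is.list(modz)) modz <- modz$modz
  modz < threshold
}

#' Depth-genotype candidate windows in archaic genomes
#'
#' Runs the full read-depth pipeline for each archaic genome: count reads
#' per window, normalize by window size, score with [modified_z()] and call
#' with [call_deletions()].
#'
#' @param reads_by_genome Named list of read data.frames, one per genome.
#' @param windows Candidate windows (`chrom`, `start`, `end`, `id`).
#' @param threshold Modified Z-score calling threshold.
#' @param scaling_constant Passed to [modified_z()].
#' @return data.frame with one row per genome x window: `genome`, `id`,
#'   `count`, `r`, `modz`, `call`.
#' @export
archaic_depth_profile <- function(reads_by_genome, windows, threshold = -5,
                                  scaling_constant = FALSE) {
  stopifnot(is.list(reads_by_genome), !is.null(names(reads_by_genome)))
  check_intervals(windows, "windows")
  out <- lapply(names(reads_by_genome), function(g) {
    counts <- count_intersecting_reads(reads_by_genome[[g]], windows)
    r <- normalized_depth(counts, windows$end - windows$start)
    mz <- modified_z(r, scaling_constant = scaling_constant)
    data.frame(genome = g, id = windows$id, count = counts, r = r,
               modz = mz$modz, call = call_deletions(mz, threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-genome presence matrix and the shared-with-archaics reduction
#'
#' @param profile Output of [archaic_depth_profile()].
#' @return List with `presence` (windows x genomes logical matrix) and
#'   `shared` (logical: called deleted in at least one genome).
#' @export
presence_matrix <- function(profile) {
  genomes <- unique(profile$genome)
  ids <- unique(profile$id)
  m <- matrix(NA, length(ids), length(genomes),
              dimnames = list(ids, genomes))
  for (g in genomes) {
    sub <- profile[profile$genome == g, ]
    m[match(sub$id, ids), g] <- sub$call
  }
  list(presence = m, shared = rowSums(m, na.rm = TRUE) > 0)
}
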