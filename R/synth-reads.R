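#' Simulate archaic read intervals over deletion loci
#'
#' Reads of fixed length are placed uniformly along each deletion locus at
#' the configured mean depth.  In genomes that the planted truth marks as
#' deletion carriers, reads overlapping the deleted window are thinned to
#' `residual_depth_fraction` of the mean depth (the default of 0 models a
#' homozygous deletion; the depth caller does not distinguish het from
#' hom).
#'
#' @param deletions Deletion interval table from [generate_cohort()].
#' @param truth Planted-truth table from [generate_cohort()].
#' @param config The [synth_config()].
#' @return Named list (one per archaic genome) of read data.frames with
#'   `chrom`, `start`, `end` (0-based half-open).
#' @export
generate_archaic_reads <- function(deletions, truth, config) {
  stopifnot(inherits(config, "synth_config"))
  rl <- config$read_length
  margin <- 2000L
  rate <- config$mean_depth / rl          # read starts per bp
  out <- list()
  for (g in config$archaic_genomes) {
    with_seed(substream_seed(config$seed, paste0("reads_", g)), {
      rows <- vector("list", nrow(deletions))
      for (i in seq_len(nrow(deletions))) {
        d <- deletions[i, ]
        lo <- max(0L, d$start - margin)
        hi <- d$end + margin
        # start density must be `rate` per bp over the placement span so
        # that windows see mean_depth coverage without edge inflation
        n_reads <- rpois(1, rate * (hi - rl - lo))
        starts <- as.integer(runif(n_reads, lo, hi - rl))
        carriers <- strsplit(truth$archaic_carriers[truth$id == d$id],
                             ",")[[1]]
        if (g %in% carriers) {
          hits <- starts + rl > d$start & starts < d$end
          drop <- hits & runif(n_reads) >= config$residual_depth_fraction
          starts <- starts[!drop]
        }
        if (length(starts))
          rows[[i]] <- data.frame(chrom = d$chrom, start = starts,
                                  end = starts + rl,
                                  stringsAsFactors = FALSE)
      }
      out[[g]] <- do.call(rbind, rows)
    })
  }
  out
}
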