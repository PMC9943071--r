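#' Write a synthetic cohort and its side tables to disk
#'
#' Emits the standard file formats of the real-data pipeline: a phased
#' VCF (biallelic SNVs with an `AA` ancestral-allele INFO tag; deletions
#' as `SVTYPE=DEL` records with `END`), per-genome read BED files, an
#' exon BED, and TSV side tables.  Internal coordinates are 0-based
#' half-open; VCF emission converts to 1-based.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @param reads Optional result of [generate_archaic_reads()].
#' @param tables Optional result of [generate_annotation_tables()].
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir, reads = NULL, tables = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"))
  write_cohort_vcf(cohort, paths["vcf"])
  if (!is.null(reads)) {
    for (g in names(reads)) {
      p <- file.path(dir, sprintf("reads_%s.bed", g))
      write_bed(reads[[g]], p)
      paths[paste0("reads_", g)] <- p
    }
  }
  if (!is.null(tables)) {
    for (nm in names(tables)) {
      if (nm == "exons") {
        p <- file.path(dir, "exons.bed")
        write.table(tables$exons, p, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
      } else {
        p <- file.path(dir, sprintf("%s.tsv", nm))
        write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
      paths[nm] <- p
    }
  }
  invisible(paths)
}

#' Write BED intervals (0-based half-open, three columns)
#' @param x data.frame with `chrom`, `start`, `end`.
#' @param path Output file.
#' @export
write_bed <- function(x, path) {
  write.table(x[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Phased VCF emission.  The AMH diploid samples are consecutive haplotype
# pairs; archaic genomes appear as two-haplotype samples as well.
write_cohort_vcf <- function(cohort, path) {
  vm <- cohort$variants
  sites <- cohort$sites
  pops <- cohort$config$populations
  dip_names <- unlist(lapply(names(pops), function(p)
    sprintf("%s_%03d", p, seq_len(pops[[p]]))))
  sample_names <- c(dip_names, cohort$config$archaic_genomes)
  n_hap <- nrow(vm$mat)
  stopifnot(n_hap == 2L * length(sample_names))

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ancientdel-synth",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")), con)
  ord <- order(sites$chrom, sites$pos)
  for (i in ord) {
    hap <- vm$mat[, i]
    gt <- paste(hap[seq(1, n_hap, 2)], hap[seq(2, n_hap, 2)], sep = "|")
    if (sites$type[i] == "del") {
      d <- cohort$deletions[cohort$deletions$id == sites$id[i], ]
      info <- sprintf("AA=A;SVTYPE=DEL;END=%d", d$end)  # 0-based end == 1-based inclusive
      ref <- "A"; alt <- "<DEL>"
    } else {
      info <- "AA=A"
      ref <- "A"; alt <- "G"
    }
    writeLines(paste(c(sites$chrom[i], sites$pos[i] + 1L, sites$id[i], ref,
                       alt, ".", "PASS", info, "GT", gt), collapse = "\t"),
               con)
  }
  invisible(path)
}
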