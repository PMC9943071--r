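#' @useDynLib ancientdel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rbinom rpois runif rnorm quantile sd prcomp
#'   pchisq ks.test wilcox.test setNames cor complete.cases
#' @importFrom utils write.table read.table head
NULL

# Derive a reproducible sub-seed from a root seed and a stream name, so that
# independent generators never consume from the same stream.  Kept below
# 2^31 - 1 to stay a valid R integer seed.
substream_seed <- function(seed, name, k = 0L) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 1000003 * 7919 + h * 104729 +
                as.numeric(k) * 15485863) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (positive && x <= 0))
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}
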