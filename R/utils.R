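#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n count across
#' @importFrom stats lm coef rnorm rpois runif rgamma rgeom median setNames
#'   complete.cases
#' @importFrom utils head tail write.table read.table
#' @importFrom data.table data.table setkey setorder rbindlist .N
NULL

.datatable.aware <- TRUE

# 0-based half-open substring of a chromosome string
seq_sub <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

# derive a reproducible substream seed (< 2^31) from a master seed and offsets
substream_seed <- function(seed, ...) {
  off <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in off) s <- (s * 48271 + as.double(o) + 1) %% 2147483647
  as.integer(s)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# running median smoother; width 1 disables
smooth_median <- function(x, width = 3L) {
  if (width <= 1L || length(x) < width) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  out <- stats::runmed(x, k = width, endrule = "keep")
  as.numeric(out)
}
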