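#' In-silico restriction digestion
#'
#' Cuts every chromosome at the annotated recognition sites of `enzyme`
#' plus any `extra_cuts` (e.g. the HO break itself), returning the
#' resulting fragments. Fragments tile each chromosome without overlap,
#' so their lengths sum to the chromosome length.
#'
#' @param genome a `genome_map`.
#' @param enzyme enzyme name present in `genome$restriction_sites`.
#' @param extra_cuts optional named integer vector of additional cut
#'   coordinates (names are chromosome names), e.g. `c(chrIII = ho_site)`.
#' @return a tibble with columns `chromosome`, `start`, `end`, `length`
#'   (0-based half-open coordinates).
#' @export
in_silico_digest <- function(genome, enzyme = "EcoRI", extra_cuts = NULL) {
  if (!enzyme %in% names(genome$restriction_sites))
    abort(sprintf("unknown enzyme '%s'", enzyme))
  sites <- genome$restriction_sites[[enzyme]]
  out <- lapply(names(genome$chromosomes), function(nm) {
    len <- nchar(genome$chromosomes[nm])
    cuts <- sites[[nm]] %||% integer(0)
    if (!is.null(extra_cuts)) {
      ec <- extra_cuts[names(extra_cuts) == nm]
      assert_that(all(ec >= 0 & ec <= len), "extra cut out of bounds")
      cuts <- c(cuts, as.integer(ec))
    }
    bounds <- sort(unique(c(0L, cuts, len)))
    tibble(chromosome = nm,
           start = head(bounds, -1L),
           end = tail(bounds, -1L))
  })
  bind_rows(out) |> mutate(length = .data$end - .data$start)
}

#' Locate the digest fragment containing a probe
#'
#' @param fragments output of [in_silico_digest()].
#' @param chromosome,start,end probe interval (0-based half-open; a
#'   zero-length probe at a fragment start hits that fragment).
#' @return the single matching fragment row.
#' @export
fragment_for_probe <- function(fragments, chromosome, start, end) {
  hit <- fragments |> filter(.data$chromosome == !!chromosome)
  if (end > start) {
    hit <- hit |> filter(.data$start <= !!start, .data$end >= !!end)
  } else {
    # zero-length probe: boundary convention is start-inclusive
    hit <- hit |> filter(.data$start <= !!start, .data$end > !!start)
  }
  if (nrow(hit) == 0)
    abort("probe spans a cut site or lies outside the digested chromosome")
  hit
}
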