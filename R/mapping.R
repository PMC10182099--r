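#' Build an exact-match k-mer index of the genome
#'
#' Every length-`k` substring of both strands is stored in a keyed table,
#' so a read maps if and only if it equals the reference exactly at some
#' locus (the 0-mismatch, end-to-end alignment contract). `k` is the read
#' length (default 75).
#'
#' @param genome a `genome_map`, or a named character vector of sequences.
#' @param k k-mer / read length.
#' @return an object of class `kmer_index`.
#' @export
build_index <- function(genome, k = 75L) {
  chroms <- if (inherits(genome, "genome_map")) genome$chromosomes else genome
  assert_that(k <= min(nchar(chroms)), "k exceeds the shortest chromosome")
  tabs <- lapply(names(chroms), function(nm) {
    seq <- chroms[nm]
    n <- nchar(seq) - k + 1L
    starts <- seq_len(n)
    fwd <- substring(seq, starts, starts + k - 1L)
    rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
    data.table::data.table(
      kmer = c(fwd, rev),
      chrom = nm,
      pos = rep(starts - 1L, 2L),        # 0-based leftmost coordinate
      strand = rep(c("+", "-"), each = n)
    )
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  structure(list(table = dt, k = as.integer(k), chrom_lengths = nchar(chroms)),
            class = "kmer_index")
}

#' Look up all perfect-match loci of a k-mer
#'
#' @param index a `kmer_index`.
#' @param kmer character vector of sequences of length `k`.
#' @return tibble (kmer, chrom, pos, strand), zero rows when unmatched.
#' @export
lookup_kmer <- function(index, kmer) {
  q <- data.table::data.table(kmer = as.character(kmer))
  hits <- index$table[q, nomatch = NULL, on = "kmer",
                      allow.cartesian = TRUE]
  as_tibble(hits)
}

#' Map reads under the 0-mismatch contract
#'
#' Reads whose length differs from the index `k`, or that contain
#' non-ACGT symbols, are reported unmapped (but still counted). Reads
#' matching more than one locus are flagged non-unique; downstream
#' coverage and discordant-pair analyses drop them (the reporting of one
#' arbitrary locus by `-k 1`-style aligners is not reproducible; on a
#' repeat-free genome the two conventions coincide).
#'
#' @param reads character vector of read sequences.
#' @param index a `kmer_index`.
#' @param read_id optional ids (defaults to seq_along).
#' @return tibble (read_id, mapped, chromosome, start, strand, n_hits,
#'   unique): `start` is the 0-based leftmost reference coordinate; for
#'   multi-hit reads the first locus in genome order is reported.
#' @export
map_reads <- function(reads, index, read_id = NULL) {
  read_id <- read_id %||% as.character(seq_along(reads))
  ok <- nchar(reads) == index$k & !grepl("[^ACGT]", reads)
  res <- tibble(read_id = read_id, seq = reads, mapped = FALSE,
                chromosome = NA_character_, start = NA_integer_,
                strand = NA_character_, n_hits = 0L, unique = FALSE)
  if (any(ok)) {
    q <- data.table::data.table(kmer = reads[ok], qi = which(ok))
    hits <- index$table[q, on = "kmer", nomatch = NULL,
                        allow.cartesian = TRUE]
    if (nrow(hits) > 0) {
      data.table::setorder(hits, qi, chrom, pos, strand)
      nh <- hits[, list(n_hits = .N, chrom = chrom[1L], pos = pos[1L],
                        strand = strand[1L]), by = "qi"]
      res$mapped[nh$qi] <- TRUE
      res$chromosome[nh$qi] <- nh$chrom
      res$start[nh$qi] <- nh$pos
      res$strand[nh$qi] <- nh$strand
      res$n_hits[nh$qi] <- nh$n_hits
      res$unique[nh$qi] <- nh$n_hits == 1L
    }
  }
  res |> select(-"seq")
}

#' @rdname map_reads
#' @param read a single read sequence.
#' @export
map_read <- function(read, index) {
  map_reads(read, index)[1L, ]
}

#' Classify mate alignments into pair classes
#'
#' A pair is `discordant` iff both mates map uniquely to different
#' chromosomes (the filter used for gene-conversion boundary mapping);
#' `concordant` iff both map uniquely to the same chromosome on opposite
#' strands within the insert bounds; `unmapped` iff neither mate maps;
#' anything else (one mate unmapped, a multi-mapped mate, or an aberrant
#' same-chromosome geometry) is `partial`.
#'
#' @param aln1,aln2 alignment tibbles from [map_reads()] for mates 1/2,
#'   row-aligned by pair.
#' @param pair_id optional pair identifiers.
#' @param insert_bounds `c(min, max)` allowed outer insert size for
#'   concordant pairs.
#' @param read_length read length (for insert computation).
#' @return tibble with per-mate coordinates and a `class` column.
#' @export
pair_reads <- function(aln1, aln2, pair_id = NULL,
                       insert_bounds = c(75, 2000), read_length = 75L) {
  assert_that(nrow(aln1) == nrow(aln2), "mate tables must be row-aligned")
  pair_id <- pair_id %||% aln1$read_id
  both_unique <- aln1$unique & aln2$unique
  same_chrom <- both_unique & aln1$chromosome == aln2$chromosome
  insert <- pmax(aln1$start + read_length, aln2$start + read_length) -
    pmin(aln1$start, aln2$start)
  concordant <- same_chrom & aln1$strand != aln2$strand &
    insert >= insert_bounds[1] & insert <= insert_bounds[2]
  discordant <- both_unique & aln1$chromosome != aln2$chromosome
  cls <- dplyr::case_when(
    discordant ~ "discordant",
    concordant ~ "concordant",
    !aln1$mapped & !aln2$mapped ~ "unmapped",
    .default = "partial"
  )
  tibble(pair_id = pair_id,
         chrom1 = aln1$chromosome, start1 = aln1$start, strand1 = aln1$strand,
         unique1 = aln1$unique,
         chrom2 = aln2$chromosome, start2 = aln2$start, strand2 = aln2$strand,
         unique2 = aln2$unique,
         class = cls)
}
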