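#' Emit paired-end reads from a simulated population
#'
#' Fragments are sampled uniformly from the double-stranded DNA of the
#' population (single-stranded regions yield no fragments, as in a
#' tagmentation library), with truncated-normal insert sizes. Mate 1 is
#' the forward strand of the fragment start, mate 2 the reverse
#' complement of the fragment end. Fragments from repaired cells carry
#' donor alleles at every polymorphic position inside the cell's
#' conversion tract (including the uncleavable donor core). No sequencing
#' errors are modelled: under the 0-mismatch alignment contract errors
#' only discard reads.
#'
#' @param population a `population_state`.
#' @param genome the `genome_map` used to simulate it.
#' @param params the [sim_params()] (library parameters are read here).
#' @param seed master seed; the substream also keys on the population's
#'   time point.
#' @param n_pairs override the pair count (default
#'   `depth * genome_size / (2 * read_length)`).
#' @return a tibble of class `read_pairs`: `pair_id`, `cell`,
#'   `chromosome`, `frag_start`, `frag_end` (truth interval, 0-based
#'   half-open), `n_converted` (donor alleles substituted), `read1`,
#'   `read2`. Attribute `total_reads` counts all emitted reads.
#' @export
emit_read_pairs <- function(population, genome, params, seed = 1L,
                            n_pairs = NULL) {
  rl <- params$read_length
  lens <- nchar(genome$chromosomes)
  G <- sum(lens)
  n_pairs <- n_pairs %||% round(params$depth * G / (2 * rl))
  assert_that(n_pairs > 0, "depth must yield at least one pair")
  t_ms <- round(as.numeric(attr(population, "time") %||% 0) * 1000)
  set.seed(substream_seed(seed, 20, t_ms))

  ds <- dsdna_intervals(population, genome)
  ds$len <- ds$end - ds$start
  ds <- ds[ds$len >= rl, , drop = FALSE]
  if (nrow(ds) == 0) {
    warn("no double-stranded DNA to sample; returning empty read set")
    return(structure(tibble(pair_id = character(0)), class = c("read_pairs", "tbl_df", "tbl", "data.frame"),
                     total_reads = 0L, read_length = rl))
  }

  # uniform anchor base over all duplex bases, fragment extended left or
  # right and truncated at the duplex-interval edge (a tagmentation
  # fragment cannot span a single-stranded junction); fragments shorter
  # than one read are dropped
  idx <- sample.int(nrow(ds), n_pairs, replace = TRUE, prob = ds$len)
  ins <- pmax(rl, round(rnorm(n_pairs, params$insert_mean, params$insert_sd)))
  anchor <- ds$start[idx] + floor(runif(n_pairs) * ds$len[idx])
  right <- runif(n_pairs) < 0.5
  fstart <- ifelse(right, anchor, pmax(anchor + 1 - ins, ds$start[idx]))
  fend <- ifelse(right, pmin(anchor + ins, ds$end[idx]), anchor + 1)
  keep <- fend - fstart >= rl
  frag <- tibble(cell = ds$cell[idx], chromosome = ds$chromosome[idx],
                 frag_start = fstart, frag_end = fend)[keep, , drop = FALSE]

  # extract fragment sequences per chromosome
  frag$seq <- NA_character_
  for (nm in unique(frag$chromosome)) {
    sel <- frag$chromosome == nm
    frag$seq[sel] <- substring(genome$chromosomes[nm],
                               frag$frag_start[sel] + 1L, frag$frag_end[sel])
  }

  # donor-allele substitution inside conversion tracts of repaired cells
  frag$n_converted <- 0L
  sites <- bind_rows(genome$polymorphisms, genome$ho_inc_variant)
  rec <- genome$config$recipient
  ho <- genome$ho_site
  repd <- population[population$repaired, , drop = FALSE]
  if (nrow(repd) > 0) {
    cand <- which(frag$chromosome == rec & frag$cell %in% repd$cell &
                    frag$frag_end > ho + min(sites$offset_from_ho) &
                    frag$frag_start <= ho + max(sites$offset_from_ho))
    ci <- match(frag$cell[cand], repd$cell)
    for (j in seq_along(cand)) {
      i <- cand[j]
      gl <- repd$gc_left_boundary[ci[j]]; gr <- repd$gc_right_boundary[ci[j]]
      hit <- sites[sites$offset_from_ho >= gl & sites$offset_from_ho <= gr &
                     sites$recipient_pos >= frag$frag_start[i] &
                     sites$recipient_pos < frag$frag_end[i], , drop = FALSE]
      if (nrow(hit) == 0) next
      s <- frag$seq[i]
      at <- hit$recipient_pos - frag$frag_start[i] + 1L
      for (k in seq_along(at)) substr(s, at[k], at[k]) <- hit$donor_allele[k]
      frag$seq[i] <- s
      frag$n_converted[i] <- nrow(hit)
    }
  }

  out <- frag |>
    mutate(pair_id = sprintf("sim_%06d", dplyr::row_number()),
           read1 = substring(.data$seq, 1L, rl),
           read2 = revcomp(substring(.data$seq,
                                     .data$frag_end - .data$frag_start - rl + 1L,
                                     .data$frag_end - .data$frag_start))) |>
    select("pair_id", "cell", "chromosome", "frag_start", "frag_end",
           "n_converted", "read1", "read2")
  structure(out, class = c("read_pairs", class(out)),
            total_reads = 2L * nrow(out), read_length = rl,
            time = attr(population, "time"))
}

#' Write simulated read pairs as FASTQ (plus a truth table)
#'
#' @param pairs a `read_pairs` tibble.
#' @param r1,r2 FASTQ paths for mates 1 and 2 (constant Phred 40).
#' @param truth optional TSV path for the ground-truth fragment table.
#' @return the paths, invisibly.
#' @export
write_read_pairs <- function(pairs, r1, r2, truth = NULL) {
  q1 <- Biostrings::BStringSet(strrep("I", nchar(pairs$read1)))
  q2 <- Biostrings::BStringSet(strrep("I", nchar(pairs$read2)))
  s1 <- Biostrings::DNAStringSet(pairs$read1)
  s2 <- Biostrings::DNAStringSet(pairs$read2)
  names(s1) <- paste0(pairs$pair_id, "/1")
  names(s2) <- paste0(pairs$pair_id, "/2")
  Biostrings::writeXStringSet(s1, r1, format = "fastq", qualities = q1)
  Biostrings::writeXStringSet(s2, r2, format = "fastq", qualities = q2)
  if (!is.null(truth))
    write.table(pairs |> select(-"read1", -"read2"), truth,
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(r1 = r1, r2 = r2, truth = truth))
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path.
#' @return tibble (id, seq).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(id = names(x), seq = as.character(x))
}
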