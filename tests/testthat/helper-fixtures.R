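# Shared fixtures, built once per test run and memoised. The test genome
# is a compact version of the default design: same donor-insert geometry
# and polymorphism layout, shorter chromosomes and a proportionally
# placed control region so simulations stay fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

test_genome_config <- function(...) {
  genome_config(
    recipient_length = 60000L, donor_length = 60000L,
    background_length = 20000L, ho_site = 30000L,
    donor_insert_start = 10000L, control_region = c(20000L, 50000L),
    block_offset = -25000L, ...
  )
}

test_genome <- function() {
  memo("test_genome", build_reference(test_genome_config(), seed = 7))
}

test_index <- function() {
  memo("test_index", build_index(test_genome(), k = 75L))
}

# map one timepoint of a simulation down to a scaled coverage track
sim_track <- function(genome, params, t, seed, index = test_index()) {
  pop <- simulate_population(params, t, genome, seed = seed)
  rp <- emit_read_pairs(pop, genome, params, seed = seed)
  a1 <- map_reads(rp$read1, index, read_id = rp$pair_id)
  a2 <- map_reads(rp$read2, index, read_id = rp$pair_id)
  list(pop = pop, reads = rp, aln1 = a1, aln2 = a2,
       track = rpgc_scale(per_base_coverage(
         dplyr::bind_rows(a1, a2), nchar(genome$chromosomes))))
}

# hand-built ratio_profile tibble for metric unit tests
fake_profile <- function(values, bin = 100L, chromosome = "chrIII",
                         timepoint = NA_real_) {
  n <- length(values)
  out <- tibble::tibble(chromosome = chromosome,
                        bin_start = (seq_len(n) - 1L) * bin,
                        bin_end = seq_len(n) * bin,
                        value = values, n = bin, timepoint = timepoint)
  class(out) <- c("ratio_profile", class(out))
  out
}
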