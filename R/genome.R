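#' Configuration for the synthetic recipient/donor reference genome
#'
#' Defaults encode the geometry of the interchromosomal gene-conversion
#' assay strain: a cleavable HO site on the recipient chromosome (chrIII),
#' a 1.3-kb donor insert on chrV made of two homology arms flanking an
#' uncleavable HO-inc site, 23 single-nucleotide polymorphisms spread over
#' the arms (three of which create EcoRI sites on the donor), recipient
#' EcoRI sites placed 2.5 kb left and 4.3 kb right of the cut (6.8-kb
#' uncut fragment, 2.5-kb cut fragment), a 120-kb control region on chrV,
#' a resection-blocking element 32 kb left of the break, and a third
#' chromosome (chrVIII) uninvolved in repair.
#'
#' All coordinates are 0-based half-open; `ho_site` is the cut coordinate
#' (the phosphodiester bond 5' of that position is cleaved).
#'
#' @param recipient,donor,background chromosome names.
#' @param recipient_length,donor_length,background_length chromosome sizes (nt).
#' @param ho_site cut coordinate on the recipient chromosome.
#' @param arm_length homology arm length (nt), both sides.
#' @param ho_core_length length of the HO recognition core straddling the cut.
#' @param donor_insert_start start of the donor insert on the donor chromosome.
#' @param poly_spacing,poly_first_offset polymorphism layout within the arms:
#'   sites sit at `±(poly_first_offset + poly_spacing * 0:(n-1))` from the cut.
#' @param n_poly_left,n_poly_right polymorphism counts per arm (12 + 11 = 23).
#' @param ecori_offsets offsets (from the cut) of the polymorphisms whose donor
#'   allele creates an EcoRI site; must be a subset of the polymorphism offsets.
#' @param recipient_ecori_offsets EcoRI cut coordinates on the recipient,
#'   relative to `ho_site` (default -2500 and +4300).
#' @param control_region half-open interval on the donor chromosome used for
#'   between-sample normalization (default 210000-330000).
#' @param block_offset position of the resection-blocking (LTR-like) element
#'   relative to the cut; negative = left side.
#' @return a list of class `genome_config`.
#' @export
genome_config <- function(recipient = "chrIII",
                          donor = "chrV",
                          background = "chrVIII",
                          recipient_length = 120000L,
                          donor_length = 340000L,
                          background_length = 40000L,
                          ho_site = 60000L,
                          arm_length = 638L,
                          ho_core_length = 24L,
                          donor_insert_start = 100000L,
                          poly_spacing = 55L,
                          poly_first_offset = 25L,
                          n_poly_left = 12L,
                          n_poly_right = 11L,
                          ecori_offsets = c(-245L, 245L, 520L),
                          recipient_ecori_offsets = c(-2500L, 4300L),
                          control_region = c(210000L, 330000L),
                          block_offset = -32000L) {
  cfg <- list(
    recipient = recipient, donor = donor, background = background,
    recipient_length = as.integer(recipient_length),
    donor_length = as.integer(donor_length),
    background_length = as.integer(background_length),
    ho_site = as.integer(ho_site),
    arm_length = as.integer(arm_length),
    ho_core_length = as.integer(ho_core_length),
    donor_insert_start = as.integer(donor_insert_start),
    poly_spacing = as.integer(poly_spacing),
    poly_first_offset = as.integer(poly_first_offset),
    n_poly_left = as.integer(n_poly_left),
    n_poly_right = as.integer(n_poly_right),
    ecori_offsets = as.integer(ecori_offsets),
    recipient_ecori_offsets = as.integer(recipient_ecori_offsets),
    control_region = as.integer(control_region),
    block_offset = as.integer(block_offset)
  )
  validate_genome_config(cfg)
  structure(cfg, class = "genome_config")
}

validate_genome_config <- function(cfg) {
  half_core <- cfg$ho_core_length %/% 2L
  assert_that(cfg$arm_length > 0 && cfg$poly_spacing > 0 &&
                cfg$recipient_length > 0 && cfg$donor_length > 0,
              "arm lengths, spacing and chromosome lengths must be positive")
  assert_that(cfg$arm_length >= cfg$poly_spacing,
              "homology arm shorter than the polymorphism spacing")
  max_left <- cfg$poly_first_offset + cfg$poly_spacing * (cfg$n_poly_left - 1L)
  max_right <- cfg$poly_first_offset + cfg$poly_spacing * (cfg$n_poly_right - 1L)
  assert_that(max_left <= cfg$arm_length + half_core - 1L &&
                max_right <= cfg$arm_length + half_core - 1L,
              "polymorphisms do not fit inside the homology arms")
  assert_that(cfg$poly_first_offset > half_core,
              "first polymorphism would fall inside the HO core")
  offs <- poly_offsets(cfg)
  assert_that(all(cfg$ecori_offsets %in% offs),
              "ecori_offsets must be existing polymorphism offsets")
  assert_that(cfg$control_region[2] <= cfg$donor_length,
              "control region exceeds the donor chromosome")
  ins_end <- cfg$donor_insert_start + 2L * cfg$arm_length + cfg$ho_core_length
  assert_that(ins_end <= cfg$control_region[1] ||
                cfg$donor_insert_start >= cfg$control_region[2],
              "control region overlaps the donor insert")
  assert_that(cfg$ho_site + cfg$block_offset > 0,
              "blocking element falls outside the recipient chromosome")
  arm_span <- cfg$arm_length + half_core
  assert_that(cfg$ho_site - arm_span - 6L > 0 &&
                cfg$ho_site + arm_span + 6L < cfg$recipient_length,
              "homology region exceeds recipient chromosome bounds")
  cuts <- cfg$ho_site + cfg$recipient_ecori_offsets
  assert_that(all(cuts > 0 & cuts < cfg$recipient_length),
              "recipient EcoRI sites out of bounds")
  invisible(cfg)
}

# signed polymorphism offsets from the cut, left then right, ascending
poly_offsets <- function(cfg) {
  left <- -(cfg$poly_first_offset + cfg$poly_spacing * seq(cfg$n_poly_left - 1L, 0L))
  right <- cfg$poly_first_offset + cfg$poly_spacing * seq(0L, cfg$n_poly_right - 1L)
  c(left, right)
}

ECORI_MOTIF <- "GAATTC"

#' Build the synthetic reference genome
#'
#' Generates the two homologous loci (recipient MATa-like and donor
#' MATa'-like), plants the configured polymorphisms and EcoRI sites, and
#' scrubs every spurious EcoRI motif from the background so that in-silico
#' digests see exactly the designed sites. The two homology arms are
#' byte-identical between chromosomes except at the polymorphic bases and
#' the single HO/HO-inc difference, so a 75-mer covering a donor allele can
#' never align to the recipient under a 0-mismatch contract.
#'
#' @param config a [genome_config()].
#' @param seed integer; identical seeds give byte-identical genomes.
#' @return a list of class `genome_map` with elements `chromosomes` (named
#'   character vector of sequences), `ho_site`, `ho_inc_site`,
#'   `polymorphisms` (tibble), `restriction_sites` (named list of per-
#'   chromosome cut-coordinate vectors), `control_region`, `donor_region`,
#'   `homology_arms`, `block_elements`, and the `config` used.
#' @export
build_reference <- function(config = genome_config(), seed = 1L) {
  cfg <- config
  validate_genome_config(cfg)
  set.seed(substream_seed(seed, 101))
  half_core <- cfg$ho_core_length %/% 2L

  # homology cassette in cut-relative coordinates [-arm-half, arm+half)
  span <- cfg$arm_length + half_core
  cassette <- strsplit(random_dna(2L * span), "")[[1]]
  rel_index <- function(off) off + span + 1L  # offset -> index into cassette

  offs <- poly_offsets(cfg)
  rec_allele <- character(length(offs))
  don_allele <- character(length(offs))
  creates <- offs %in% cfg$ecori_offsets
  for (i in seq_along(offs)) {
    p <- rel_index(offs[i])
    if (creates[i]) {
      # donor allele completes GAATTC; shared context carries GAATT
      cassette[(p - 5L):(p - 1L)] <- strsplit("GAATT", "")[[1]]
      rec_allele[i] <- sample(c("A", "G", "T"), 1L)
      don_allele[i] <- "C"
    } else {
      rec_allele[i] <- cassette[p]
      don_allele[i] <- sample(setdiff(c("A", "C", "G", "T"), rec_allele[i]), 1L)
    }
    cassette[p] <- rec_allele[i]
  }

  # HO-inc differs from the cleavable core by one substitution 2 nt right
  # of the scissile bond
  inc_rel <- rel_index(2L)
  inc_base <- sample(setdiff(c("A", "C", "G", "T"), cassette[inc_rel]), 1L)

  rec_cassette <- cassette
  don_cassette <- cassette
  don_cassette[vapply(offs, rel_index, integer(1))] <- don_allele
  don_cassette[inc_rel] <- inc_base

  # purge EcoRI motifs from the cassette that are not the designed ones
  designed_don <- sort(rel_index(cfg$ecori_offsets) - 5L)  # motif start idx
  scrub_cassette <- function() {
    repeat {
      bad <- integer(0)
      for (cas in list(rec_cassette, don_cassette)) {
        s <- paste(cas, collapse = "")
        hits <- unlist(gregexpr(ECORI_MOTIF, s, fixed = TRUE))
        hits <- hits[hits > 0]
        bad <- union(bad, setdiff(hits, designed_don))
      }
      if (length(bad) == 0) break
      for (b in bad) {
        # mutate a context base of the spurious motif that is neither a
        # polymorphic position nor part of a designed motif
        cand <- setdiff(b:(b + 5L),
                        c(vapply(offs, rel_index, 1L), inc_rel,
                          unlist(lapply(designed_don, function(d) d:(d + 5L)))))
        if (length(cand) == 0)
          abort("polymorphism placement collides with a restriction site it must not create")
        j <- cand[1]
        new <- sample(setdiff(c("A", "C", "G", "T"), rec_cassette[j]), 1L)
        rec_cassette[j] <<- new
        don_cassette[j] <<- new
      }
    }
  }
  scrub_cassette()
  # recipient cassette must carry no EcoRI site at all
  rs <- paste(rec_cassette, collapse = "")
  if (any(unlist(gregexpr(ECORI_MOTIF, rs, fixed = TRUE)) > 0))
    abort("polymorphism placement collides with a restriction site it must not create")

  # chromosome backgrounds
  chroms <- c(
    setNames(random_dna(cfg$recipient_length), cfg$recipient),
    setNames(random_dna(cfg$donor_length), cfg$donor),
    setNames(random_dna(cfg$background_length), cfg$background)
  )

  splice <- function(seq, start, insert) {
    paste0(substring(seq, 1L, start), insert,
           substring(seq, start + nchar(insert) + 1L, nchar(seq)))
  }
  rec_start <- cfg$ho_site - span                       # 0-based insert point
  chroms[cfg$recipient] <- splice(chroms[cfg$recipient], rec_start,
                                  paste(rec_cassette, collapse = ""))
  chroms[cfg$donor] <- splice(chroms[cfg$donor], cfg$donor_insert_start,
                              paste(don_cassette, collapse = ""))
  ho_inc_site <- cfg$donor_insert_start + span          # cut-equivalent coord

  # plant recipient EcoRI sites: motif starts one base left of the cut coord
  for (off in cfg$recipient_ecori_offsets) {
    cut <- cfg$ho_site + off
    chroms[cfg$recipient] <- splice(chroms[cfg$recipient], cut - 1L, ECORI_MOTIF)
  }

  # scrub spurious EcoRI motifs outside the designed set (background and
  # junctions only; cassette interior is already clean)
  keep <- list()
  keep[[cfg$recipient]] <- cfg$ho_site + cfg$recipient_ecori_offsets - 1L
  keep[[cfg$donor]] <- ho_inc_site + cfg$ecori_offsets - 5L
  keep[[cfg$background]] <- integer(0)
  protected <- list()
  protected[[cfg$recipient]] <- c(rec_start, rec_start + 2L * span - 1L)
  protected[[cfg$donor]] <- c(cfg$donor_insert_start,
                              cfg$donor_insert_start + 2L * span - 1L)
  protected[[cfg$background]] <- c(1L, 0L)
  for (nm in names(chroms)) {
    repeat {
      hits <- unlist(gregexpr(ECORI_MOTIF, chroms[nm], fixed = TRUE))
      hits <- hits[hits > 0] - 1L                       # 0-based motif starts
      bad <- setdiff(hits, keep[[nm]])
      if (length(bad) == 0) break
      for (b in bad) {
        # mutate one motif base lying outside the homology cassette
        idx <- b:(b + 5L)
        ok <- idx < protected[[nm]][1] | idx > protected[[nm]][2]
        assert_that(any(ok), "cannot scrub EcoRI motif inside homology region")
        j <- idx[ok][1]
        old <- substring(chroms[nm], j + 1L, j + 1L)
        chroms[nm] <- paste0(substring(chroms[nm], 1L, j),
                             sample(setdiff(c("A", "C", "G", "T"), old), 1L),
                             substring(chroms[nm], j + 2L, nchar(chroms[nm])))
      }
    }
  }

  restriction_sites <- lapply(setNames(names(chroms), names(chroms)), function(nm) {
    hits <- unlist(gregexpr(ECORI_MOTIF, chroms[nm], fixed = TRUE))
    hits <- hits[hits > 0]
    sort(as.integer(hits))                              # cut after G: 0-based cut = hit (1-based start) - 1 + 1
  })
  restriction_sites <- list(EcoRI = restriction_sites)

  polymorphisms <- tibble(
    recipient_pos = cfg$ho_site + offs,
    donor_pos = ho_inc_site + offs,
    recipient_allele = rec_allele,
    donor_allele = don_allele,
    creates_ecori = creates,
    offset_from_ho = offs
  )

  inc_variant <- tibble(
    recipient_pos = cfg$ho_site + 2L,
    donor_pos = ho_inc_site + 2L,
    recipient_allele = rec_cassette[inc_rel],
    donor_allele = inc_base,
    creates_ecori = FALSE,
    offset_from_ho = 2L
  )

  arm_tbl <- tibble(
    chromosome = rep(c(cfg$recipient, cfg$donor), each = 2L),
    arm = rep(c("left", "right"), 2L),
    start = c(cfg$ho_site - span, cfg$ho_site + half_core,
              cfg$donor_insert_start, ho_inc_site + half_core),
    end = c(cfg$ho_site - half_core, cfg$ho_site + span,
            ho_inc_site - half_core, cfg$donor_insert_start + 2L * span)
  )

  gm <- structure(list(
    chromosomes = chroms,
    ho_site = cfg$ho_site,
    ho_inc_site = ho_inc_site,
    polymorphisms = polymorphisms,
    ho_inc_variant = inc_variant,
    restriction_sites = restriction_sites,
    control_region = list(chromosome = cfg$donor,
                          start = cfg$control_region[1],
                          end = cfg$control_region[2]),
    donor_region = list(chromosome = cfg$donor,
                        start = cfg$donor_insert_start,
                        end = cfg$donor_insert_start + 2L * span),
    homology_arms = arm_tbl,
    block_elements = tibble(chromosome = cfg$recipient,
                            position = cfg$ho_site + cfg$block_offset,
                            label = "LTR"),
    config = cfg
  ), class = "genome_map")
  validate_genome_map(gm)
  gm
}

validate_genome_map <- function(gm) {
  p <- gm$polymorphisms
  assert_that(all(p$recipient_allele != p$donor_allele),
              "polymorphism alleles must differ")
  assert_that(!is.unsorted(p$recipient_pos) && !is.unsorted(p$donor_pos),
              "polymorphisms must map monotonically")
  assert_that(all(p$offset_from_ho == p$recipient_pos - gm$ho_site),
              "offset_from_ho inconsistent")
  for (enz in names(gm$restriction_sites)) {
    for (nm in names(gm$restriction_sites[[enz]])) {
      s <- gm$restriction_sites[[enz]][[nm]]
      assert_that(all(s > 0 & s < nchar(gm$chromosomes[nm])) &&
                    !is.unsorted(s, strictly = TRUE),
                  "restriction sites out of bounds or unsorted")
    }
  }
  cr <- gm$control_region; dr <- gm$donor_region
  assert_that(!(cr$chromosome == dr$chromosome &&
                  cr$start < dr$end && dr$start < cr$end),
              "control region overlaps donor region")
  arms <- gm$homology_arms
  inside <- vapply(seq_len(nrow(p)), function(i) {
    any(arms$chromosome == dr$chromosome &
          p$donor_pos[i] >= arms$start & p$donor_pos[i] < arms$end)
  }, logical(1))
  assert_that(all(inside), "every polymorphism must lie inside a homology arm")
  invisible(gm)
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map>\n")
  for (nm in names(x$chromosomes))
    cat(sprintf("  %s: %d nt\n", nm, nchar(x$chromosomes[nm])))
  cat(sprintf("  HO cut at %s:%d; HO-inc at %s:%d\n",
              x$config$recipient, x$ho_site, x$config$donor, x$ho_inc_site))
  cat(sprintf("  %d polymorphisms (%d EcoRI-creating), donor insert %d nt\n",
              nrow(x$polymorphisms), sum(x$polymorphisms$creates_ecori),
              x$donor_region$end - x$donor_region$start))
  invisible(x)
}

#' Write / read the reference genome and its site annotation
#'
#' The genome is written as FASTA plus a BED-like TSV of annotated sites
#' (chrom, start, end, label, allele, partner_chrom, partner_start).
#' `read_reference()` reconstructs an equivalent `genome_map`, rescanning
#' restriction sites from the sequence, so external references with a
#' user-supplied site annotation can enter the pipeline.
#'
#' @param genome a `genome_map`.
#' @param fasta,sites output/input file paths.
#' @return `write_reference()` returns the paths invisibly;
#'   `read_reference()` returns a `genome_map`.
#' @export
write_reference <- function(genome, fasta, sites) {
  dna <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(dna, fasta)
  p <- genome$polymorphisms
  cfg <- genome$config
  rows <- bind_rows(
    tibble(chrom = cfg$recipient, start = p$recipient_pos,
           end = p$recipient_pos + 1L,
           label = ifelse(p$creates_ecori, "poly_ecori", "poly"),
           allele = p$recipient_allele,
           partner_chrom = cfg$donor, partner_start = p$donor_pos,
           partner_allele = p$donor_allele),
    tibble(chrom = cfg$recipient, start = genome$ho_site,
           end = genome$ho_site, label = "HO", allele = NA_character_,
           partner_chrom = NA_character_, partner_start = NA_integer_,
           partner_allele = NA_character_),
    tibble(chrom = cfg$donor, start = genome$ho_inc_site,
           end = genome$ho_inc_site, label = "HO_inc", allele = NA_character_,
           partner_chrom = NA_character_, partner_start = NA_integer_,
           partner_allele = NA_character_),
    tibble(chrom = genome$control_region$chromosome,
           start = genome$control_region$start,
           end = genome$control_region$end, label = "control_region",
           allele = NA_character_, partner_chrom = NA_character_,
           partner_start = NA_integer_, partner_allele = NA_character_),
    tibble(chrom = genome$donor_region$chromosome,
           start = genome$donor_region$start, end = genome$donor_region$end,
           label = "donor_region", allele = NA_character_,
           partner_chrom = NA_character_, partner_start = NA_integer_,
           partner_allele = NA_character_),
    tibble(chrom = genome$homology_arms$chromosome,
           start = genome$homology_arms$start, end = genome$homology_arms$end,
           label = paste0("arm_", genome$homology_arms$arm),
           allele = NA_character_, partner_chrom = NA_character_,
           partner_start = NA_integer_, partner_allele = NA_character_),
    tibble(chrom = genome$block_elements$chromosome,
           start = genome$block_elements$position,
           end = genome$block_elements$position + 1L,
           label = paste0("block_", genome$block_elements$label),
           allele = NA_character_, partner_chrom = NA_character_,
           partner_start = NA_integer_, partner_allele = NA_character_)
  )
  write.table(rows, sites, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, sites = sites))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta, sites) {
  dna <- Biostrings::readDNAStringSet(fasta)
  chroms <- setNames(as.character(dna), sub("\\s.*", "", names(dna)))
  tab <- as_tibble(read.table(sites, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
  pick <- function(lbl) tab[tab$label == lbl, , drop = FALSE]
  ho <- pick("HO"); inc <- pick("HO_inc")
  assert_that(nrow(ho) == 1 && nrow(inc) == 1,
              "site annotation must contain one HO and one HO_inc row")
  polys <- tab[tab$label %in% c("poly", "poly_ecori"), , drop = FALSE]
  polys <- polys[order(polys$start), , drop = FALSE]
  polymorphisms <- tibble(
    recipient_pos = as.integer(polys$start),
    donor_pos = as.integer(polys$partner_start),
    recipient_allele = polys$allele,
    donor_allele = polys$partner_allele,
    creates_ecori = polys$label == "poly_ecori",
    offset_from_ho = as.integer(polys$start) - as.integer(ho$start)
  )
  cr <- pick("control_region"); dr <- pick("donor_region")
  arms <- tab[grepl("^arm_", tab$label), , drop = FALSE]
  blocks <- tab[grepl("^block_", tab$label), , drop = FALSE]
  restriction_sites <- list(EcoRI = lapply(
    setNames(names(chroms), names(chroms)),
    function(nm) {
      hits <- unlist(gregexpr(ECORI_MOTIF, chroms[nm], fixed = TRUE))
      sort(as.integer(hits[hits > 0]))
    }))
  structure(list(
    chromosomes = chroms,
    ho_site = as.integer(ho$start),
    ho_inc_site = as.integer(inc$start),
    polymorphisms = polymorphisms,
    restriction_sites = restriction_sites,
    control_region = list(chromosome = cr$chrom, start = as.integer(cr$start),
                          end = as.integer(cr$end)),
    donor_region = list(chromosome = dr$chrom, start = as.integer(dr$start),
                        end = as.integer(dr$end)),
    homology_arms = tibble(chromosome = arms$chrom,
                           arm = sub("^arm_", "", arms$label),
                           start = as.integer(arms$start),
                           end = as.integer(arms$end)),
    block_elements = tibble(chromosome = blocks$chrom,
                            position = as.integer(blocks$start),
                            label = sub("^block_", "", blocks$label)),
    # partial configuration inferred from the annotation: chromosome
    # roles and arm geometry, enough for the coverage/GC/discordant
    # stages to run on an external reference
    config = list(
      recipient = ho$chrom,
      donor = inc$chrom,
      background = setdiff(names(chroms), c(ho$chrom, inc$chrom))[1],
      arm_length = {
        a <- arms[arms$chrom == ho$chrom & arms$label == "arm_left", ]
        if (nrow(a) == 1) as.integer(a$end - a$start) else NA_integer_
      },
      ho_core_length = {
        l <- arms[arms$chrom == ho$chrom & arms$label == "arm_left", ]
        r <- arms[arms$chrom == ho$chrom & arms$label == "arm_right", ]
        if (nrow(l) == 1 && nrow(r) == 1)
          as.integer(r$start - l$end) else NA_integer_
      },
      ho_site = as.integer(ho$start)
    )
  ), class = "genome_map")
}
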