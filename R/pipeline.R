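PIPELINE_STAGES <- c("build_ref", "simulate", "map", "coverage",
                     "resection", "synthesis", "gc", "discordant")

#' Configuration of an end-to-end pipeline run
#'
#' @param genome a [genome_config()].
#' @param params a [sim_params()].
#' @param analysis an [analysis_config()]; its control region defaults to
#'   the genome's annotated one.
#' @param timepoints hours sampled (must include 0, the undamaged
#'   reference sample).
#' @param seed master seed; recorded in every report.
#' @param stages subset of `r paste(PIPELINE_STAGES, collapse = ", ")`,
#'   or `"all"`.
#' @param out_dir optional directory for FASTA / FASTQ / SAM / BedGraph /
#'   TSV / JSON artifacts; `NULL` keeps everything in memory.
#' @return a list of class `run_config`.
#' @export
run_config <- function(genome = genome_config(),
                       params = sim_params(),
                       analysis = analysis_config(),
                       timepoints = 0:10,
                       seed = 1L,
                       stages = "all",
                       out_dir = NULL) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  assert_that(all(stages %in% PIPELINE_STAGES),
              sprintf("unknown stage; available: %s",
                      paste(PIPELINE_STAGES, collapse = ", ")))
  assert_that(0 %in% timepoints, "timepoints must include 0 (the T0 sample)")
  structure(list(genome = genome, params = params, analysis = analysis,
                 timepoints = sort(unique(timepoints)), seed = as.integer(seed),
                 stages = stages, out_dir = out_dir),
            class = "run_config")
}

require_stage <- function(state, what, needed) {
  if (is.null(state[[what]]))
    abort(sprintf("stage '%s' requires stage '%s' to run first", needed, what))
  state[[what]]
}

#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates reference building, population simulation and read
#' emission per timepoint, 0-mismatch mapping, RPGC + T0 coverage
#' normalization, and the resection / re-synthesis / gene-conversion /
#' discordant-pair reports. Deterministic given the seed. When
#' `out_dir` is set, standard-format artifacts are written per stage and
#' a JSON summary (with the seed and parameters) at the end.
#'
#' @param config a [run_config()].
#' @return a list (report bundle) with one element per executed stage.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  st <- list(seed = cfg$seed)
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = cfg$seed, timepoints = cfg$timepoints)

  if ("build_ref" %in% cfg$stages) {
    st$genome <- build_reference(cfg$genome, seed = cfg$seed)
    if (!is.null(out))
      write_reference(st$genome, file.path(out, "reference.fasta"),
                      file.path(out, "sites.tsv"))
  }

  if ("simulate" %in% cfg$stages) {
    genome <- require_stage(st, "genome", "simulate")
    st$populations <- lapply(setNames(cfg$timepoints, cfg$timepoints),
                             function(t)
                               simulate_population(cfg$params, t, genome,
                                                   seed = cfg$seed))
    st$reads <- lapply(st$populations, function(pop)
      emit_read_pairs(pop, genome, cfg$params, seed = cfg$seed))
    if (!is.null(out)) {
      for (tp in names(st$reads)) {
        write_read_pairs(st$reads[[tp]],
                         file.path(out, sprintf("t%s_R1.fastq", tp)),
                         file.path(out, sprintf("t%s_R2.fastq", tp)),
                         file.path(out, sprintf("t%s_truth.tsv", tp)))
      }
    }
  }

  if ("map" %in% cfg$stages) {
    genome <- require_stage(st, "genome", "map")
    reads <- require_stage(st, "reads", "map")
    index <- build_index(genome, k = cfg$params$read_length)
    st$alignments <- lapply(reads, function(rp) {
      a1 <- map_reads(rp$read1, index, read_id = rp$pair_id)
      a2 <- map_reads(rp$read2, index, read_id = rp$pair_id)
      list(mate1 = a1, mate2 = a2,
           pairs = pair_reads(a1, a2, pair_id = rp$pair_id,
                              insert_bounds = cfg$analysis$insert_bounds,
                              read_length = cfg$params$read_length),
           total_reads = attr(rp, "total_reads"))
    })
    log$read_counts <- lapply(st$alignments, function(a)
      c(total = a$total_reads,
        mapped = sum(a$mate1$mapped) + sum(a$mate2$mapped),
        unique = sum(a$mate1$unique) + sum(a$mate2$unique),
        discordant_pairs = sum(a$pairs$class == "discordant")))
    if (!is.null(out)) {
      lens <- nchar(genome$chromosomes)
      for (tp in names(st$alignments)) {
        a <- st$alignments[[tp]]
        aln <- bind_rows(
          a$mate1 |> mutate(mate = 1L, seq = reads[[tp]]$read1),
          a$mate2 |> mutate(mate = 2L, seq = reads[[tp]]$read2))
        write_sam(aln, lens, file.path(out, sprintf("t%s.sam", tp)))
      }
    }
    rm(index)
  }

  if ("coverage" %in% cfg$stages) {
    genome <- require_stage(st, "genome", "coverage")
    alns <- require_stage(st, "alignments", "coverage")
    st <- c(st, coverage_stage(alns, genome, cfg, out))
  }

  an <- cfg$analysis
  ho <- st$genome$ho_site %||% NULL

  if ("resection" %in% cfg$stages) {
    profiles <- require_stage(st, "profiles", "resection")
    genome <- st$genome
    tnames <- as.numeric(names(profiles))
    res <- list()
    if (any(tnames == 1)) {
      res$short_range <- short_range_resection(profiles[["1"]], ho,
                                               window = an$short_range_window)
    }
    block <- genome$block_elements$position[1]
    censor_left <- ho - block
    censor_right <- nchar(genome$chromosomes[genome$config$recipient]) - ho
    in_window <- tnames >= an$resection_interval[1] &
      tnames <= an$resection_interval[2]
    res$rate <- if (sum(in_window) >= 2) {
      long_range_rate(profiles, ho,
                      level = an$half_coverage_level,
                      interval = an$resection_interval,
                      smooth_bins = an$smooth_bins,
                      censor_left = censor_left,
                      censor_right = censor_right)
    } else NULL
    res$max_extent <- bind_rows(lapply(names(st$tracks), function(tp)
      max_resection_extent(st$tracks[[tp]], genome, st$mask,
                           cutoff = an$max_extent_cutoff, bin = an$bin,
                           smooth_bins = an$smooth_bins) |>
        mutate(timepoint = as.numeric(tp))))
    st$resection <- res
  }

  if ("synthesis" %in% cfg$stages) {
    profiles <- require_stage(st, "profiles", "synthesis")
    # the re-synthesis window opens once resection has plateaued (4 h on)
    if (sum(as.numeric(names(profiles)) >= 4) >= 2) {
      tmax <- max(as.numeric(names(profiles)))
      interval <- c(4, tmax)
      syn <- list()
      syn$series <- bind_rows(lapply(an$synthesis_distances, function(dst)
        bind_rows(lapply(c("left", "right"), function(s)
          coverage_time_series(profiles, ho, dst, s)))))
      syn$trends <- list()
      for (dst in an$synthesis_distances) for (s in c("left", "right")) {
        ser <- syn$series[syn$series$distance == dst & syn$series$side == s, ]
        syn$trends[[sprintf("%s_%d", s, dst)]] <- synthesis_rate(ser, interval)
      }
      d0 <- an$synthesis_distances[1]
      syn$initiation <- bind_rows(lapply(c("left", "right"), function(s)
        initiation_rate(syn$trends[[sprintf("%s_%d", s, d0)]])))
      st$synthesis <- syn
    }
  }

  if ("gc" %in% cfg$stages) {
    profiles <- require_stage(st, "profiles", "gc")
    tracks <- st$tracks
    genome <- st$genome
    tmax <- as.character(max(as.numeric(names(tracks))))
    fr <- site_fractions(tracks[[tmax]], tracks[["0"]], genome,
                         window = an$read_length)
    fac <- correction_factor(profiles, ho,
                             distance = an$synthesis_distances[1])
    st$gc <- list(fractions = apply_gc_correction(fr, fac),
                  factors = fac, timepoint = as.numeric(tmax))
    if (!is.null(out))
      write.table(st$gc$fractions, file.path(out, "gc_fractions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("discordant" %in% cfg$stages) {
    alns <- require_stage(st, "alignments", "discordant")
    genome <- st$genome
    dp <- bind_rows(lapply(names(alns), function(tp)
      extract_discordant(alns[[tp]]$pairs, genome,
                         timepoint = as.numeric(tp))))
    class(dp) <- c("discordant_pairs", class(tibble()))
    totals <- sum(vapply(alns, function(a) a$total_reads, numeric(1)))
    dc <- discordant_coverage(dp, genome, read_length = an$read_length)
    regions <- default_regions(dc)
    st$discordant <- list(
      pairs = classify_quadrant(dp, genome$ho_site, genome$ho_inc_site),
      fraction = discordant_fraction(
        dp, vapply(alns, function(a) a$total_reads, numeric(1))),
      coverage = dc,
      regions = classify_regions(dp, genome, regions,
                                 read_length = an$read_length),
      background = background_fraction(dp, genome, totals))
    if (!is.null(out)) {
      write.table(st$discordant$pairs,
                  file.path(out, "discordant_pairs.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  st$log <- log
  report_stages <- c("coverage", "resection", "synthesis", "gc", "discordant")
  if (!is.null(out) && length(intersect(cfg$stages, report_stages)) > 0) {
    summary <- list(seed = cfg$seed, timepoints = cfg$timepoints,
                    read_counts = log$read_counts)
    if (!is.null(st$resection)) {
      summary$resection_rate <- st$resection$rate$rates
      summary$max_extent <- st$resection$max_extent
    }
    if (!is.null(st$synthesis)) summary$initiation <- st$synthesis$initiation
    if (!is.null(st$gc)) summary$correction_factors <- st$gc$factors
    if (!is.null(st$discordant)) {
      summary$discordant_fraction <- st$discordant$fraction
      summary$regions <- st$discordant$regions
    }
    jsonlite::write_json(summary, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  st
}

# shared coverage stage: RPGC scaling, T0 mask, ratio + section profiles
coverage_stage <- function(alns, genome, cfg, out) {
  an <- cfg$analysis
  lens <- nchar(genome$chromosomes)
  rec <- genome$config$recipient
  tracks <- lapply(alns, function(a)
    rpgc_scale(per_base_coverage(
      bind_rows(a$mate1, a$mate2), lens,
      read_length = cfg$params$read_length)))
  mask <- t0_mask(tracks[["0"]], threshold = an$t0_threshold)
  split <- setNames(genome$ho_site, rec)
  ctrl <- genome$control_region
  profiles <- lapply(setNames(names(tracks), names(tracks)), function(tp)
    ratio_profile(tracks[[tp]], tracks[["0"]], mask, bin = an$bin,
                  chromosome = rec, split_at = split,
                  control_region = ctrl, timepoint = as.numeric(tp)))
  sections <- lapply(setNames(names(tracks), names(tracks)), function(tp)
    section_normalize(tracks[[tp]], tracks[["0"]], ctrl,
                      section = an$section, timepoint = as.numeric(tp)))
  cm <- colormap_matrix(sections, rec)
  if (!is.null(out)) {
    for (tp in names(tracks))
      write_bedgraph(tracks[[tp]], file.path(out, sprintf("t%s.bedgraph", tp)))
    write.table(bind_rows(profiles), file.path(out, "ratio_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(bind_rows(sections), file.path(out, "section_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(tracks = tracks, mask = mask, profiles = profiles,
       sections = sections, colormap = cm)
}

#' Re-run the pipeline from user-supplied alignments
#'
#' Ingests SAM files (one per timepoint, mates written as individual
#' records sharing the pair id) plus a reference FASTA and site
#' annotation, then runs the pipeline stages from coverage onward
#' unchanged. Reads whose length differs from the configured read length
#' are rejected and counted.
#'
#' @param sam_files named character vector of SAM paths; names are hours
#'   and must include `"0"`.
#' @param fasta,sites reference produced by [write_reference()] (or an
#'   external reference with a compatible annotation).
#' @param config a [run_config()]; its genome field is ignored in favour
#'   of the supplied reference.
#' @return a report bundle as from [run_pipeline()].
#' @export
ingest_external <- function(sam_files, fasta, sites, config = run_config()) {
  assert_that("0" %in% names(sam_files),
              "sam_files must include the undamaged '0' sample")
  genome <- read_reference(fasta, sites)
  rl <- config$params$read_length
  rejected <- integer(0)
  alns <- lapply(sam_files, function(path) {
    rec <- read_sam(path)
    bad <- rec$seq != "*" & nchar(rec$seq) != rl
    rejected <<- c(rejected, sum(bad))
    rec <- rec[!bad, , drop = FALSE]
    # multi-mapped records carry MAPQ 0 (as written by write_sam); treat
    # them as non-unique so they are excluded downstream
    rec$unique <- rec$mapped & rec$mapq > 0L
    m1 <- rec[bitwAnd(rec$flag, 128L) == 0L, , drop = FALSE]
    m2 <- rec[bitwAnd(rec$flag, 128L) > 0L, , drop = FALSE]
    common <- intersect(m1$read_id, m2$read_id)
    a1 <- m1[match(common, m1$read_id), , drop = FALSE]
    a2 <- m2[match(common, m2$read_id), , drop = FALSE]
    list(mate1 = a1, mate2 = a2,
         pairs = pair_reads(a1, a2, pair_id = common,
                            insert_bounds = config$analysis$insert_bounds,
                            read_length = rl),
         total_reads = nrow(rec))
  })
  message(sprintf("rejected %d reads with length != %d",
                  sum(rejected), rl))
  cfg <- config
  st <- list(seed = cfg$seed, genome = genome, alignments = alns)
  st <- c(st, coverage_stage(alns, genome, cfg, cfg$out_dir))
  st
}
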