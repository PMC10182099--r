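#' Simulation parameters for the repair time course
#'
#' The population model: each cell is cut with probability
#' `cut_efficiency` shortly after induction; both DSB ends are then
#' resected 5'-3' at a per-cell, per-side velocity drawn once from a gamma
#' distribution (`velocity_shape = Inf` gives a deterministic velocity).
#' Left-side resection halts at the blocking element annotated in the
#' genome. A fraction `repair_fraction` of cells repairs the break by gene
#' conversion at a gamma-distributed `repair_time`; from then on duplex
#' DNA is restored from the break outward at `resynthesis_velocity`, and
#' the conversion tract substitutes donor alleles over
#' `[-gc_left, +gc_right]` (geometric tails beyond the HO core, so every
#' repaired cell incorporates the uncleavable donor core). In the default
#' (wild-type-like) mode resection stops once a cell repairs; with
#' `resection_stop_on_repair = FALSE` unrepaired-style over-resection
#' continues, emulating a resection-inhibition mutant.
#'
#' @param n_cells cells in the population.
#' @param cut_efficiency probability a cell is ever cut.
#' @param resection_delay hours between induction and resection start.
#' @param resection_velocity mean resection velocity, nt/h per side.
#' @param velocity_shape gamma shape of the per-cell velocity (Inf =
#'   deterministic; smaller = more cell-to-cell dispersion).
#' @param repair_fraction probability a cut cell ever repairs.
#' @param repair_time_mean,repair_time_shape gamma repair-time (h).
#' @param resynthesis_velocity duplex restoration velocity, nt/h per side.
#' @param gc_tract_left,gc_tract_right mean tract boundary distance from
#'   the cut (nt) per side.
#' @param gc_tract_fixed make every tract exactly
#'   `[-gc_tract_left, +gc_tract_right]` instead of geometric.
#' @param resection_stop_on_repair logical, see above.
#' @param degrade_ssdna probability that a cell's resected single strand
#'   is degraded (destabilized) rather than retained.
#' @param read_length,insert_mean,insert_sd,depth library parameters:
#'   read length (nt), insert size distribution, mean sequencing depth.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 2000L,
                       cut_efficiency = 0.95,
                       resection_delay = 0.25,
                       resection_velocity = 5000,
                       velocity_shape = 8,
                       repair_fraction = 0.8,
                       repair_time_mean = 6,
                       repair_time_shape = 12,
                       resynthesis_velocity = 2000,
                       gc_tract_left = 600,
                       gc_tract_right = 100,
                       gc_tract_fixed = FALSE,
                       resection_stop_on_repair = TRUE,
                       degrade_ssdna = 0,
                       read_length = 75L,
                       insert_mean = 300,
                       insert_sd = 50,
                       depth = 30) {
  p <- list(n_cells = as.integer(n_cells), cut_efficiency = cut_efficiency,
            resection_delay = resection_delay,
            resection_velocity = resection_velocity,
            velocity_shape = velocity_shape,
            repair_fraction = repair_fraction,
            repair_time_mean = repair_time_mean,
            repair_time_shape = repair_time_shape,
            resynthesis_velocity = resynthesis_velocity,
            gc_tract_left = gc_tract_left, gc_tract_right = gc_tract_right,
            gc_tract_fixed = isTRUE(gc_tract_fixed),
            resection_stop_on_repair = isTRUE(resection_stop_on_repair),
            degrade_ssdna = degrade_ssdna,
            read_length = as.integer(read_length),
            insert_mean = insert_mean, insert_sd = insert_sd, depth = depth)
  assert_that(p$resection_velocity >= 0 && p$resynthesis_velocity >= 0,
              "velocities must be non-negative")
  assert_that(all(c(p$cut_efficiency, p$repair_fraction, p$degrade_ssdna) >= 0 &
                    c(p$cut_efficiency, p$repair_fraction, p$degrade_ssdna) <= 1),
              "probabilities must lie in [0, 1]")
  assert_that(p$read_length <= p$insert_mean,
              "read length must not exceed the mean insert size")
  structure(p, class = "sim_params")
}

# per-cell latent variables drawn once from the master seed, so the state
# at any time point is a deterministic function of (seed, t)
cell_latents <- function(params, genome, seed) {
  n <- params$n_cells
  draw <- function(op, fn) { set.seed(substream_seed(seed, op)); fn(n) }
  vshape <- params$velocity_shape
  rvel <- function(n) {
    if (is.infinite(vshape)) rep(params$resection_velocity, n)
    else rgamma(n, shape = vshape, rate = vshape / params$resection_velocity)
  }
  half_core <- (genome$config$ho_core_length %||% 24L) %/% 2L
  rtract <- function(mean_off) function(n) {
    if (params$gc_tract_fixed) return(rep(mean_off, n))
    m <- max(mean_off - half_core, 1)
    half_core + rgeom(n, prob = 1 / (m + 1))
  }
  tibble(
    cell = seq_len(n),
    cut = draw(1, function(n) runif(n) < params$cut_efficiency),
    v_left = draw(2, rvel),
    v_right = draw(3, rvel),
    repairer = draw(4, function(n) runif(n) < params$repair_fraction),
    repair_time = draw(5, function(n)
      rgamma(n, shape = params$repair_time_shape,
             rate = params$repair_time_shape / params$repair_time_mean)),
    gc_left = -draw(6, rtract(params$gc_tract_left)),
    gc_right = draw(7, rtract(params$gc_tract_right)),
    degraded = draw(8, function(n) runif(n) < params$degrade_ssdna)
  )
}

#' Simulate the cell population at one time point
#'
#' @param params a [sim_params()].
#' @param t hours after HO induction (0 = undamaged).
#' @param genome a `genome_map`.
#' @param seed master seed; per-cell randomness comes from fixed
#'   substreams, so states at different `t` describe the same cells.
#' @return a `population_state` tibble, one row per cell, with resection
#'   extents, re-synthesis extents, repair status and conversion tract
#'   boundaries (signed offsets from the cut; NA when unrepaired).
#' @export
simulate_population <- function(params, t, genome, seed = 1L) {
  assert_that(t >= 0, "time must be non-negative")
  lat <- cell_latents(params, genome, seed)
  ho <- genome$ho_site
  rec_len <- nchar(genome$chromosomes[genome$config$recipient])
  block <- genome$block_elements$position[1]
  left_cap <- if (length(block)) ho - block else ho
  left_cap <- min(left_cap, ho)
  right_cap <- rec_len - ho

  cut <- lat$cut & t > 0
  repaired <- cut & lat$repairer & t >= lat$repair_time
  stop_t <- ifelse(params$resection_stop_on_repair & lat$repairer,
                   pmin(t, lat$repair_time), t)
  dur <- pmax(0, stop_t - params$resection_delay)
  left_extent <- ifelse(cut, pmin(lat$v_left * dur, left_cap), 0)
  right_extent <- ifelse(cut, pmin(lat$v_right * dur, right_cap), 0)
  resynth_dur <- pmax(0, t - lat$repair_time)
  resynth_left <- ifelse(repaired,
                         pmin(left_extent, params$resynthesis_velocity * resynth_dur), 0)
  resynth_right <- ifelse(repaired,
                          pmin(right_extent, params$resynthesis_velocity * resynth_dur), 0)
  half_span <- genome$config$arm_length + (genome$config$ho_core_length %/% 2L)

  pop <- tibble(
    cell = lat$cell,
    cut = cut,
    left_extent = round(left_extent),
    right_extent = round(right_extent),
    resynth_left = round(resynth_left),
    resynth_right = round(resynth_right),
    repaired = repaired,
    gc_left_boundary = ifelse(repaired, pmax(lat$gc_left, -half_span), NA_real_),
    gc_right_boundary = ifelse(repaired, pmin(lat$gc_right, half_span), NA_real_),
    degraded = lat$degraded & cut
  )
  structure(pop, class = c("population_state", class(pop)),
            time = t, params = params,
            ho_site = ho, recipient = genome$config$recipient,
            chrom_lengths = nchar(genome$chromosomes))
}

# single-stranded intervals on the recipient chromosome, one or two rows
# per cut cell: [ho - left_extent, ho - resynth_left) and
# [ho + resynth_right, ho + right_extent)
ssdna_intervals <- function(population) {
  ho <- attr(population, "ho_site")
  p <- population[population$cut, , drop = FALSE]
  out <- tibble(
    cell = rep(p$cell, 2L),
    start = c(ho - p$left_extent, ho + p$resynth_right),
    end = c(ho - p$resynth_left, ho + p$right_extent)
  )
  out[out$end > out$start, , drop = FALSE]
}

#' Double-stranded intervals of each cell
#'
#' The sequencing library only incorporates double-stranded fragments, so
#' these intervals are the sampling space for read emission. Uncut cells
#' and fully re-synthesized repaired cells return whole chromosomes;
#' donor and background chromosomes are always fully duplex.
#'
#' @param population a `population_state`.
#' @param genome the `genome_map` used to simulate it.
#' @param cells optional subset of cell ids.
#' @return tibble (cell, chromosome, start, end).
#' @export
dsdna_intervals <- function(population, genome, cells = NULL) {
  if (!is.null(cells)) population <- population[population$cell %in% cells, ]
  if (nrow(population) == 0)
    return(tibble(cell = integer(0), chromosome = character(0),
                  start = numeric(0), end = numeric(0)))
  ho <- attr(population, "ho_site")
  rec <- attr(population, "recipient")
  lens <- attr(population, "chrom_lengths")
  other <- setdiff(names(lens), rec)

  p <- population
  # recipient chromosome: up to three duplex pieces
  rec_rows <- bind_rows(
    tibble(cell = p$cell, chromosome = rec,
           start = 0, end = ifelse(p$cut, ho - p$left_extent, lens[rec])),
    tibble(cell = p$cell[p$cut], chromosome = rec,
           start = ho - p$resynth_left[p$cut], end = ho + p$resynth_right[p$cut]),
    tibble(cell = p$cell[p$cut], chromosome = rec,
           start = ho + p$right_extent[p$cut], end = lens[rec])
  )
  rec_rows <- rec_rows[rec_rows$end > rec_rows$start, , drop = FALSE]
  # merge adjacent pieces (fully re-synthesized cells)
  rec_rows <- rec_rows |>
    arrange(.data$cell, .data$start) |>
    group_by(.data$cell, .data$chromosome) |>
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -1))) |>
    group_by(.data$cell, .data$chromosome, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select(-"grp")

  other_rows <- tidyr::expand_grid(cell = p$cell, chromosome = other) |>
    mutate(start = 0, end = as.numeric(lens[.data$chromosome]))
  bind_rows(rec_rows, other_rows) |> arrange(.data$cell, .data$chromosome, .data$start)
}

#' Fraction of cells in which a position is double-stranded
#'
#' Analytic oracle for the coverage-ratio profiles: the expected
#' T0-normalized coverage at a position equals the fraction of cells in
#' which that position is duplex.
#'
#' @param population a `population_state`.
#' @param positions integer positions on the recipient chromosome.
#' @return numeric vector in `[0, 1]`.
#' @export
expected_relative_coverage <- function(population, positions) {
  lens <- attr(population, "chrom_lengths")
  rec_len <- lens[attr(population, "recipient")]
  assert_that(all(positions >= 0 & positions < rec_len),
              "positions out of bounds")
  ss <- ssdna_intervals(population)
  n <- nrow(population)
  if (nrow(ss) == 0) return(rep(1, length(positions)))
  # difference array over the number of single-stranded cells per base
  d <- numeric(rec_len + 1L)
  starts <- pmax(0, ss$start) + 1L
  ends <- pmin(rec_len, ss$end) + 1L
  for (i in seq_along(starts)) {
    d[starts[i]] <- d[starts[i]] + 1
    d[ends[i]] <- d[ends[i]] - 1
  }
  n_ss <- cumsum(d)[positions + 1L]
  1 - n_ss / n
}

#' Predicted relative qPCR signal over an amplicon
#'
#' Each cell contributes 1 if the amplicon is fully duplex, 0.5 if it
#' overlaps single-stranded DNA (one template strand remains), and 0 if
#' the resected strand was degraded. The population mean is already
#' normalized to the undamaged state (where every cell contributes 1), so
#' a fully single-stranded amplicon returns 0.5.
#'
#' @param population a `population_state`.
#' @param amplicon `c(start, end)` on the recipient chromosome.
#' @return scalar relative signal in `[0, 1]`.
#' @export
simulate_qpcr_signal <- function(population, amplicon) {
  lens <- attr(population, "chrom_lengths")
  rec_len <- lens[attr(population, "recipient")]
  assert_that(amplicon[1] >= 0 && amplicon[2] <= rec_len && amplicon[2] > amplicon[1],
              "amplicon out of bounds")
  ss <- ssdna_intervals(population)
  hit <- ss[ss$start < amplicon[2] & ss$end > amplicon[1], , drop = FALSE]
  ss_cells <- unique(hit$cell)
  contrib <- rep(1, nrow(population))
  idx <- match(ss_cells, population$cell)
  contrib[idx] <- ifelse(population$degraded[idx], 0, 0.5)
  mean(contrib)
}
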