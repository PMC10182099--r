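# simulate one timepoint and return classified pairs plus totals
sim_pairs <- function(gm, sp, t, seed, index = test_index()) {
  pop <- simulate_population(sp, t, gm, seed = seed)
  rp <- emit_read_pairs(pop, gm, sp, seed = seed)
  a1 <- map_reads(rp$read1, index, read_id = rp$pair_id)
  a2 <- map_reads(rp$read2, index, read_id = rp$pair_id)
  list(pop = pop, reads = rp,
       pairs = pair_reads(a1, a2, pair_id = rp$pair_id),
       total = attr(rp, "total_reads"))
}

test_that("simulations without gene conversion yield no recipient-donor pairs", {
  gm <- test_genome()
  sp <- sim_params(n_cells = 300, depth = 20, repair_fraction = 0)
  s <- sim_pairs(gm, sp, 4, seed = 71)
  dp <- extract_discordant(s$pairs, gm, timepoint = 4)
  expect_equal(nrow(dp[!dp$background, ]), 0L)
  bg <- background_fraction(dp, gm, s$total)
  expect_equal(bg$n_pairs, 0L)
  expect_equal(bg$fraction, 0)
})

test_that("pairs straddling a tract boundary are discordant with exact coordinates", {
  gm <- test_genome()
  ho <- gm$ho_site; inc <- gm$ho_inc_site
  idx <- test_index()
  # hand-built fragment from a repaired cell with tract [-600, +100]:
  # mate1 wholly inside the tract (donor alleles), mate2 wholly outside
  sites <- dplyr::bind_rows(gm$polymorphisms, gm$ho_inc_variant)
  conv <- sites[sites$offset_from_ho >= -600 & sites$offset_from_ho <= 100, ]
  recomb <- unname(gm$chromosomes[gm$config$recipient])
  for (i in seq_len(nrow(conv)))
    substr(recomb, conv$recipient_pos[i] + 1L, conv$recipient_pos[i] + 1L) <-
      conv$donor_allele[i]
  m1_start <- ho - 400L                       # inside tract
  m2_start <- ho + 300L                       # outside tract, past +100 + 75
  read1 <- substring(recomb, m1_start + 1L, m1_start + 75L)
  read2 <- resectr:::revcomp(substring(recomb, m2_start + 1L, m2_start + 75L))
  a1 <- map_reads(read1, idx, "p1"); a2 <- map_reads(read2, idx, "p1")
  pr <- pair_reads(a1, a2, "p1")
  expect_equal(pr$class, "discordant")
  dp <- extract_discordant(pr, gm, timepoint = 10)
  expect_equal(dp$donor_coord, inc + (m1_start - ho))
  expect_equal(dp$recipient_coord, m2_start)
  # a mate covering sites on both sides of the boundary matches neither
  # locus (donor allele at +80, recipient allele at +135)
  mid <- substring(recomb, ho + 71L, ho + 145L)
  expect_false(map_read(mid, idx)$mapped)
})

test_that("quadrant classification follows the >= tie convention", {
  gm <- test_genome()
  ho <- gm$ho_site; inc <- gm$ho_inc_site
  mk <- function(rc, dc) {
    tibble::tibble(pair_id = "x", recipient_coord = rc, donor_coord = dc,
                   chrom1 = gm$config$recipient, chrom2 = gm$config$donor,
                   strand1 = "+", strand2 = "-", background = FALSE,
                   timepoint = 10)
  }
  expect_equal(as.character(classify_quadrant(mk(ho - 600L, inc - 500L),
                                              ho, inc)$quadrant), "LB")
  expect_equal(as.character(classify_quadrant(mk(ho + 100L, inc - 50L),
                                              ho, inc)$quadrant), "RB")
  expect_equal(as.character(classify_quadrant(mk(ho - 50L, inc + 100L),
                                              ho, inc)$quadrant), "LT")
  expect_equal(as.character(classify_quadrant(mk(ho + 100L, inc + 150L),
                                              ho, inc)$quadrant), "RT")
  # exactly on the axes goes right/top
  expect_equal(as.character(classify_quadrant(mk(ho, inc - 50L),
                                              ho, inc)$quadrant), "RB")
  expect_equal(as.character(classify_quadrant(mk(ho - 50L, inc),
                                              ho, inc)$quadrant), "LT")
})

test_that("quadrants partition the pairs and match the simulated tract", {
  gm <- test_genome()
  idx <- test_index()
  sp <- sim_params(n_cells = 700, depth = 40, cut_efficiency = 1,
                   repair_fraction = 0.8, repair_time_mean = 4,
                   resynthesis_velocity = 4000, gc_tract_left = 600,
                   gc_tract_right = 100, gc_tract_fixed = TRUE)
  dp <- dplyr::bind_rows(lapply(c(6, 8, 10), function(t)
    extract_discordant(sim_pairs(gm, sp, t, seed = 73, index = idx)$pairs,
                       gm, timepoint = t)))
  q <- classify_quadrant(dp, gm$ho_site, gm$ho_inc_site)
  expect_equal(nrow(q), nrow(dp[!dp$background, ]))     # none lost
  expect_false(any(is.na(q$quadrant)))                  # none unassigned
  # a [-600, +100] tract yields left-side boundaries at LB and right-side
  # ones in the top quadrants
  expect_gt(sum(q$quadrant == "LB"), 0)
  expect_gt(sum(q$quadrant %in% c("RT", "LT")), 0)
})

test_that("discordant fractions count pairs against total reads", {
  gm <- test_genome()
  dp0 <- tibble::tibble(pair_id = character(0), recipient_coord = integer(0),
                        donor_coord = integer(0), chrom1 = character(0),
                        chrom2 = character(0), strand1 = character(0),
                        strand2 = character(0), background = logical(0),
                        timepoint = numeric(0))
  expect_error(discordant_fraction(dp0, 0), "positive")
  dp <- tibble::tibble(pair_id = as.character(1:5),
                       recipient_coord = 1:5, donor_coord = 1:5,
                       chrom1 = gm$config$recipient, chrom2 = gm$config$donor,
                       strand1 = "+", strand2 = "-", background = FALSE,
                       timepoint = 10)
  fr <- discordant_fraction(dp, 1e6)
  expect_equal(fr$fraction, 5e-6)
})

test_that("discordant mate coverage conserves read mass in the break frame", {
  gm <- test_genome()
  idx <- test_index()
  sp <- sim_params(n_cells = 500, depth = 30, cut_efficiency = 1,
                   repair_fraction = 0.8, repair_time_mean = 4,
                   resynthesis_velocity = 4000, gc_tract_left = 300,
                   gc_tract_right = 100, gc_tract_fixed = TRUE)
  dp <- extract_discordant(sim_pairs(gm, sp, 10, seed = 79, index = idx)$pairs,
                           gm, timepoint = 10)
  gc <- dp[!dp$background, ]
  dc <- discordant_coverage(dp, gm)
  expect_equal(sum(dc$recipient), 75 * nrow(gc))
  expect_equal(sum(dc$donor), 75 * (nrow(gc) - dc$n_excluded))
  empty <- extract_discordant(
    tibble::tibble(pair_id = character(0), chrom1 = character(0),
                   start1 = integer(0), strand1 = character(0),
                   unique1 = logical(0), chrom2 = character(0),
                   start2 = integer(0), strand2 = character(0),
                   unique2 = logical(0), class = character(0)), gm)
  dc0 <- discordant_coverage(empty, gm)
  expect_equal(sum(dc0$recipient) + sum(dc0$donor), 0)
})

test_that("boundary estimates find peak intersections", {
  # symmetric triangular peaks crossing at offset 0
  off <- seq(-500L, 499L)
  rec <- pmax(0, 300 - abs(off + 150))
  don <- pmax(0, 300 - abs(off - 150))
  dc <- structure(list(offset = off, recipient = rec, donor = don,
                       n_excluded = 0L, read_length = 75L),
                  class = "discordant_coverage")
  est <- boundary_estimate(dc, c(-400, 400), smooth = 5)
  expect_lt(abs(est$boundary_offset), 10)
  # swapping the tracks returns the same coordinate
  swapped <- structure(list(offset = off, recipient = don, donor = rec,
                            n_excluded = 0L, read_length = 75L),
                       class = "discordant_coverage")
  est2 <- boundary_estimate(swapped, c(-400, 400), smooth = 5)
  expect_equal(est2$boundary_offset, est$boundary_offset, tolerance = 1e-8)
  # no crossing in the window: censored
  est3 <- boundary_estimate(dc, c(-400, -100), smooth = 5)
  expect_true(est3$censored)
})

test_that("boundary estimates recover fixed simulated tracts within a read length", {
  gm <- test_genome()
  idx <- test_index()
  for (tract in list(c(200, 100), c(600, 100), c(600, 600))) {
    sp <- sim_params(n_cells = 900, depth = 50, cut_efficiency = 1,
                     repair_fraction = 0.8, repair_time_mean = 4,
                     resynthesis_velocity = 4000, gc_tract_left = tract[1],
                     gc_tract_right = tract[2], gc_tract_fixed = TRUE)
    dp <- dplyr::bind_rows(lapply(c(6, 8, 10), function(t)
      extract_discordant(sim_pairs(gm, sp, t, seed = 83, index = idx)$pairs,
                         gm, timepoint = t)))
    dc <- discordant_coverage(dp, gm)
    bl <- boundary_estimate(dc, c(-730, -50))
    br <- boundary_estimate(dc, c(50, 730))
    expect_false(bl$censored); expect_false(br$censored)
    expect_lt(abs(bl$boundary_offset - (-tract[1])), 75)
    expect_lt(abs(br$boundary_offset - tract[2]), 75)
  }
})

test_that("region classification recovers mixture proportions", {
  gm <- test_genome()
  idx <- test_index()
  # two subpopulations: 70% long left tracts, 30% short; realized by two
  # separate simulations merged with depths in the target ratio (the
  # discordant count scales with sequencing depth, not cell count)
  mk <- function(depth, left, seed) {
    sp <- sim_params(n_cells = 500, depth = depth, cut_efficiency = 1,
                     repair_fraction = 1, repair_time_mean = 3,
                     resynthesis_velocity = 6000, gc_tract_left = left,
                     gc_tract_right = 100, gc_tract_fixed = TRUE)
    dplyr::bind_rows(lapply(c(6, 9), function(t)
      extract_discordant(sim_pairs(gm, sp, t, seed = seed, index = idx)$pairs,
                         gm, timepoint = t)))
  }
  dp <- dplyr::bind_rows(mk(28, 600, seed = 89), mk(12, 150, seed = 97))
  regions <- tibble::tibble(region = c("distal_left", "proximal_left"),
                            lo = c(-725, -362), hi = c(-362, 0))
  cls <- classify_regions(dp, gm, regions)
  expect_equal(sum(cls$proportion), 1)
  n_cl <- sum(cls$n)
  p_distal <- cls$proportion[cls$region == "distal_left"]
  se <- sqrt(0.7 * 0.3 / n_cl)
  expect_lt(abs(p_distal - 0.7), 3 * se + 0.05)
  expect_error(
    classify_regions(dp, gm, tibble::tibble(region = c("a", "b"),
                                            lo = c(-700, -400),
                                            hi = c(-300, 0))),
    "overlapping")
  one <- classify_regions(dp, gm, tibble::tibble(region = "all",
                                                 lo = -725, hi = 725))
  expect_equal(one$proportion, 1)
})

test_that("background pairs stay below the repair-pair signal", {
  gm <- test_genome()
  idx <- test_index()
  sp <- sim_params(n_cells = 600, depth = 30, cut_efficiency = 1,
                   repair_fraction = 0.8, repair_time_mean = 4,
                   resynthesis_velocity = 4000)
  s <- sim_pairs(gm, sp, 10, seed = 101, index = idx)
  dp <- extract_discordant(s$pairs, gm, timepoint = 10)
  bg <- background_fraction(dp, gm, s$total)
  gc_frac <- discordant_fraction(dp, s$total)
  expect_equal(bg$fraction, 0)        # error-free chemistry: no chimeras
  expect_gte(gc_frac$fraction, bg$fraction)
})
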