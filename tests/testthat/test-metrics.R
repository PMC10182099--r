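test_that("short-range resection summarises the +/- 100 nt window", {
  ho <- 5000L
  flat <- fake_profile(rep(1, 100))
  s <- short_range_resection(flat, ho)
  expect_equal(s$decline, c(0, 0))
  expect_equal(attr(s, "asymmetry"), NaN)   # 0/0: no decline on either side
  v <- rep(1, 100); v[50] <- 0.4; v[51] <- 0.8   # left bin 0.4, right bin 0.8
  p <- fake_profile(v)
  s2 <- short_range_resection(p, ho)
  expect_equal(s2$decline[s2$side == "left"], 0.6)
  expect_equal(s2$decline[s2$side == "right"], 0.2)
  expect_equal(attr(s2, "asymmetry"), 3)
  masked <- fake_profile(c(rep(1, 45), rep(NA, 10), rep(1, 45)))
  expect_error(short_range_resection(masked, ho), "masked")
})

test_that("crossing distance is interpolated from a step profile", {
  ho <- 5000L
  v <- rep(1, 100)
  v[31:70] <- 0                       # zero from -2000 to +2000
  p <- fake_profile(v)
  dl <- distance_at_level(p, ho, "left", level = 0.5, smooth_bins = 1)
  dr <- distance_at_level(p, ho, "right", level = 0.5, smooth_bins = 1)
  # crossing between bin mids at 1950 and 2050
  expect_equal(dl$distance, 2000)
  expect_equal(dr$distance, 2000)
  expect_false(dl$censored)
  # profile at or above the level everywhere: front at the break
  d0 <- distance_at_level(fake_profile(rep(0.95, 100)), ho, "left")
  expect_equal(d0$distance, 0)
  # never recovering: censored at the limit
  dc <- distance_at_level(fake_profile(rep(0.1, 100)), ho, "right",
                          censor_at = 3000)
  expect_true(dc$censored)
  expect_equal(dc$distance, 3000)
})

test_that("the resection front is the outermost crossing after smoothing", {
  ho <- 5000L
  v <- rep(1, 100)
  v[41:50] <- 0                       # resected to -1000
  v[30] <- 0.2                        # isolated noisy dip further out
  p <- fake_profile(v)
  noisy <- distance_at_level(p, ho, "left", smooth_bins = 1)
  smoothed <- distance_at_level(p, ho, "left", smooth_bins = 3)
  expect_gt(noisy$distance, 1900)     # raw: spurious outer crossing
  expect_lt(smoothed$distance, 1100)  # median filter removes the dip
})

test_that("long-range rate equals delta s over delta t for two points", {
  ho <- 5000L
  mk <- function(d) {                 # profile resected to distance d
    v <- rep(1, 100)
    z <- (ho %/% 100) + seq(-ceiling(d / 100) + 1L, ceiling(d / 100))
    v[z] <- 0
    fake_profile(v)
  }
  profs <- list("1" = mk(1000), "4" = mk(4000))
  fit <- long_range_rate(profs, ho, smooth_bins = 1)
  expect_equal(fit$rates$rate_nt_per_h, c(1000, 1000), tolerance = 1e-6)
  flat <- list("1" = mk(2000), "2" = mk(2000), "4" = mk(2000))
  fit0 <- long_range_rate(flat, ho, smooth_bins = 1)
  expect_equal(fit0$rates$rate_nt_per_h, c(0, 0), tolerance = 1e-6)
  expect_error(long_range_rate(profs["1"], ho), "two timepoints")
  td <- tidy(fit)
  expect_equal(td$rate_nt_per_h, c(1000, 1000), tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$n_censored, 0L)
})

test_that("long-range rate recovers simulated velocities within 10 percent", {
  gm <- test_genome()
  idx <- test_index()
  for (v in c(2000, 4000)) {
    sp <- sim_params(n_cells = 600, depth = 30, cut_efficiency = 1,
                     resection_delay = 0, velocity_shape = Inf,
                     resection_velocity = v, repair_fraction = 0)
    sims <- lapply(setNames(c(0, 1, 2, 4), c(0, 1, 2, 4)), function(t)
      sim_track(gm, sp, t, seed = 29, index = idx))
    mask <- t0_mask(sims[["0"]]$track)
    profs <- lapply(sims[c("1", "2", "4")], function(s)
      ratio_profile(s$track, sims[["0"]]$track, mask, chromosome = "chrIII",
                    split_at = c(chrIII = gm$ho_site),
                    control_region = gm$control_region))
    fit <- long_range_rate(profs, gm$ho_site,
                           censor_left = 25000, censor_right = 30000)
    expect_lt(max(abs(fit$rates$rate_nt_per_h - v)) / v, 0.10)
  }
})

test_that("crossing distances never regress without re-synthesis", {
  gm <- test_genome()
  idx <- test_index()
  sp <- sim_params(n_cells = 500, depth = 20, cut_efficiency = 1,
                   resection_velocity = 3000, velocity_shape = 8,
                   repair_fraction = 0)
  sims <- lapply(setNames(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4)), function(t)
    sim_track(gm, sp, t, seed = 37, index = idx))
  mask <- t0_mask(sims[["0"]]$track)
  d <- vapply(c("1", "2", "3", "4"), function(tp) {
    p <- ratio_profile(sims[[tp]]$track, sims[["0"]]$track, mask,
                       chromosome = "chrIII",
                       split_at = c(chrIII = gm$ho_site),
                       control_region = gm$control_region)
    distance_at_level(p, gm$ho_site, "right", censor_at = 30000)$distance
  }, numeric(1))
  expect_true(all(diff(d) >= -100))   # one bin of slack for interpolation
})

test_that("maximum resection extent scans outward to the adaptive cutoff", {
  gm <- test_genome()
  rec <- gm$config$recipient
  lens <- nchar(gm$chromosomes)
  flat <- resectr:::new_coverage_track(
    lapply(lens, function(l) rep(1, l)), scaled = TRUE)
  m0 <- max_resection_extent(flat, gm)
  expect_equal(m0$distance, c(0, 0))
  # coverage zero up to the blocking element on the left: censored there
  v <- lapply(lens, function(l) rep(1, l))
  v[[rec]][(gm$ho_site - 25000 + 1):gm$ho_site] <- 0
  blocked <- resectr:::new_coverage_track(v, scaled = TRUE)
  mb <- max_resection_extent(blocked, gm)
  left <- mb[mb$side == "left", ]
  expect_true(left$censored)
  expect_equal(left$distance, 25000)
  expect_equal(left$censor_limit, 25000)
  # extent grows monotonically with the resected span
  prev <- 0
  for (d in c(2000, 8000, 16000)) {
    v2 <- lapply(lens, function(l) rep(1, l))
    v2[[rec]][(gm$ho_site - d + 1):(gm$ho_site + d)] <- 0
    me <- max_resection_extent(resectr:::new_coverage_track(v2, scaled = TRUE), gm)
    expect_true(all(me$distance >= prev))
    prev <- max(me$distance)
  }
})

test_that("synthesis trend lines and initiation rates follow the algebra", {
  ser <- tibble::tibble(time = c(4, 9), value = c(0.1, 0.6),
                        side = "left", distance = 500L)
  tr <- synthesis_rate(ser, c(4, 9))
  expect_equal(tr$m, 0.1)
  ir <- initiation_rate(tr)
  expect_equal(ir$delta_t_h, 5)
  expect_equal(ir$rate_kb_per_h, 0.1)
  flat <- tibble::tibble(time = 4:9, value = rep(0.3, 6),
                         side = "right", distance = 500L)
  tr0 <- synthesis_rate(flat)
  expect_equal(tr0$m, 0)
  expect_false(initiation_rate(tr0)$defined)
  m5 <- synthesis_rate(tibble::tibble(time = c(0, 1), value = c(0, 0.5),
                                      side = "left", distance = 500L))
  expect_equal(initiation_rate(m5)$rate_kb_per_h, 0.5)
  expect_error(synthesis_rate(ser, c(4, 4.5)), "two points")
  expect_equal(glance(tr)$initiation_rate_kb_per_h, 0.1)
})

test_that("coverage series pick the bin at the requested distance", {
  ho <- 5000L
  profs <- list("0" = fake_profile(rep(1, 100)),
                "4" = fake_profile(seq(0.005, 0.995, by = 0.01)))
  ser <- coverage_time_series(profs, ho, 500L, "left")
  expect_equal(ser$value[1], 1)
  # bin [4500,4600) holds the value at ho - 500
  expect_equal(ser$value[2], profs[["4"]]$value[46])
  ser2 <- coverage_time_series(profs, ho, 500L, "right")
  expect_equal(ser2$value[2], profs[["4"]]$value[56])
  masked <- list("0" = fake_profile(c(rep(1, 45), NA, rep(1, 54))))
  expect_error(coverage_time_series(masked, ho, 500L, "left"), "masked")
})

test_that("population-level synthesis rate tracks the repaired fraction", {
  gm <- test_genome()
  idx <- test_index()
  sp <- sim_params(n_cells = 600, depth = 25, cut_efficiency = 1,
                   repair_fraction = 1, repair_time_mean = 6,
                   repair_time_shape = 6, resynthesis_velocity = 4000,
                   gc_tract_left = 200, gc_tract_right = 100,
                   gc_tract_fixed = TRUE)
  times <- c(0, 4, 6, 8, 10)
  sims <- lapply(setNames(times, times), function(t)
    sim_track(gm, sp, t, seed = 43, index = idx))
  mask <- t0_mask(sims[["0"]]$track)
  profs <- lapply(sims[-1], function(s)
    ratio_profile(s$track, sims[["0"]]$track, mask, chromosome = "chrIII",
                  split_at = c(chrIII = gm$ho_site),
                  control_region = gm$control_region))
  ser <- coverage_time_series(profs, gm$ho_site, 500L, "right")
  tr <- synthesis_rate(ser, c(4, 10))
  # expected slope: d/dt P(repair_time <= t - 0.125) over the interval
  expected <- diff(pgamma(c(4, 10) - 0.125, shape = 6, rate = 1)) / 6
  expect_lt(abs(tr$m - expected) / expected, 0.35)
  expect_true(initiation_rate(tr)$defined)
})
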