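#' Analysis constants
#'
#' Every numeric constant of the coverage analysis in one place: the T0
#' low-coverage threshold (0.2), the half-coverage crossing level (0.5),
#' the maximum-resection cutoff (0.9 of the recipient-chromosome mean),
#' the 100-nt ratio bins, 2-kb sections, the +/- 100 nt short-range
#' window, the 1-4 h long-range interval, the 500 / 15000 nt synthesis
#' distances, the default control region, and the 75-nt read length.
#'
#' @param ... overrides of the defaults.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    t0_threshold = 0.2,
    half_coverage_level = 0.5,
    max_extent_cutoff = 0.9,
    bin = 100L,
    section = 2000L,
    short_range_window = 100L,
    resection_interval = c(1, 4),
    synthesis_distances = c(500L, 15000L),
    control_region = list(chromosome = "chrV", start = 210000L, end = 330000L),
    read_length = 75L,
    smooth_bins = 3L,
    insert_bounds = c(75, 2000)
  )
  dots <- list(...)
  assert_that(all(names(dots) %in% names(cfg)),
              "unknown analysis_config field")
  cfg[names(dots)] <- dots
  structure(cfg, class = "analysis_config")
}

# side-resolved view of a ratio profile: distance of each bin's inner and
# outer edge from the cut; the split bin at the cut means position 0
# belongs to neither side
profile_side <- function(profile, ho_site, side,
                         chromosome = profile$chromosome[1]) {
  p <- profile[profile$chromosome == chromosome & !is.na(profile$value), ,
               drop = FALSE]
  if (side == "left") {
    p <- p[p$bin_end <= ho_site, , drop = FALSE]
    p$dist_inner <- ho_site - p$bin_end
    p$dist_outer <- ho_site - p$bin_start
    p$dist_mid <- ho_site - (p$bin_start + p$bin_end) / 2
  } else {
    p <- p[p$bin_start >= ho_site, , drop = FALSE]
    p$dist_inner <- p$bin_start - ho_site
    p$dist_outer <- p$bin_end - ho_site
    p$dist_mid <- (p$bin_start + p$bin_end) / 2 - ho_site
  }
  p[order(p$dist_mid), , drop = FALSE]
}

#' Short-range resection summary at 1 h
#'
#' Mean T0-normalized coverage decline over the +/- `window` nt flanking
#' the cut, per side, plus the left/right asymmetry of the decline.
#'
#' @param profile_1h `ratio_profile` of the 1 h sample (built with
#'   `split_at` the cut so bins do not straddle it).
#' @param ho_site cut coordinate.
#' @param window half-window in nt (default 100).
#' @param chromosome recipient chromosome (default: first in profile).
#' @return tibble (side, mean_ratio, decline) with attribute `asymmetry`
#'   (= left decline / right decline).
#' @export
short_range_resection <- function(profile_1h, ho_site, window = 100L,
                                  chromosome = profile_1h$chromosome[1]) {
  sides <- lapply(c("left", "right"), function(s) {
    p <- profile_side(profile_1h, ho_site, s, chromosome)
    p <- p[p$dist_inner < window, , drop = FALSE]
    if (nrow(p) == 0) abort("short-range window fully masked")
    w <- pmin(p$dist_outer, window) - p$dist_inner
    tibble(side = s, mean_ratio = sum(p$value * w) / sum(w))
  })
  out <- bind_rows(sides) |> mutate(decline = 1 - .data$mean_ratio)
  attr(out, "asymmetry") <- out$decline[out$side == "left"] /
    out$decline[out$side == "right"]
  out
}

#' Distance from the cut where coverage crosses a level
#'
#' Scans outward from the cut and returns the linearly interpolated
#' distance of the resection front: the outermost upward crossing of
#' `level`, i.e. the last point below `level` before the profile stays at
#' or above it. A 3-bin running median (configurable; width 1 disables)
#' suppresses spurious crossings from counting noise; ties are broken
#' toward the break. If the profile is at or above `level` everywhere the
#' front is at the break (distance 0); if it never comes back up the
#' estimate is censored at the blocking element or chromosome end.
#'
#' @param profile a `ratio_profile` (split at the cut).
#' @param ho_site cut coordinate.
#' @param side `"left"` or `"right"`.
#' @param level crossing level (default 0.5).
#' @param smooth_bins running-median width in bins.
#' @param censor_at censoring distance (blocking element or chromosome
#'   end); defaults to the outermost available bin.
#' @param chromosome recipient chromosome.
#' @return tibble (side, distance, censored, censor_limit).
#' @export
distance_at_level <- function(profile, ho_site, side, level = 0.5,
                              smooth_bins = 3L, censor_at = NULL,
                              chromosome = profile$chromosome[1]) {
  p <- profile_side(profile, ho_site, side, chromosome)
  if (!is.null(censor_at)) p <- p[p$dist_mid <= censor_at, , drop = FALSE]
  if (nrow(p) == 0) abort("profile fully masked on that side")
  limit <- censor_at %||% max(p$dist_outer)
  v <- smooth_median(p$value, smooth_bins)
  d <- p$dist_mid
  if (v[1] >= level) return(tibble(side = side, distance = 0,
                                   censored = FALSE, censor_limit = limit))
  above <- v >= level
  if (!any(above)) return(tibble(side = side, distance = limit,
                                 censored = TRUE, censor_limit = limit))
  # outermost upward crossing: last below-level bin whose successors
  # include the final plateau at/above level
  i <- max(which(!above))
  if (i == length(v)) {
    # profile dips below level at the outermost bin: censored
    return(tibble(side = side, distance = limit, censored = TRUE,
                  censor_limit = limit))
  }
  x0 <- d[i]; x1 <- d[i + 1]; y0 <- v[i]; y1 <- v[i + 1]
  dist <- if (y1 == y0) x0 else x0 + (level - y0) / (y1 - y0) * (x1 - x0)
  tibble(side = side, distance = dist, censored = FALSE, censor_limit = limit)
}

#' Long-range resection rate from the 0.5-coverage crossing
#'
#' Ordinary least-squares slope of the half-coverage distance against
#' time over the 1-4 h interval (`v = delta_s / delta_t`; for two
#' timepoints the slope equals the difference quotient exactly).
#' Censored distances are excluded from the regression.
#'
#' @param profiles named list of `ratio_profile`s; names are hours.
#' @param ho_site cut coordinate.
#' @param level crossing level (default 0.5).
#' @param interval time interval in hours (default `c(1, 4)`).
#' @param smooth_bins,censor_left,censor_right passed to
#'   [distance_at_level()] per side.
#' @param chromosome recipient chromosome.
#' @return object of class `resection_rate_fit`: list with `rates`
#'   (tibble side, rate_nt_per_h), `distances` (per timepoint) and the
#'   per-side `lm` fits. Supports [generics::tidy()] / [generics::glance()].
#' @export
long_range_rate <- function(profiles, ho_site, level = 0.5,
                            interval = c(1, 4), smooth_bins = 3L,
                            censor_left = NULL, censor_right = NULL,
                            chromosome = NULL) {
  times <- as.numeric(names(profiles))
  assert_that(!any(is.na(times)), "profiles must be named by hours")
  use <- times >= interval[1] & times <= interval[2]
  assert_that(sum(use) >= 2, "need at least two timepoints in the interval")
  chromosome <- chromosome %||% profiles[[1]]$chromosome[1]
  dist <- bind_rows(lapply(which(use), function(i) {
    bind_rows(
      distance_at_level(profiles[[i]], ho_site, "left", level, smooth_bins,
                        censor_left, chromosome),
      distance_at_level(profiles[[i]], ho_site, "right", level, smooth_bins,
                        censor_right, chromosome)
    ) |> mutate(time = times[i])
  }))
  fits <- lapply(c(left = "left", right = "right"), function(s) {
    d <- dist[dist$side == s & !dist$censored, , drop = FALSE]
    if (nrow(d) < 2) abort(sprintf("all %s-side timepoints censored", s))
    lm(distance ~ time, data = d)
  })
  rates <- tibble(side = names(fits),
                  rate_nt_per_h = unname(vapply(fits, function(f)
                    coef(f)[["time"]], numeric(1))))
  structure(list(rates = rates, distances = dist, fits = fits,
                 level = level, interval = interval),
            class = "resection_rate_fit")
}

#' @export
print.resection_rate_fit <- function(x, ...) {
  cat(sprintf("<resection_rate_fit> %.1f-coverage crossing, %g-%g h\n",
              x$level, x$interval[1], x$interval[2]))
  print(x$rates)
  invisible(x)
}

#' Maximum extent of resection at a coverage cutoff
#'
#' Outward scan from the cut for the first distance at which the binned,
#' RPGC-scaled coverage of the sample reaches `cutoff` times the mean
#' coverage of the recipient chromosome of the same sample (computed over
#' unmasked positions, before T0 normalization). Since ssDNA-rich samples
#' have a depressed chromosome mean, the effective cutoff adapts per
#' sample. Censored at the blocking element / chromosome end when the
#' coverage never reaches the cutoff.
#'
#' @param track scaled `coverage_track` of the sample.
#' @param genome the `genome_map` (supplies the cut, chromosome and
#'   blocking element).
#' @param mask T0 mask from [t0_mask()].
#' @param cutoff fraction of the chromosome mean (default 0.9).
#' @param bin bin width for the scan (default 100).
#' @param smooth_bins running-median width.
#' @return tibble (side, distance, censored, censor_limit, threshold).
#' @export
max_resection_extent <- function(track, genome, mask = NULL, cutoff = 0.9,
                                 bin = 100L, smooth_bins = 3L) {
  rec <- genome$config$recipient
  ho <- genome$ho_site
  v <- track$data[[rec]]
  m <- mask[[rec]] %||% rep(FALSE, length(v))
  chrom_mean <- mean(v[!m])
  thr <- cutoff * chrom_mean
  len <- length(v)
  block <- genome$block_elements$position[genome$block_elements$chromosome == rec]
  limits <- c(left = if (length(block)) ho - min(block) else ho,
              right = len - ho)
  out <- lapply(c("left", "right"), function(s) {
    limit <- limits[[s]]
    # bin means outward from the cut on this side, masked positions dropped
    n_bins <- ceiling(limit / bin)
    starts <- (seq_len(n_bins) - 1L) * bin
    vals <- vapply(starts, function(d0) {
      idx <- if (s == "left") (ho - pmin(d0 + bin, limit) + 1L):(ho - d0)
      else (ho + d0 + 1L):(ho + pmin(d0 + bin, limit))
      x <- v[idx][!m[idx]]
      if (length(x) == 0) NA_real_ else mean(x)
    }, numeric(1))
    keep <- !is.na(vals)
    d_mid <- starts + bin / 2
    vals <- smooth_median(vals[keep], smooth_bins)
    d_mid <- d_mid[keep]
    if (length(vals) == 0 || vals[1] >= thr)
      return(tibble(side = s, distance = 0, censored = FALSE,
                    censor_limit = limit, threshold = thr))
    i <- which(vals >= thr)
    if (length(i) == 0)
      return(tibble(side = s, distance = limit, censored = TRUE,
                    censor_limit = limit, threshold = thr))
    i <- min(i)
    x0 <- d_mid[i - 1]; x1 <- d_mid[i]; y0 <- vals[i - 1]; y1 <- vals[i]
    dist <- if (y1 == y0) x1 else x0 + (thr - y0) / (y1 - y0) * (x1 - x0)
    tibble(side = s, distance = dist, censored = FALSE,
           censor_limit = limit, threshold = thr)
  })
  bind_rows(out)
}

#' Coverage-versus-time series at a fixed distance from the cut
#'
#' @param profiles named list of `ratio_profile`s (names = hours).
#' @param ho_site cut coordinate.
#' @param distance distance from the cut in nt (e.g. 500 or 15000).
#' @param side `"left"` or `"right"`.
#' @param chromosome recipient chromosome.
#' @return tibble (time, value, side, distance).
#' @export
coverage_time_series <- function(profiles, ho_site, distance, side,
                                 chromosome = NULL) {
  times <- as.numeric(names(profiles))
  chromosome <- chromosome %||% profiles[[1]]$chromosome[1]
  pos <- if (side == "left") ho_site - distance else ho_site + distance
  vals <- vapply(profiles, function(p) {
    p <- p[p$chromosome == chromosome & p$bin_start <= pos &
             p$bin_end > pos, , drop = FALSE]
    if (nrow(p) == 0 || is.na(p$value[1])) {
      abort("bin containing the requested distance is masked")
    }
    p$value[1]
  }, numeric(1))
  tibble(time = times, value = unname(vals), side = side,
         distance = distance)
}

#' Re-synthesis rate from a coverage trend line
#'
#' Least-squares line `y = m x + b` through the coverage-vs-time series
#' over `interval`; the synthesis rate S is the slope m (coverage units
#' per hour).
#'
#' @param series tibble from [coverage_time_series()].
#' @param interval hours, e.g. `c(4, 10)`.
#' @return object of class `synthesis_trend` (fields `m`, `b`, `fit`,
#'   `series`, `interval`); supports [generics::tidy()] /
#'   [generics::glance()].
#' @export
synthesis_rate <- function(series, interval = range(series$time)) {
  d <- series[series$time >= interval[1] & series$time <= interval[2], ,
              drop = FALSE]
  assert_that(nrow(d) >= 2, "need at least two points in the interval")
  fit <- lm(value ~ time, data = d)
  structure(list(m = coef(fit)[["time"]], b = coef(fit)[["(Intercept)"]],
                 fit = fit, series = d, interval = interval,
                 side = series$side[1], distance = series$distance[1]),
            class = "synthesis_trend")
}

#' @export
print.synthesis_trend <- function(x, ...) {
  cat(sprintf("<synthesis_trend> side %s at %d nt: y = %.4f x + %.4f (%g-%g h)\n",
              x$side, x$distance, x$m, x$b, x$interval[1], x$interval[2]))
  invisible(x)
}

#' Re-synthesis initiation rate from a trend line
#'
#' Time to progress from coverage 0 to 0.5 along the trend line is
#' `delta_t = 0.5 / m`; with `delta_s` fixed at 0.5 kb the initiation
#' rate is `v = 0.5 / delta_t` kb/h (numerically equal to the slope when
#' coverage is per-hour). Undefined (NA, flagged) for non-positive
#' slopes.
#'
#' @param trend a `synthesis_trend` (fit at the 0.5-kb distance).
#' @param delta_s coverage span / distance in kb (default 0.5).
#' @return tibble (side, delta_t_h, rate_kb_per_h, defined).
#' @export
initiation_rate <- function(trend, delta_s = 0.5) {
  if (trend$m <= 1e-12) {   # numerically flat or declining trend
    return(tibble(side = trend$side, delta_t_h = NA_real_,
                  rate_kb_per_h = NA_real_, defined = FALSE))
  }
  dt <- delta_s / trend$m
  tibble(side = trend$side, delta_t_h = dt, rate_kb_per_h = delta_s / dt,
         defined = TRUE)
}
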