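#' Per-polymorphism donor-allele representation
#'
#' For every polymorphic site the coverage of the donor and recipient
#' coordinates is taken as the mean over the read-length window centered
#' on the site (any overlapping 0-mismatch read is allele-informative),
#' each normalized by its own T0 value. Reported per site:
#' `raw_fraction = d / (d + r)` (donor share; 0.5 at baseline) and
#' `donor_excess = d - 1` (T0-normalized donor coverage gain; 0 at
#' baseline, and in expectation equal to the probability that the site
#' lies inside a conversion tract times the repaired fraction of the
#' population). Sites with zero T0 coverage are flagged unusable.
#'
#' Both per-site ratios are divided by the control-region ratio of the
#' sample pair, so that genome-wide RPGC inflation from single-stranded
#' regions does not masquerade as donor-allele gain.
#'
#' @param track_tx,track_t0 scaled `coverage_track`s of the repaired and
#'   undamaged samples.
#' @param genome a `genome_map`.
#' @param window averaging window in nt (default 75, the read length).
#' @param include_inc also report the HO-inc core variant site.
#' @param control_region list (chromosome, start, end); defaults to the
#'   genome's annotated control region.
#' @return a tibble: site index, offset_from_ho, side, recipient /
#'   donor coverages, raw_fraction, donor_excess, usable.
#' @export
site_fractions <- function(track_tx, track_t0, genome, window = 75L,
                           include_inc = TRUE,
                           control_region = genome$control_region) {
  sites <- genome$polymorphisms
  if (include_inc && !is.null(genome$ho_inc_variant))
    sites <- bind_rows(sites, genome$ho_inc_variant)
  rec <- genome$config$recipient
  don <- genome$config$donor
  half <- window %/% 2L
  win_mean <- function(v, pos) {
    i0 <- pmax(pos - half, 0L) + 1L
    i1 <- pmin(pos + half + 1L, length(v))
    vapply(seq_along(pos), function(k) mean(v[i0[k]:i1[k]]), numeric(1))
  }
  r_tx <- win_mean(track_tx$data[[rec]], sites$recipient_pos)
  r_t0 <- win_mean(track_t0$data[[rec]], sites$recipient_pos)
  d_tx <- win_mean(track_tx$data[[don]], sites$donor_pos)
  d_t0 <- win_mean(track_t0$data[[don]], sites$donor_pos)
  cf <- if (is.null(control_region)) 1
        else control_ratio(track_tx, track_t0, control_region)
  usable <- r_t0 > 0 & d_t0 > 0
  r <- ifelse(usable, r_tx / r_t0 / cf, NA_real_)
  d <- ifelse(usable, d_tx / d_t0 / cf, NA_real_)
  tibble(site = seq_len(nrow(sites)),
         offset_from_ho = sites$offset_from_ho,
         side = ifelse(sites$offset_from_ho < 0, "left", "right"),
         recipient_ratio = r, donor_ratio = d,
         raw_fraction = d / (d + r),
         donor_excess = d - 1,
         usable = usable)
}

#' Repair-efficiency correction factor
#'
#' The maximum over the time course of the T0-normalized coverage at
#' 0.5 kb from the cut: the fraction of cells that ever restored duplex
#' DNA there, i.e. the repaired fraction. Computed per side (left sites
#' are corrected with the left recovery, right sites with the right);
#' a single pooled factor (the mean of the two) is also reported.
#'
#' The undamaged T0 sample is the normalization reference and is excluded
#' from the maximum. The estimate assumes the probed distance lies beyond
#' the conversion tract: cells whose tract covers it emit donor-allele
#' reads there, which depresses recipient-side recovery.
#'
#' @param profiles named list of `ratio_profile`s over the time course
#'   (names = hours).
#' @param ho_site cut coordinate.
#' @param distance distance from the cut in nt (default 500).
#' @param chromosome recipient chromosome.
#' @return tibble (side, factor) with attribute `pooled`.
#' @export
correction_factor <- function(profiles, ho_site, distance = 500L,
                              chromosome = NULL) {
  profiles <- profiles[as.numeric(names(profiles)) > 0]
  assert_that(length(profiles) > 0, "no post-induction profiles supplied")
  out <- bind_rows(lapply(c("left", "right"), function(s) {
    ser <- coverage_time_series(profiles, ho_site, distance, s, chromosome)
    tibble(side = s, factor = max(ser$value))
  }))
  attr(out, "pooled") <- mean(out$factor)
  out
}

#' Correct per-site conversion estimates for incomplete repair
#'
#' Divides the donor-coverage excess by the repair-fraction correction
#' factor (per side by default, pooled on request), yielding the
#' per-site conversion probability among repaired cells, capped to
#' `[0, 1]`.
#'
#' @param fractions tibble from [site_fractions()].
#' @param factors tibble from [correction_factor()].
#' @param pooled use the single pooled factor for both sides.
#' @return the input tibble with `correction_factor` and
#'   `corrected_fraction` columns.
#' @export
apply_gc_correction <- function(fractions, factors, pooled = FALSE) {
  if (pooled) {
    f <- rep(attr(factors, "pooled"), nrow(fractions))
  } else {
    f <- factors$factor[match(fractions$side, factors$side)]
  }
  fractions |>
    mutate(correction_factor = f,
           corrected_fraction = pmin(pmax(.data$donor_excess, 0) / f, 1))
}
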