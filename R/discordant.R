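#' Extract inter-chromosomal discordant read pairs
#'
#' Keeps pairs whose two mates map uniquely to different chromosomes.
#' Pairs joining the recipient and donor chromosomes are the
#' gene-conversion signal; all other inter-chromosomal combinations are
#' retained (flagged `background = TRUE`) for background estimation.
#'
#' @param pairs classified pairs from [pair_reads()].
#' @param genome a `genome_map`.
#' @param timepoint hours, recorded in the output.
#' @return tibble of class `discordant_pairs`: pair_id,
#'   recipient_coord, donor_coord (leftmost mapped base of the mate on
#'   each chromosome; NA for background pairs), chrom1/chrom2,
#'   strands, background, timepoint.
#' @export
extract_discordant <- function(pairs, genome, timepoint = NA_real_) {
  rec <- genome$config$recipient
  don <- genome$config$donor
  d <- pairs[pairs$class == "discordant", , drop = FALSE]
  is_gc <- (d$chrom1 == rec & d$chrom2 == don) |
    (d$chrom1 == don & d$chrom2 == rec)
  rec_coord <- ifelse(d$chrom1 == rec, d$start1,
                      ifelse(d$chrom2 == rec, d$start2, NA_integer_))
  don_coord <- ifelse(d$chrom1 == don, d$start1,
                      ifelse(d$chrom2 == don, d$start2, NA_integer_))
  out <- tibble(pair_id = d$pair_id,
                recipient_coord = rec_coord,
                donor_coord = don_coord,
                chrom1 = d$chrom1, chrom2 = d$chrom2,
                strand1 = d$strand1, strand2 = d$strand2,
                background = !is_gc,
                timepoint = timepoint)
  class(out) <- c("discordant_pairs", class(out))
  out
}

#' Discordant-pair fraction of the library
#'
#' Proportion of recipient-donor discordant pairs relative to the total
#' number of reads analyzed (counted before any filtering).
#'
#' @param pairs a `discordant_pairs` tibble.
#' @param total_reads total reads in the library.
#' @return tibble (timepoint, n_pairs, total_reads, fraction).
#' @export
discordant_fraction <- function(pairs, total_reads) {
  assert_that(all(total_reads > 0), "total read count must be positive")
  gc <- pairs[!pairs$background, , drop = FALSE]
  out <- gc |>
    count(.data$timepoint, name = "n_pairs") |>
    tidyr::complete(timepoint = unique(pairs$timepoint),
                    fill = list(n_pairs = 0L))
  tot <- if (!is.null(names(total_reads)))
    unname(total_reads[as.character(out$timepoint)]) else total_reads
  out |> mutate(total_reads = tot,
                fraction = .data$n_pairs / .data$total_reads)
}

#' Quadrant classification of a recipient/donor discordant pair
#'
#' The recipient axis is divided at the cut (HO) and the donor axis at
#' the uncleavable donor site (HO-inc); coordinates exactly at a divider
#' go right/top (>= convention). Bottom quadrants are boundaries of
#' conversion events on the left side of the break (LB = left boundary,
#' RB = right boundary); top quadrants are events on the right side.
#'
#' @param pairs a `discordant_pairs` tibble (background pairs excluded).
#' @param ho_site,ho_inc_site divider coordinates.
#' @return the tibble with a `quadrant` factor column (LB, RB, LT, RT).
#' @export
classify_quadrant <- function(pairs, ho_site, ho_inc_site) {
  p <- pairs[!pairs$background, , drop = FALSE]
  left <- p$recipient_coord < ho_site
  bottom <- p$donor_coord < ho_inc_site
  p$quadrant <- factor(ifelse(bottom, ifelse(left, "LB", "RB"),
                              ifelse(left, "LT", "RT")),
                       levels = c("LB", "RB", "LT", "RT"))
  p
}

#' Break-centered coverage of the discordant mates
#'
#' Builds two per-base coverage tracks over the homology region: one from
#' the recipient-chromosome mates, one from the donor-chromosome mates
#' with donor coordinates translated into the recipient frame through the
#' homology-arm correspondence (donor_pos - ho_inc + ho). Donor mates
#' whose footprint leaves the homology arms cannot be translated and are
#' flagged and excluded.
#'
#' @param pairs a `discordant_pairs` tibble.
#' @param genome a `genome_map`.
#' @param read_length mate footprint (nt).
#' @param span half-width of the break-centered frame (nt).
#' @return list of class `discordant_coverage`: `offset` (positions
#'   relative to the cut), `recipient`, `donor` (per-base counts),
#'   `n_excluded`.
#' @export
discordant_coverage <- function(pairs, genome, read_length = 75L,
                                span = NULL) {
  ho <- genome$ho_site
  inc <- genome$ho_inc_site
  cfg <- genome$config
  span <- span %||% (cfg$arm_length + cfg$ho_core_length %/% 2L +
                       as.integer(read_length))
  p <- pairs[!pairs$background, , drop = FALSE]
  arms <- genome$homology_arms
  don_arms <- arms[arms$chromosome == cfg$donor, , drop = FALSE]
  don_lo <- min(don_arms$start); don_hi <- max(don_arms$end)
  translatable <- p$donor_coord >= don_lo & p$donor_coord + read_length <= don_hi
  n_excluded <- sum(!translatable)

  offs <- seq(-span, span - 1L)
  cover <- function(starts) {
    v <- numeric(2L * span)
    s <- pmax(starts, -span)
    e <- pmin(starts + read_length, span)
    ok <- e > s
    for (i in which(ok)) {
      idx <- (s[i] + span + 1L):(e[i] + span)
      v[idx] <- v[idx] + 1
    }
    v
  }
  rec_track <- cover(p$recipient_coord - ho)
  don_track <- cover(p$donor_coord[translatable] - inc)
  structure(list(offset = offs, recipient = rec_track, donor = don_track,
                 n_excluded = n_excluded, read_length = read_length),
            class = "discordant_coverage")
}

#' Conversion-boundary estimate from intersecting coverage peaks
#'
#' Within a window of the break-centered frame, finds the offset where
#' the recipient-mate and donor-mate coverage difference changes sign
#' (linearly interpolated): the point where the two peaks intersect,
#' i.e. a conversion tract boundary. With several sign changes the
#' crossing with the strongest support (largest min of the two tracks,
#' ties toward the window center) is returned. Censored (NA) when the
#' tracks do not cross inside the window.
#'
#' @param dc a `discordant_coverage`.
#' @param window `c(lo, hi)` offsets from the cut.
#' @param smooth running-mean half-width in nt for the difference track.
#' @return tibble (window_lo, window_hi, boundary_offset, censored).
#' @export
boundary_estimate <- function(dc, window, smooth = 25L) {
  sel <- dc$offset >= window[1] & dc$offset <= window[2]
  assert_that(any(sel), "window outside the frame")
  off <- dc$offset[sel]
  r <- dc$recipient[sel]; d <- dc$donor[sel]
  assert_that(sum(r) > 0 && sum(d) > 0,
              "both tracks must be nonzero in the window")
  k <- 2L * as.integer(smooth) + 1L
  ma <- function(x) as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  diffs <- ma(r) - ma(d)
  supp <- pmin(ma(r), ma(d))
  ok <- !is.na(diffs)
  idx <- which(ok[-length(ok)] & ok[-1] &
                 sign(diffs[-length(diffs)]) * sign(diffs[-1]) < 0)
  if (length(idx) == 0) {
    zero <- which(ok & diffs == 0 & supp > 0)
    if (length(zero) > 0)
      return(tibble(window_lo = window[1], window_hi = window[2],
                    boundary_offset = off[zero[which.max(supp[zero])]],
                    censored = FALSE))
    return(tibble(window_lo = window[1], window_hi = window[2],
                  boundary_offset = NA_real_, censored = TRUE))
  }
  center <- mean(window)
  score <- supp[idx] - abs(off[idx] - center) * 1e-9
  i <- idx[which.max(score)]
  x0 <- off[i]; x1 <- off[i + 1]; y0 <- diffs[i]; y1 <- diffs[i + 1]
  cross <- x0 + (0 - y0) / (y1 - y0) * (x1 - x0)
  tibble(window_lo = window[1], window_hi = window[2],
         boundary_offset = cross, censored = FALSE)
}

#' Assign discordant pairs to boundary regions and summarise
#'
#' Each pair is reduced to a boundary position estimate (the midpoint
#' between the inner edges of its two mates in the break-centered frame)
#' and assigned to the unique region band containing it; pairs outside
#' every band are `unclassified`. Proportions are reported over
#' classified pairs, and a representative tract extent per region is the
#' peak-intersection estimate inside the region window.
#'
#' @param pairs a `discordant_pairs` tibble.
#' @param genome a `genome_map`.
#' @param regions tibble (region, lo, hi) of non-overlapping half-open
#'   offset bands in the break-centered frame; see [default_regions()].
#' @param read_length mate footprint (nt).
#' @return tibble (region, lo, hi, n, proportion, boundary_offset,
#'   boundary_censored); attribute `n_unclassified`.
#' @export
classify_regions <- function(pairs, genome, regions, read_length = 75L) {
  assert_that(all(regions$hi > regions$lo), "empty region band")
  o <- order(regions$lo)
  assert_that(all(regions$hi[o][-nrow(regions)] <= regions$lo[o][-1]),
              "overlapping region definitions")
  ho <- genome$ho_site; inc <- genome$ho_inc_site
  p <- pairs[!pairs$background, , drop = FALSE]
  rec_off <- p$recipient_coord - ho
  don_off <- p$donor_coord - inc
  # midpoint between the inner edges of the two mates: the left mate's
  # right end and the right mate's left start
  left_off <- pmin(rec_off, don_off)
  right_off <- pmax(rec_off, don_off)
  boundary <- (left_off + read_length + right_off) / 2
  ri <- rep(NA_integer_, length(boundary))
  for (i in seq_len(nrow(regions))) {
    ri[boundary >= regions$lo[i] & boundary < regions$hi[i]] <- i
  }
  n_uncl <- sum(is.na(ri))
  counts <- tabulate(ri, nbins = nrow(regions))
  dc <- discordant_coverage(pairs, genome, read_length)
  ests <- lapply(seq_len(nrow(regions)), function(i) {
    win <- c(regions$lo[i], regions$hi[i])
    tryCatch(boundary_estimate(dc, win),
             error = function(e) tibble(window_lo = win[1], window_hi = win[2],
                                        boundary_offset = NA_real_,
                                        censored = TRUE))
  })
  est <- bind_rows(ests)
  out <- tibble(region = regions$region, lo = regions$lo, hi = regions$hi,
                n = counts,
                proportion = if (sum(counts) > 0) counts / sum(counts)
                             else rep(NA_real_, length(counts)),
                boundary_offset = est$boundary_offset,
                boundary_censored = est$censored)
  attr(out, "n_unclassified") <- n_uncl
  out
}

#' Default region bands from the coverage-peak intersections
#'
#' Derives five bands (distal left, mid left, proximal left, proximal
#' right, distal right) from the two strongest recipient/donor peak
#' intersections on each side of the cut; these are a graphical
#' convention, so any explicit `regions` tibble can override them.
#'
#' @param dc a `discordant_coverage`.
#' @param span outer limit of the bands (default the frame edge).
#' @return tibble (region, lo, hi).
#' @export
default_regions <- function(dc, span = max(dc$offset) + 1L) {
  est_l <- tryCatch(boundary_estimate(dc, c(-span, 0)),
                    error = function(e) NULL)
  est_r <- tryCatch(boundary_estimate(dc, c(0, span)),
                    error = function(e) NULL)
  bl <- if (!is.null(est_l) && !est_l$censored) est_l$boundary_offset else -span / 2
  br <- if (!is.null(est_r) && !est_r$censored) est_r$boundary_offset else span / 2
  tibble(region = c("A", "B", "C", "D", "E"),
         lo = c(-span, bl - 100, bl / 2, 0, br + 100),
         hi = c(bl - 100, bl / 2, 0, br + 100, span))
}

#' Background discordant fraction against an uninvolved chromosome
#'
#' @param pairs a `discordant_pairs` tibble (background pairs included).
#' @param genome a `genome_map`.
#' @param total_reads total reads analyzed.
#' @param control_chrom chromosome not involved in repair (default the
#'   genome's background chromosome).
#' @return tibble (n_pairs, total_reads, fraction).
#' @export
background_fraction <- function(pairs, genome, total_reads,
                                control_chrom = genome$config$background) {
  rec <- genome$config$recipient
  sel <- (pairs$chrom1 == rec & pairs$chrom2 == control_chrom) |
    (pairs$chrom1 == control_chrom & pairs$chrom2 == rec)
  tibble(n_pairs = sum(sel), total_reads = total_reads,
         fraction = sum(sel) / total_reads)
}
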