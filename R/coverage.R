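new_coverage_track <- function(data, scaled = FALSE) {
  structure(list(data = data, scaled = scaled), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track>%s\n", if (x$scaled) " (RPGC-scaled)" else ""))
  for (nm in names(x$data))
    cat(sprintf("  %s: %d nt, mean %.3f\n", nm, length(x$data[[nm]]),
                mean(x$data[[nm]])))
  invisible(x)
}

#' @export
as_tibble.coverage_track <- function(x, ...) {
  bind_rows(lapply(names(x$data), function(nm)
    tibble(chromosome = nm, pos = seq_along(x$data[[nm]]) - 1L,
           coverage = x$data[[nm]])))
}

#' Per-base coverage from alignments
#'
#' Each uniquely mapped alignment increments every base it covers by 1;
#' non-unique alignments are dropped (deterministic alternative to the
#' arbitrary single locus reported by `-k 1`-style aligners).
#'
#' @param aln alignment tibble from [map_reads()] (or [read_sam()]).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param read_length alignment footprint (nt).
#' @return a `coverage_track`.
#' @export
per_base_coverage <- function(aln, chrom_lengths, read_length = 75L) {
  use <- aln[aln$mapped & (aln$unique %||% TRUE), , drop = FALSE]
  if (!is.null(use$unique)) use <- use[use$unique, , drop = FALSE]
  data <- lapply(setNames(names(chrom_lengths), names(chrom_lengths)),
                 function(nm) {
    len <- as.integer(chrom_lengths[nm])
    sel <- use[use$chromosome == nm, , drop = FALSE]
    if (nrow(sel) == 0) return(numeric(len))
    if (any(sel$start < 0 | sel$start + read_length > len))
      abort(sprintf("alignment beyond bounds of %s", nm))
    cov <- IRanges::coverage(IRanges::IRanges(start = sel$start + 1L,
                                              width = read_length),
                             width = len)
    as.numeric(cov)
  })
  new_coverage_track(data, scaled = FALSE)
}

#' RPGC-style scaling of a coverage track
#'
#' Divides every value by the genome-wide mean so the mean per-base
#' coverage becomes 1 (reads-per-genomic-content normalization).
#'
#' @param track an unscaled `coverage_track`.
#' @return a scaled `coverage_track`.
#' @export
rpgc_scale <- function(track) {
  assert_that(!track$scaled, "track is already scaled")
  tot <- sum(vapply(track$data, sum, numeric(1)))
  len <- sum(vapply(track$data, length, numeric(1)))
  if (tot == 0) abort("zero total coverage; cannot scale")
  m <- tot / len
  new_coverage_track(lapply(track$data, function(v) v / m), scaled = TRUE)
}

#' Low-coverage mask from the undamaged (T0) sample
#'
#' Positions whose scaled T0 coverage falls below `threshold` are masked
#' from the whole sample set: they reflect low intrinsic mappability, not
#' resection.
#'
#' @param track_t0 scaled `coverage_track` of the 0 h sample.
#' @param threshold scaled-coverage cutoff (default 0.2).
#' @return named list of logical vectors (TRUE = masked).
#' @export
t0_mask <- function(track_t0, threshold = 0.2) {
  assert_that(track_t0$scaled, "T0 track must be RPGC-scaled first")
  lapply(track_t0$data, function(v) v < threshold)
}

#' Binned coverage-ratio profile against the T0 sample
#'
#' Per unmasked position the ratio `tx / t0` is computed, then averaged
#' in `bin`-nt bins anchored at coordinate 0. When `split_at` is given
#' (the cut coordinate), the bin containing it is split into two partial
#' bins at the cut, so that position 0 of each side belongs to exactly
#' one side. Fully masked bins carry `NA`.
#'
#' When `control_region` is given, every ratio is additionally divided by
#' the control-region ratio of the same sample pair, removing the
#' genome-wide inflation that RPGC scaling introduces once part of the
#' genome is single-stranded (the same correction the section profiles
#' apply).
#'
#' @param track_tx,track_t0 scaled `coverage_track`s of the same genome.
#' @param mask mask from [t0_mask()] (guarantees no division by zero).
#' @param bin bin width in nt (default 100).
#' @param chromosome optional chromosome subset.
#' @param split_at optional named vector of split coordinates, e.g.
#'   `c(chrIII = ho_site)`.
#' @param control_region optional list (chromosome, start, end).
#' @param timepoint hours, recorded in the output.
#' @return a tibble of class `ratio_profile`: chromosome, bin_start,
#'   bin_end, value, n (unmasked positions), timepoint.
#' @export
ratio_profile <- function(track_tx, track_t0, mask, bin = 100L,
                          chromosome = NULL, split_at = NULL,
                          control_region = NULL, timepoint = NA_real_) {
  assert_that(track_tx$scaled && track_t0$scaled,
              "both tracks must be RPGC-scaled")
  cf <- if (is.null(control_region)) 1
        else control_ratio(track_tx, track_t0, control_region)
  chroms <- chromosome %||% names(track_tx$data)
  out <- lapply(chroms, function(nm) {
    tx <- track_tx$data[[nm]]; t0 <- track_t0$data[[nm]]
    m <- mask[[nm]] %||% rep(FALSE, length(t0))
    ratio <- ifelse(m, NA_real_, tx / t0 / cf)
    pos <- seq_along(ratio) - 1L
    bin_start <- (pos %/% bin) * bin
    s <- split_at[nm]
    if (!is.null(split_at) && !is.na(s)) {
      in_split_bin <- bin_start == (s %/% bin) * bin
      bin_start <- ifelse(in_split_bin & pos >= s, s, bin_start)
    }
    dt <- data.table::data.table(bin_start = bin_start, ratio = ratio)
    agg <- dt[, list(s = sum(ratio, na.rm = TRUE),
                     n = sum(!is.na(ratio))), by = "bin_start"]
    agg$value <- ifelse(agg$n > 0, agg$s / agg$n, NA_real_)
    ends <- (agg$bin_start %/% bin) * bin + bin
    if (!is.null(split_at) && !is.na(s)) {
      # partial bin left of the split ends at the split coordinate
      ends[agg$bin_start == (s %/% bin) * bin & s > agg$bin_start &
             s < agg$bin_start + bin] <- s
    }
    tibble(chromosome = nm, bin_start = agg$bin_start,
           bin_end = pmin(ends, length(ratio)),
           value = agg$value, n = agg$n, timepoint = timepoint)
  })
  res <- bind_rows(out) |> arrange(.data$chromosome, .data$bin_start)
  class(res) <- c("ratio_profile", class(res))
  res
}

# ratio of control-region means between a sample and the T0 reference
control_ratio <- function(track_tx, track_t0, control_region) {
  cr <- control_region
  idx <- (cr$start + 1L):cr$end
  t0 <- mean(track_t0$data[[cr$chromosome]][idx])
  if (t0 == 0) abort("control region has zero T0 coverage")
  tx <- mean(track_tx$data[[cr$chromosome]][idx])
  if (tx == 0) abort("control region has zero coverage at this timepoint")
  tx / t0
}

#' Control-region-corrected 2-kb section profile
#'
#' Implements the double normalization
#' `C_N = (C_sec_Tx / C_sec_T0) / (C_ctrl_Tx / C_ctrl_T0)`: the average
#' coverage of each section is first normalized to the undamaged sample,
#' then to the same ratio over a large control region on an uninvolved
#' part of the donor chromosome, which makes profiles comparable between
#' experiments. The control region's own value is 1 by construction.
#'
#' @param track_tx,track_t0 scaled `coverage_track`s.
#' @param control_region list (chromosome, start, end), default the
#'   genome's annotated 120-kb region.
#' @param section section width in nt (default 2000).
#' @param chromosome optional chromosome subset.
#' @param timepoint hours, recorded in the output.
#' @return a tibble of class `section_profile` with attribute
#'   `control_factor`.
#' @export
section_normalize <- function(track_tx, track_t0, control_region,
                              section = 2000L, chromosome = NULL,
                              timepoint = NA_real_) {
  assert_that(track_tx$scaled && track_t0$scaled,
              "both tracks must be RPGC-scaled")
  cr <- control_region
  factor <- control_ratio(track_tx, track_t0, cr)
  chroms <- chromosome %||% names(track_tx$data)
  out <- lapply(chroms, function(nm) {
    tx <- track_tx$data[[nm]]; t0 <- track_t0$data[[nm]]
    pos <- seq_along(tx) - 1L
    sec <- (pos %/% section) * section
    dt <- data.table::data.table(sec = sec, tx = tx, t0 = t0)
    agg <- dt[, list(mtx = mean(tx), mt0 = mean(t0)), by = "sec"]
    tibble(chromosome = nm, section_start = agg$sec,
           section_end = pmin(agg$sec + section, length(tx)),
           value = ifelse(agg$mt0 > 0, (agg$mtx / agg$mt0) / factor, NA_real_),
           timepoint = timepoint)
  })
  res <- bind_rows(out) |> arrange(.data$chromosome, .data$section_start)
  class(res) <- c("section_profile", class(res))
  attr(res, "control_factor") <- factor
  attr(res, "control_region") <- cr
  res
}

#' Time-by-section matrix of normalized coverage
#'
#' Stacks section profiles over the time course into the numeric matrix
#' behind a colormap chart (rows = timepoints, columns = sections).
#'
#' @param profiles list of `section_profile`s (one per timepoint).
#' @param chromosome chromosome to extract.
#' @return numeric matrix with timepoints as rownames and section start
#'   coordinates as colnames.
#' @export
colormap_matrix <- function(profiles, chromosome) {
  rows <- lapply(profiles, function(p) {
    p <- p[p$chromosome == chromosome, , drop = FALSE]
    setNames(p$value, p$section_start)
  })
  secs <- names(rows[[1]])
  for (r in rows) assert_that(identical(names(r), secs),
                              "section profiles do not share sections")
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(profiles, function(p)
    as.character(p$timepoint[1]), character(1))
  m
}
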