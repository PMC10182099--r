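#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_tile
#'   geom_vline labs autoplot scale_fill_gradientn facet_wrap theme_minimal
NULL

#' Plot a binned coverage-ratio profile
#'
#' @param object a `ratio_profile`.
#' @param ho_site optional cut coordinate, drawn as a dashed line.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ratio_profile <- function(object, ho_site = NULL, ...) {
  p <- ggplot(object, aes(x = (.data$bin_start + .data$bin_end) / 2,
                          y = .data$value)) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~chromosome, scales = "free_x") +
    labs(x = "position (nt)", y = "coverage ratio vs T0") +
    theme_minimal()
  if (!is.null(ho_site))
    p <- p + geom_vline(xintercept = ho_site, linetype = "dashed")
  p
}

#' Plot a time-by-section coverage matrix (colormap chart)
#'
#' @param m matrix from [colormap_matrix()].
#' @param ho_site optional cut coordinate.
#' @return a ggplot.
#' @export
plot_colormap <- function(m, ho_site = NULL) {
  df <- tibble(
    timepoint = rep(as.numeric(rownames(m)), times = ncol(m)),
    section = rep(as.numeric(colnames(m)), each = nrow(m)),
    value = as.vector(m)
  )
  p <- ggplot(df, aes(x = .data$section, y = .data$timepoint,
                      fill = pmin(.data$value, 1.5))) +
    geom_tile() +
    scale_fill_gradientn(colours = c("purple", "blue", "green", "red"),
                         name = "normalized\ncoverage") +
    labs(x = "section start (nt)", y = "time (h)") +
    theme_minimal()
  if (!is.null(ho_site))
    p <- p + geom_vline(xintercept = ho_site, linetype = "dashed")
  p
}

#' Plot break-centered discordant-mate coverage
#'
#' Recipient-mate and donor-mate per-base coverage in the break-centered
#' frame; their intersections mark conversion-tract boundaries.
#'
#' @param object a `discordant_coverage`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.discordant_coverage <- function(object, ...) {
  df <- bind_rows(
    tibble(offset = object$offset, coverage = object$recipient,
           locus = "recipient"),
    tibble(offset = object$offset, coverage = object$donor, locus = "donor")
  )
  ggplot(df, aes(x = .data$offset, y = .data$coverage,
                 colour = .data$locus)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "offset from cut (nt)", y = "discordant-mate coverage") +
    theme_minimal()
}

#' Scatter plot of discordant pair coordinates
#'
#' Recipient coordinate against donor coordinate, the quadrant view of
#' gene-conversion boundaries.
#'
#' @param pairs a classified `discordant_pairs` tibble (see
#'   [classify_quadrant()]).
#' @param ho_site,ho_inc_site quadrant dividers.
#' @return a ggplot.
#' @export
plot_discordant_pairs <- function(pairs, ho_site, ho_inc_site) {
  ggplot(pairs, aes(x = .data$recipient_coord, y = .data$donor_coord,
                    colour = .data$quadrant)) +
    geom_point(alpha = 0.6) +
    geom_vline(xintercept = ho_site, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = ho_inc_site, linetype = "dashed") +
    labs(x = "recipient mate coordinate", y = "donor mate coordinate") +
    theme_minimal()
}

#' Bar plot of corrected per-site conversion fractions
#'
#' @param fractions tibble from [apply_gc_correction()].
#' @return a ggplot.
#' @export
plot_gc_profile <- function(fractions) {
  ggplot(fractions[fractions$usable, ],
         aes(x = .data$offset_from_ho, y = .data$corrected_fraction)) +
    geom_col(width = 30) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "offset from cut (nt)", y = "corrected conversion fraction") +
    theme_minimal()
}
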