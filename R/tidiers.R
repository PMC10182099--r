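#' @importFrom generics tidy glance
NULL

#' Tidy a long-range resection rate fit
#'
#' @param x a `resection_rate_fit`.
#' @param ... unused.
#' @return one row per side: slope (nt/h), intercept, r.squared, number
#'   of uncensored timepoints.
#' @export
tidy.resection_rate_fit <- function(x, ...) {
  bind_rows(lapply(names(x$fits), function(s) {
    f <- x$fits[[s]]
    tibble(side = s,
           rate_nt_per_h = coef(f)[["time"]],
           intercept = coef(f)[["(Intercept)"]],
           r.squared = summary(f)$r.squared,
           n_timepoints = length(f$residuals))
  }))
}

#' @rdname tidy.resection_rate_fit
#' @export
glance.resection_rate_fit <- function(x, ...) {
  tibble(level = x$level,
         interval_start = x$interval[1], interval_end = x$interval[2],
         rate_left = x$rates$rate_nt_per_h[x$rates$side == "left"],
         rate_right = x$rates$rate_nt_per_h[x$rates$side == "right"],
         n_censored = sum(x$distances$censored))
}

#' Tidy a re-synthesis trend line
#'
#' @param x a `synthesis_trend`.
#' @param ... unused.
#' @return one row: side, distance, slope m (S, coverage/h), intercept b.
#' @export
tidy.synthesis_trend <- function(x, ...) {
  tibble(side = x$side, distance = x$distance,
         m = x$m, b = x$b,
         r.squared = summary(x$fit)$r.squared)
}

#' @rdname tidy.synthesis_trend
#' @export
glance.synthesis_trend <- function(x, ...) {
  ir <- initiation_rate(x)
  tibble(side = x$side, distance = x$distance, synthesis_rate = x$m,
         initiation_rate_kb_per_h = ir$rate_kb_per_h,
         interval_start = x$interval[1], interval_end = x$interval[2])
}

#' @export
generics::tidy

#' @export
generics::glance
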