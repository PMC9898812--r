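#' Tidy a distance summary into one row per statistic
#'
#' @param x a `regbash_dist` from [distance_stats()].
#' @param ... ignored.
#' @return tibble with `statistic` and `value` columns.
#' @export
tidy.regbash_dist <- function(x, ...) {
  tibble(
    statistic = c("n", "min", "max", "median", "ci_low", "ci_high",
                  "percentile_95"),
    value = as.numeric(c(x$n, x$min, x$max, x$median, x$ci_low, x$ci_high,
                         x$percentile_95)))
}

#' One-row summary of a distance summary
#'
#' @param x a `regbash_dist` from [distance_stats()].
#' @param ... ignored.
#' @return one-row tibble with every reported statistic plus bootstrap
#'   settings.
#' @export
glance.regbash_dist <- function(x, ...) {
  tibble(n = x$n, min = x$min, max = x$max, median = x$median,
         ci_low = x$ci_low, ci_high = x$ci_high,
         percentile_95 = x$percentile_95, ci_reliable = x$ci_reliable,
         B = x$B, seed = x$seed)
}
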