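#' @importFrom ggplot2 ggplot aes geom_col geom_histogram geom_jitter
#'   geom_errorbar labs facet_wrap theme_minimal scale_y_log10 geom_vline
NULL

#' Plot a category breakdown as a bar chart
#'
#' @param object a `regbash_breakdown`.
#' @param level which breakdown level to show.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.regbash_breakdown <- function(object, level = "gene_category", ...) {
  d <- tibble::as_tibble(object) %>% filter(.data$level == !!level)
  ggplot(d, aes(x = stats::reorder(.data$category, -.data$n),
                y = .data$percent)) +
    geom_col(fill = "grey30") +
    labs(x = NULL, y = "% of alleles",
         title = "Alleles by impact on the host gene") +
    theme_minimal()
}

#' @rdname autoplot.regbash_breakdown
#' @param breakdown a `regbash_breakdown`.
#' @export
plot_category_breakdown <- function(breakdown, level = "gene_category") {
  autoplot(breakdown, level = level)
}

#' Plot a distance-to-TSS summary
#'
#' Histogram of element distances with the median, its bootstrap CI and the
#' 95th percentile marked.
#'
#' @param object a `regbash_dist`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.regbash_dist <- function(object, ...) {
  d <- tibble(distance = object$distances)
  ggplot(d, aes(x = .data$distance)) +
    geom_histogram(bins = 30, fill = "grey60") +
    geom_vline(xintercept = object$median, linetype = 1) +
    geom_vline(xintercept = c(object$ci_low, object$ci_high), linetype = 2) +
    geom_vline(xintercept = object$percentile_95, linetype = 3) +
    labs(x = "distance to TSS (bp)", y = "elements",
         title = "Element distance to the transcription start site",
         subtitle = "solid: median; dashed: bootstrap 95% CI; dotted: 95th percentile") +
    theme_minimal()
}

#' @rdname autoplot.regbash_dist
#' @param distances a `regbash_dist`.
#' @export
plot_distance_summary <- function(distances) autoplot(distances)

#' Plot per-region activity-conclusion percentages
#'
#' @param object a `regbash_activity`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.regbash_activity <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$region, y = .data$percent, fill = .data$conclusion)) +
    geom_col(position = "stack") +
    labs(x = NULL, y = "% of studies", fill = "inferred activity",
         title = "Inferred native activity by region") +
    theme_minimal()
}

#' @rdname autoplot.regbash_activity
#' @param activity a `regbash_activity`.
#' @export
plot_activity_breakdown <- function(activity) autoplot(activity)

#' Plot tested mutations per study by technique
#'
#' @param object a `regbash_throughput` or the raw studies tibble with
#'   `technique` and `n_mutations`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.regbash_throughput <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$technique, y = .data$total)) +
    geom_col(fill = "grey30") +
    labs(x = NULL, y = "tested mutations (total)",
         title = "Throughput by technique") +
    theme_minimal()
}

#' @rdname autoplot.regbash_throughput
#' @param studies raw studies tibble; when given, a per-study jitter on a
#'   log scale is drawn instead of technique totals.
#' @export
plot_throughput <- function(object, studies = NULL) {
  if (!is.null(studies)) {
    return(
      ggplot(studies, aes(x = .data$technique, y = .data$n_mutations)) +
        geom_jitter(width = 0.2, height = 0, alpha = 0.5) +
        scale_y_log10() +
        labs(x = NULL, y = "tested mutations per study",
             title = "Throughput by technique") +
        theme_minimal()
    )
  }
  autoplot(object)
}
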