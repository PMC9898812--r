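#' Category breakdown of consequence calls
#'
#' Counts and printed-style percentages (half-up, one decimal) of calls per
#' census group, gene category and fine category. Groups follow the census
#' convention that synonymous alleles are counted among the non-coding
#' candidates: `coding`, `splicing`, `non_coding` (regulatory +
#' synonymous), `unassigned`.
#'
#' @param calls tibble with `gene_category` and `fine_category` columns.
#' @return a `regbash_breakdown` tibble with `level` (`group` /
#'   `gene_category` / `fine_category`), `category`, `parent`, `n`,
#'   `percent` (of total). Empty input yields an empty breakdown.
#' @export
category_breakdown <- function(calls) {
  calls <- tibble::as_tibble(calls)
  empty <- tibble(level = character(0), category = character(0),
                  parent = character(0), n = integer(0), percent = numeric(0))
  if (!nrow(calls)) {
    return(structure(empty, class = c("regbash_breakdown", class(empty))))
  }
  total <- nrow(calls)
  grp_of <- c(coding = "coding", splicing = "splicing",
              synonymous = "non_coding", non_coding_regulatory = "non_coding",
              intergenic_unassigned = "unassigned")
  calls$group <- unname(grp_of[calls$gene_category])
  pct <- function(n) half_up(100 * n / total, 1)
  lvl <- function(d, level, col, parent) {
    d %>%
      group_by(category = .data[[col]], parent = {{ parent }}) %>%
      summarise(n = n(), .groups = "drop") %>%
      mutate(level = level, percent = pct(.data$n)) %>%
      select("level", "category", "parent", "n", "percent")
  }
  out <- dplyr::bind_rows(
    lvl(calls, "group", "group", NA_character_),
    lvl(calls, "gene_category", "gene_category", .data$group),
    lvl(calls, "fine_category", "fine_category", .data$gene_category)
  ) %>%
    mutate(total = total) %>%
    arrange(match(.data$level, c("group", "gene_category", "fine_category")),
            dplyr::desc(.data$n), .data$category)
  structure(out, class = c("regbash_breakdown", class(out)))
}

#' Distance-to-TSS summary with a bootstrap CI of the median
#'
#' Reports n, min, max, the 95th percentile by the nearest-rank method, the
#' sample median, and a percentile-bootstrap 95% confidence interval of the
#' median (`B` resamples, 2.5/97.5 percentiles), deterministic for a fixed
#' seed.
#'
#' @param distances non-negative distances in bp.
#' @param B bootstrap resamples (>= 1000 recommended for reported CIs).
#' @param seed integer seed for the bootstrap.
#' @return a `regbash_dist` object; see [glance.regbash_dist()].
#' @export
distance_stats <- function(distances, B = 1000L, seed = 1L) {
  if (length(distances) == 0L) {
    stop("distance_stats() needs at least one distance", call. = FALSE)
  }
  if (any(distances < 0)) stop("distances must be non-negative", call. = FALSE)
  n <- length(distances)
  sorted <- sort(distances)
  p95 <- sorted[ceiling(0.95 * n)]
  med <- stats::median(distances)
  boot_medians <- withr::with_seed(seed, {
    m <- matrix(sample(distances, n * B, replace = TRUE), nrow = B)
    apply(m, 1, stats::median)
  })
  ci <- unname(stats::quantile(boot_medians, c(0.025, 0.975)))
  out <- list(
    n = n, min = min(distances), max = max(distances),
    percentile_95 = p95, median = med,
    ci_low = ci[1], ci_high = ci[2],
    ci_reliable = n >= 5L,
    B = as.integer(B), seed = as.integer(seed),
    distances = distances, boot_medians = boot_medians)
  class(out) <- "regbash_dist"
  out
}

#' @export
print.regbash_dist <- function(x, ...) {
  cat("<distance summary> n = ", x$n, ", median = ", x$median,
      " bp (bootstrap 95% CI ", x$ci_low, "-", x$ci_high,
      if (!x$ci_reliable) ", unreliable: n < 5" else "",
      "), 95th percentile = ", x$percentile_95, " bp, range ",
      x$min, "-", x$max, " bp\n", sep = "")
  invisible(x)
}

#' Per-region activity-conclusion percentages
#'
#' For each region category, the percentage of studies concluding each
#' native activity (activating / repressive / both). A study spanning two
#' region categories contributes to both denominators; studies with
#' conclusion `none` are dropped from the denominators; regions with no
#' studies are omitted.
#'
#' @param studies tibble with `study_id`, `region` (or a `regions`
#'   list/comma-separated column) and `conclusion`.
#' @return a `regbash_activity` tibble: `region`, `conclusion`, `n`,
#'   `n_region`, `percent` (of studies covering that region).
#' @export
activity_breakdown <- function(studies) {
  st <- tibble::as_tibble(studies)
  if (!("region" %in% names(st)) && "regions" %in% names(st)) {
    st <- st %>%
      mutate(region = if (is.list(.data$regions)) .data$regions
             else strsplit(.data$regions, ",", fixed = TRUE)) %>%
      tidyr::unnest("region")
  }
  st <- st %>% filter(.data$conclusion != "none")
  out <- st %>%
    group_by(.data$region) %>%
    mutate(n_region = dplyr::n_distinct(.data$study_id)) %>%
    group_by(.data$region, .data$conclusion, .data$n_region) %>%
    summarise(n = dplyr::n_distinct(.data$study_id), .groups = "drop") %>%
    mutate(percent = half_up(100 * .data$n / .data$n_region, 1)) %>%
    select("region", "conclusion", "n", "n_region", "percent") %>%
    arrange(.data$region, dplyr::desc(.data$percent))
  structure(out, class = c("regbash_activity", class(out)))
}

#' Tested-mutations-per-study throughput by technique
#'
#' Totals, maxima and means (half-up, one decimal) of the number of tested
#' mutations per study, per technique.
#'
#' @param studies tibble with `technique` and `n_mutations`.
#' @return a `regbash_throughput` tibble: `technique`, `n_studies`, `total`,
#'   `max`, `mean`.
#' @export
study_throughput <- function(studies) {
  out <- tibble::as_tibble(studies) %>%
    group_by(.data$technique) %>%
    summarise(n_studies = n(),
              total = sum(.data$n_mutations),
              max = max(.data$n_mutations),
              mean = half_up(sum(.data$n_mutations) / n(), 1),
              .groups = "drop") %>%
    arrange(.data$technique)
  structure(out, class = c("regbash_throughput", class(out)))
}
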