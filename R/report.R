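#' Write the machine-readable census report
#'
#' Emits `report.json` (stable key order, every statistic with its input row
#' counts, seed and software version) plus one TSV per figure-style table:
#' category breakdown, distance summary, per-region activity percentages and
#' per-technique throughput. Region keys of the activity section are always
#' present (null when that region has no studies), as are the three
#' technique keys of the throughput section. Two runs with the same inputs
#' and seed produce byte-identical JSON.
#'
#' @param dir output directory (created if missing).
#' @param breakdown a `regbash_breakdown` (or `NULL`).
#' @param distances a `regbash_dist` (or `NULL`).
#' @param activity a `regbash_activity` (or `NULL`).
#' @param throughput a `regbash_throughput` (or `NULL`).
#' @param seed the pipeline seed to record.
#' @return path of the JSON report, invisibly.
#' @export
write_report <- function(dir, breakdown = NULL, distances = NULL,
                         activity = NULL, throughput = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  regions <- c("transcriptional_cis_regulatory", "five_prime_UTR",
               "three_prime_UTR", "intron", "downstream")
  conclusions <- c("activating", "repressive", "both")
  techniques <- c("forward_genetics", "crispr", "reporter")

  activity_obj <- setNames(lapply(regions, function(r) {
    if (is.null(activity)) return(NULL)
    d <- activity[activity$region == r, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    pct <- setNames(as.list(rep(0, length(conclusions))), conclusions)
    for (i in seq_len(nrow(d))) pct[[d$conclusion[i]]] <- d$percent[i]
    list(n_studies = d$n_region[1], percent = pct)
  }), regions)

  throughput_obj <- setNames(lapply(techniques, function(t) {
    if (is.null(throughput)) return(NULL)
    d <- throughput[throughput$technique == t, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    list(n_studies = d$n_studies, total = d$total, max = d$max, mean = d$mean)
  }), techniques)

  report <- list(
    software = list(package = "regbash",
                    version = as.character(utils::packageVersion("regbash"))),
    seed = seed,
    category_breakdown = if (is.null(breakdown)) NULL else list(
      n_input = if (nrow(breakdown)) breakdown$total[1] else 0L,
      rows = breakdown %>% select("level", "category", "parent", "n", "percent")
    ),
    distances = if (is.null(distances)) NULL else
      distances[c("n", "min", "max", "percentile_95", "median",
                  "ci_low", "ci_high", "ci_reliable", "B", "seed")],
    activity = activity_obj,
    throughput = throughput_obj
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")

  if (!is.null(breakdown)) {
    readr::write_tsv(tibble::as_tibble(breakdown),
                     file.path(dir, "category_breakdown.tsv"))
  }
  if (!is.null(distances)) {
    readr::write_tsv(glance(distances), file.path(dir, "distances.tsv"))
  }
  if (!is.null(activity)) {
    readr::write_tsv(tibble::as_tibble(activity),
                     file.path(dir, "activity.tsv"))
  }
  if (!is.null(throughput)) {
    readr::write_tsv(tibble::as_tibble(throughput),
                     file.path(dir, "throughput.tsv"))
  }
  invisible(json_path)
}

#' Validate a census report against the shipped schema
#'
#' Structural validation of `report.json`: required keys and value types,
#' checked recursively against the JSON schema shipped in
#' `inst/extdata/report-schema.json`.
#'
#' @param path path to a report JSON file.
#' @param schema_path schema to validate against.
#' @return `TRUE` invisibly if valid, otherwise stops listing the problems.
#' @export
validate_report <- function(path,
                            schema_path = system.file("extdata",
                                                      "report-schema.json",
                                                      package = "regbash")) {
  report <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(schema_path)
  problems <- check_schema(report, schema, "$")
  if (length(problems)) {
    stop("report does not match schema:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

check_schema <- function(x, schema, where) {
  problems <- character(0)
  types <- unlist(schema$type) %||% "any"
  type_of <- function(v) {
    if (is.null(v)) "null"
    else if (is.list(v) && (!is.null(names(v)) || !length(v))) "object"
    else if (is.list(v)) "array"
    else if (is.character(v)) "string"
    else if (is.logical(v)) "boolean"
    else "number"
  }
  tx <- type_of(x)
  if (!("any" %in% types) && !(tx %in% types)) {
    return(paste0(where, ": expected ", paste(types, collapse = "|"),
                  ", got ", tx))
  }
  if (tx == "object") {
    for (req in unlist(schema$required)) {
      if (!(req %in% names(x))) {
        problems <- c(problems, paste0(where, ": missing required key '",
                                       req, "'"))
      }
    }
    for (key in names(schema$properties)) {
      if (key %in% names(x)) {
        problems <- c(problems,
                      check_schema(x[[key]], schema$properties[[key]],
                                   paste0(where, ".", key)))
      }
    }
  }
  problems
}
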