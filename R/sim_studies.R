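#' Generate curated element and study tables with known ground truth
#'
#' Emulates a manually curated catalogue of regulatory elements and of the
#' publications that tested them. Element distances to the TSS are drawn
#' log-normal around a configured median (intronic elements sit at 0 bp);
#' per-study mutation counts are constructed so that the configured
#' per-technique totals, maximum and forward-screen mean are exact; activity
#' records are drawn per region with the configured "down" probabilities.
#' The generating parameters are returned as ground truth for
#' parameter-recovery tests. Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return list with tibbles `elements` (item_id, region, distance_raw,
#'   source_label, effect, severity, mechanism, curation flags), `studies`
#'   (study_id, technique, regions, n_mutations, closest_bp, furthest_bp),
#'   `study_records` (study_id, region, effect, severity, mechanism), and
#'   `truth` (generating parameters: distance median, per-technique
#'   throughput, per-study conclusions).
#' @export
sim_study_tables <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, build_study_tables(config))
}

build_study_tables <- function(cfg) {
  regions <- c("transcriptional_cis_regulatory", "five_prime_UTR",
               "three_prime_UTR", "intron")
  region_w <- c(0.75, 0.08, 0.12, 0.05)
  draw_dist <- function(n) {
    as.integer(round(rlnorm(n, meanlog = log(cfg$dist_median),
                            sdlog = cfg$dist_sdlog)))
  }
  p_down_of <- function(region) {
    p <- cfg$p_down[region]
    ifelse(is.na(p), cfg$p_down[["transcriptional_cis_regulatory"]], p)
  }

  # --- element table -------------------------------------------------------
  n_el <- cfg$n_elements
  el_region <- sample(regions, n_el, replace = TRUE, prob = region_w)
  el_dist <- ifelse(el_region == "transcriptional_cis_regulatory",
                    draw_dist(n_el),
                    ifelse(el_region == "intron", 0L, NA_integer_))
  el_down <- runif(n_el) < p_down_of(el_region)
  elements <- tibble(
    item_id = sprintf("e%04d", seq_len(n_el)),
    region = el_region,
    distance_raw = as.integer(el_dist),
    source_label = ifelse(
      el_region == "transcriptional_cis_regulatory" & runif(n_el) < 0.15,
      "enhancer", NA_character_),
    effect = ifelse(el_down, "down", "up"),
    severity = ifelse(el_down, sample(c("null", "reduced"), n_el,
                                      replace = TRUE), NA_character_),
    mechanism = ifelse(el_region == "three_prime_UTR" & el_down &
                         runif(n_el) < 0.3, "NMD", NA_character_),
    protein_change = FALSE, passenger = FALSE, insufficient_info = FALSE)

  # --- per-study mutation counts: exact configured marginals ---------------
  n_rep <- cfg$n_reporter
  rep_counts <- c(cfg$reporter_max, rep(1L, n_rep - 1L))
  extra <- cfg$reporter_total - sum(rep_counts)
  if (extra < 0) stop("reporter_total too small for n_reporter", call. = FALSE)
  add <- as.integer(rmultinom(1, extra, rep(1, n_rep - 1L)))
  rep_counts[-1] <- rep_counts[-1] + add
  while (any(rep_counts[-1] >= cfg$reporter_max)) {
    i <- which(rep_counts[-1] >= cfg$reporter_max)[1] + 1L
    j <- which.min(rep_counts[-1]) + 1L
    rep_counts[i] <- rep_counts[i] - 1L
    rep_counts[j] <- rep_counts[j] + 1L
  }
  rep_counts <- c(rep_counts[1], sample(rep_counts[-1]))

  n_fwd <- cfg$n_forward
  n_two <- as.integer(round(n_fwd * (cfg$forward_mean - 1)))
  fwd_counts <- sample(c(rep(2L, n_two), rep(1L, n_fwd - n_two)))

  n_cr <- cfg$n_crispr
  crispr_total <- cfg$endogenous_total - sum(fwd_counts)
  if (crispr_total < n_cr) {
    stop("endogenous_total too small for the forward-screen counts",
         call. = FALSE)
  }
  cr_counts <- 1L + as.integer(rmultinom(1, crispr_total - n_cr, rep(1, n_cr)))

  studies <- tibble(
    study_id = sprintf("s%03d", seq_len(n_rep + n_fwd + n_cr)),
    technique = c(rep("reporter", n_rep), rep("forward_genetics", n_fwd),
                  rep("crispr", n_cr)),
    n_mutations = c(rep_counts, fwd_counts, cr_counts))

  # regions covered and distance extremes per study
  studies$regions <- vapply(seq_len(nrow(studies)), function(i) {
    k <- sample(1:2, 1L, prob = c(0.9, 0.1))
    paste(sample(regions[1:3], k, prob = c(0.6, 0.15, 0.25)),
          collapse = ",")
  }, character(1))
  is_rep <- studies$technique == "reporter"
  ext <- t(vapply(seq_len(nrow(studies)), function(i) {
    if (!is_rep[i]) return(c(NA_integer_, NA_integer_))
    sort(draw_dist(2L))
  }, integer(2)))
  studies$closest_bp <- ext[, 1]
  studies$furthest_bp <- ext[, 2]

  # activity records per study
  recs <- purrr::map(seq_len(nrow(studies)), function(i) {
    k <- sample_range(cfg$records_per_study)
    reg <- sample(strsplit(studies$regions[i], ",")[[1]], k, replace = TRUE)
    down <- runif(k) < p_down_of(reg)
    tibble(study_id = studies$study_id[i], region = reg,
           effect = ifelse(down, "down", "up"),
           severity = ifelse(down, sample(c("null", "reduced"), k,
                                          replace = TRUE), NA_character_),
           mechanism = ifelse(reg == "three_prime_UTR" & down &
                                runif(k) < 0.3, "NMD", NA_character_))
  })
  study_records <- dplyr::bind_rows(recs)

  truth_conclusions <- study_records %>%
    group_by(.data$study_id) %>%
    summarise(conclusion = dplyr::case_when(
      all(.data$effect == "down") ~ "activating",
      all(.data$effect == "up") ~ "repressive",
      TRUE ~ "both"), .groups = "drop")

  truth <- list(
    dist_median = cfg$dist_median,
    throughput = tibble(
      technique = c("reporter", "forward_genetics", "crispr"),
      total = c(cfg$reporter_total, sum(fwd_counts), sum(cr_counts)),
      max = c(cfg$reporter_max, max(fwd_counts), max(cr_counts)),
      mean = c(half_up(cfg$reporter_total / n_rep, 1), cfg$forward_mean,
               half_up(sum(cr_counts) / n_cr, 1))),
    conclusions = truth_conclusions)

  list(elements = elements, studies = studies,
       study_records = study_records, truth = truth)
}

#' Write the synthetic study tables to versioned TSVs
#'
#' @param tables output of [sim_study_tables()].
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_study_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(elements = file.path(dir, "elements.tsv"),
             studies = file.path(dir, "studies.tsv"),
             study_records = file.path(dir, "study_records.tsv"))
  for (nm in names(paths)) {
    writeLines("# regbash_table v1", paths[[nm]])
    readr::write_tsv(tables[[nm]], paths[[nm]], na = "", append = TRUE,
                     col_names = TRUE)
  }
  invisible(paths)
}

#' Read a versioned regbash TSV table
#'
#' @param path TSV written by [write_study_tables()] or [write_alleles()].
#' @return tibble.
#' @export
read_regbash_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
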