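#' Apply the curation exclusion rules to consequence calls
#'
#' Encodes the conservative exclusion of candidates that are likely not
#' truly non-coding or not gene regulatory. An allele is excluded iff, in
#' this order:
#' \enumerate{
#'   \item it changes protein sequence in any isoform — its gene category is
#'     `coding`, it carries an ectopic-splice-donor flag, or the curation
#'     table marks a publication-reported protein change
#'     (`protein_changing_any_isoform`);
#'   \item it is marked as a passenger mutation (`passenger`);
#'   \item it is marked as having insufficient functional information
#'     (`insufficient_information`).
#' }
#' Each excluded record carries exactly the first matching reason, so
#' retained + excluded partition the input.
#'
#' @param calls tibble of consequence calls ([classify_alleles()] output, or
#'   any tibble with `allele_id`, `gene_category`, and optionally
#'   `ectopic_donor`).
#' @param curation_table optional tibble with `item_id` and logical flags
#'   `protein_change`, `passenger`, `insufficient_info` (missing flags are
#'   treated as `FALSE`). Ids in the table but absent from `calls` trigger a
#'   warning.
#' @return the calls tibble with `included` (logical) and `exclusion_reason`
#'   columns added.
#' @export
apply_exclusion_rules <- function(calls, curation_table = NULL) {
  out <- tibble::as_tibble(calls)
  if (!("ectopic_donor" %in% names(out))) out$ectopic_donor <- FALSE
  flags <- tibble(item_id = out$allele_id,
                  protein_change = FALSE, passenger = FALSE,
                  insufficient_info = FALSE)
  if (!is.null(curation_table) && nrow(curation_table)) {
    ct <- tibble::as_tibble(curation_table)
    for (col in c("protein_change", "passenger", "insufficient_info")) {
      if (!(col %in% names(ct))) ct[[col]] <- FALSE
      ct[[col]][is.na(ct[[col]])] <- FALSE
    }
    orphans <- setdiff(ct$item_id, out$allele_id)
    if (length(orphans)) {
      warning(length(orphans), " curation-table id(s) absent from calls: ",
              paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
    }
    ct <- ct[, c("item_id", "protein_change", "passenger", "insufficient_info")]
    flags <- flags %>%
      select("item_id") %>%
      left_join(ct, by = "item_id") %>%
      mutate(across(c("protein_change", "passenger", "insufficient_info"),
                    ~ dplyr::coalesce(.x, FALSE)))
  }
  out$exclusion_reason <- dplyr::case_when(
    out$gene_category == "coding" | out$ectopic_donor |
      flags$protein_change ~ "protein_changing_any_isoform",
    flags$passenger ~ "passenger",
    flags$insufficient_info ~ "insufficient_information",
    TRUE ~ NA_character_)
  out$included <- is.na(out$exclusion_reason)
  out
}

#' Strand-aware distance from an element to the transcription start site
#'
#' The distance is the gap, measured upstream, from the element boundary
#' nearest the TSS to the TSS. Elements overlapping the TSS or lying at or
#' downstream of it (e.g. intronic elements) get 0 — the convention that
#' puts the closest regulatory elements "within introns at 0 bp".
#' Vectorized.
#'
#' @param start,end element interval, 0-based half-open.
#' @param tss 0-based position of the first transcribed base.
#' @param strand `"+"` or `"-"`.
#' @return integer distances in bp (>= 0).
#' @export
tss_distance <- function(start, end, tss, strand) {
  d_plus <- tss - end
  d_minus <- start - tss - 1L
  as.integer(pmax(0L, ifelse(strand == "+", d_plus, d_minus)))
}

#' Round a distance for display the way the census tables do
#'
#' Distances under 1,000 bp round to the nearest 50, between 1,000 and
#' 5,000 bp to the nearest 100, and above 5,000 bp to the nearest 500
#' ("several 100s for the very distant elements"). Raw distances should
#' always be retained alongside. Vectorized.
#'
#' @param x raw distances in bp.
#' @return rounded distances.
#' @export
round_distance <- function(x) {
  out <- ifelse(x < 1000, round_to_unit(x, 50),
                ifelse(x <= 5000, round_to_unit(x, 100),
                       round_to_unit(x, 500)))
  as.integer(out)
}

#' Assign regulatory region classes to curated records
#'
#' Transcriptional-context records (upstream/promoter-region elements)
#' become `core_promoter` when their distance to the TSS is within
#' `core_promoter_bp` (default 100 bp, symmetric window), `enhancer` when
#' the original publication called them an enhancer (`source_label`), and
#' `promoter` otherwise. UTR, intron and downstream classes pass through
#' from the consequence context. The three transcriptional classes also
#' carry the umbrella flag `transcriptional_cis_regulatory`.
#'
#' @param records tibble with `context` (a fine category or `"promoter"`/
#'   `"transcriptional"`), `distance_raw`, and optionally `source_label`.
#' @param core_promoter_bp core-promoter window around the TSS, bp.
#' @return `records` with `region_class` and `transcriptional_cis_regulatory`
#'   columns added; records with no assignable context get `NA` and a
#'   warning.
#' @export
assign_regulatory_class <- function(records, core_promoter_bp = 100) {
  out <- tibble::as_tibble(records)
  if (!("source_label" %in% names(out))) out$source_label <- NA_character_
  transcriptional <- c("upstream", "promoter", "transcriptional",
                       "transcriptional_cis_regulatory", "intergenic")
  out$region_class <- dplyr::case_when(
    out$context == "five_prime_UTR" ~ "five_prime_UTR",
    out$context == "three_prime_UTR" ~ "three_prime_UTR",
    out$context == "intronic" ~ "intron",
    out$context == "intron" ~ "intron",
    out$context == "downstream" ~ "downstream",
    out$context %in% transcriptional & !is.na(out$distance_raw) &
      abs(out$distance_raw) <= core_promoter_bp ~ "core_promoter",
    out$context %in% transcriptional &
      dplyr::coalesce(out$source_label == "enhancer", FALSE) ~ "enhancer",
    out$context %in% transcriptional ~ "promoter",
    TRUE ~ NA_character_)
  if (anyNA(out$region_class)) {
    warning(sum(is.na(out$region_class)),
            " record(s) without an assignable region class", call. = FALSE)
  }
  out$transcriptional_cis_regulatory <-
    out$region_class %in% c("core_promoter", "promoter", "enhancer")
  out
}

#' Infer native sequence activity from a mutation's effect
#'
#' A mutation that reduces or abolishes expression ("down" — null and
#' reduced severities alike) implies the native sequence activates; a gain
#' of expression in extra cells, tissues or stages ("up") implies it
#' represses. Vectorized; unknown effects give `NA` with a warning.
#'
#' @param effect character vector of `"down"` / `"up"`.
#' @return character vector of `"activating"` / `"repressive"`.
#' @export
infer_activity <- function(effect) {
  out <- dplyr::case_when(effect == "down" ~ "activating",
                          effect == "up" ~ "repressive",
                          TRUE ~ NA_character_)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " record(s) with unknown effect skipped",
            call. = FALSE)
  }
  out
}

#' Aggregate per-record activities to one conclusion per study
#'
#' A study concludes `activating` if every record is activating,
#' `repressive` if every record is repressive, and `both` otherwise. With
#' `nmd_filter = TRUE`, records whose mechanism is nonsense-mediated decay
#' ("NMD") are removed before aggregating — such 3'UTR mutations cause
#' downregulation without pointing to a native activating element. Studies
#' with no records left get conclusion `none` (and should be dropped from
#' percentage denominators).
#'
#' @param records tibble with `study_id`, `effect`, and optionally
#'   `mechanism`.
#' @param nmd_filter drop `mechanism == "NMD"` records first?
#' @return tibble with `study_id`, `conclusion`, `n_records`.
#' @export
aggregate_study_activity <- function(records, nmd_filter = FALSE) {
  rec <- tibble::as_tibble(records)
  if (!("mechanism" %in% names(rec))) rec$mechanism <- NA_character_
  all_ids <- unique(rec$study_id)
  if (nmd_filter) {
    rec <- rec %>% filter(!dplyr::coalesce(.data$mechanism == "NMD", FALSE))
  }
  rec$activity <- infer_activity(rec$effect)
  rec <- rec %>% filter(!is.na(.data$activity))
  agg <- rec %>%
    group_by(.data$study_id) %>%
    summarise(conclusion = dplyr::case_when(
      all(.data$activity == "activating") ~ "activating",
      all(.data$activity == "repressive") ~ "repressive",
      TRUE ~ "both"), n_records = n(), .groups = "drop")
  dropped <- setdiff(all_ids, agg$study_id)
  if (length(dropped)) {
    agg <- dplyr::bind_rows(agg, tibble(study_id = dropped,
                                        conclusion = "none", n_records = 0L))
  }
  agg %>% arrange(.data$study_id)
}
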