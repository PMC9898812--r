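#' Default feature precedence for conservative overlap resolution
#'
#' When two feature kinds claim the same base, the kind kept is the one that
#' would make an allele there *not* count as non-coding/regulatory: coding
#' sequence and splice sites outrank UTRs, which outrank introns and flanks.
#' This mirrors the curation direction of excluding alleles that change
#' protein sequence in any isoform. Kinds grouped in the same list element
#' share a rank and never truncate each other.
#'
#' @return a list of character vectors, highest precedence first.
#' @export
default_precedence <- function() {
  list(
    "CDS",
    c("splice_donor", "splice_acceptor"),
    "five_prime_UTR",
    "three_prime_UTR",
    "intron",
    c("upstream_flank", "downstream_flank")
  )
}

#' Resolve overlapping features conservatively
#'
#' Given feature intervals from (possibly many) transcripts, removes overlaps
#' so that every base is labelled only by the highest-precedence kind that
#' covered it in the input. Lower-precedence intervals are truncated or split
#' (never expanded); intervals of the same rank do not cut each other.
#' The classic case is 3'UTR sequence of one gene overlapping coding sequence
#' of another: the UTR is truncated, the CDS kept intact.
#'
#' @param features tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `kind`, and any id columns to carry through.
#' @param precedence list of character vectors, highest rank first; must
#'   cover every kind present in `features`.
#' @return tibble in the same format, disjoint across kinds per chromosome,
#'   sorted by (chrom, start, end).
#' @export
resolve_overlaps <- function(features, precedence = default_precedence()) {
  features <- tibble::as_tibble(features)
  if (!nrow(features)) return(features)
  known <- unlist(precedence)
  unknown <- setdiff(unique(features$kind), known)
  if (length(unknown)) {
    stop("unknown feature kind(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rank <- setNames(rep(seq_along(precedence), lengths(precedence)), known)

  out <- list()
  for (chr in unique(features$chrom)) {
    fc <- features[features$chrom == chr, , drop = FALSE]
    blocked <- IRanges::IRanges()
    for (r in seq_along(precedence)) {
      rows <- fc[rank[fc$kind] == r, , drop = FALSE]
      if (!nrow(rows)) next
      ir <- IRanges::IRanges(rows$start + 1L, rows$end)
      if (length(blocked)) {
        pieces <- purrr::map(seq_len(nrow(rows)), function(i) {
          kept <- IRanges::setdiff(ir[i], blocked)
          if (!length(kept)) return(NULL)
          res <- rows[rep(i, length(kept)), , drop = FALSE]
          res$start <- IRanges::start(kept) - 1L
          res$end <- IRanges::end(kept)
          res
        })
        out[[length(out) + 1L]] <- dplyr::bind_rows(pieces)
      } else {
        out[[length(out) + 1L]] <- rows
      }
      blocked <- IRanges::reduce(c(blocked, ir))
    }
  }
  dplyr::bind_rows(out) %>%
    arrange(.data$chrom, .data$start, .data$end, .data$kind)
}
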