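#' Write an allele table to TSV
#'
#' Columns `chrom`, `pos` (converted to 1-based in the file), `id`, `ref`,
#' `alt`, `source`, preceded by a versioned comment line. Empty `ref`/`alt`
#' (insertions/deletions) are written as empty fields.
#'
#' @param alleles tibble as produced by [sim_alleles()] (0-based `pos`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alleles <- function(alleles, path) {
  out <- alleles %>% mutate(pos = .data$pos + 1L)
  writeLines("# regbash_allele_table v1", path)
  readr::write_tsv(out, path, na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and validate an allele table against the genome
#'
#' Reads a TSV with header `chrom`, `pos` (1-based in the file), `id`,
#' `ref`, `alt`, `source`. Positions are converted to the internal 0-based
#' convention, `ref` is checked against the genome (mismatching rows are
#' rejected and reported, loading continues), exact duplicates (same chrom,
#' pos, ref, alt, id) are collapsed with a warning, and indels are
#' left-aligned against the genome.
#'
#' @param path TSV path.
#' @param annotation a `genome_annotation` providing the genome.
#' @return tibble of validated alleles; rejected rows (with their file line
#'   numbers and reason) are attached as `attr(, "rejected")`.
#' @export
read_alleles <- function(path, annotation) {
  raw <- readr::read_tsv(path, comment = "#", na = character(0),
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           pos = readr::col_integer(),
                           id = readr::col_character(),
                           ref = readr::col_character(),
                           alt = readr::col_character(),
                           source = readr::col_character()
                         ), progress = FALSE)
  raw$ref[is.na(raw$ref)] <- ""
  raw$alt[is.na(raw$alt)] <- ""
  raw$line <- seq_len(nrow(raw)) + 2L  # header + version line
  raw$pos <- raw$pos - 1L

  if (!nrow(raw)) {
    out <- raw %>% select(-"line")
    attr(out, "rejected") <- raw[0, ]
    return(out)
  }

  chrom_seq <- setNames(as.character(annotation$genome),
                        names(annotation$genome))
  reason <- rep(NA_character_, nrow(raw))
  reason[raw$ref == "" & raw$alt == ""] <- "ref and alt both empty"
  known <- raw$chrom %in% names(chrom_seq)
  reason[!known & is.na(reason)] <- "chromosome not in genome"
  check <- which(is.na(reason) & raw$ref != "" & known)
  if (length(check)) {
    obs <- vapply(check, function(i) {
      seq_at(chrom_seq[[raw$chrom[i]]], raw$pos[i], raw$pos[i] + nchar(raw$ref[i]))
    }, character(1))
    bad <- obs != raw$ref[check]
    reason[check[bad]] <- paste0("ref mismatch (genome has '",
                                 substr(obs[bad], 1, 20), "')")
  }

  rejected <- raw[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  if (nrow(rejected)) {
    warning(nrow(rejected), " allele row(s) rejected (lines ",
            paste(utils::head(rejected$line, 10), collapse = ", "), ")",
            call. = FALSE)
  }
  ok <- raw[is.na(reason), , drop = FALSE] %>% select(-"line")

  ndup <- nrow(ok) - nrow(dplyr::distinct(
    ok, .data$chrom, .data$pos, .data$ref, .data$alt, .data$id))
  if (ndup > 0) {
    warning(ndup, " duplicate allele row(s) collapsed", call. = FALSE)
    ok <- dplyr::distinct(ok, .data$chrom, .data$pos, .data$ref, .data$alt,
                          .data$id, .keep_all = TRUE)
  }

  ok <- normalize_alleles(ok, annotation)
  attr(ok, "rejected") <- rejected
  ok
}

#' Left-align insertions and deletions against the genome
#'
#' Pure insertions (`ref == ""`) and deletions (`alt == ""`) are shifted to
#' their leftmost equivalent representation, the conventional normalization
#' for indel coordinates. Substitutions are returned unchanged.
#'
#' @param alleles allele tibble (0-based `pos`).
#' @param annotation a `genome_annotation`.
#' @return the tibble with normalized `pos`/`ref`/`alt`.
#' @export
normalize_alleles <- function(alleles, annotation) {
  if (!nrow(alleles)) return(alleles)
  chrom_seq <- setNames(as.character(annotation$genome),
                        names(annotation$genome))
  is_del <- alleles$alt == "" & alleles$ref != ""
  is_ins <- alleles$ref == "" & alleles$alt != ""
  for (i in which(is_del | is_ins)) {
    cs <- chrom_seq[[alleles$chrom[i]]]
    if (is.null(cs)) next
    pos <- alleles$pos[i]
    seqv <- if (is_del[i]) alleles$ref[i] else alleles$alt[i]
    k <- nchar(seqv)
    while (pos > 0L && base_at(cs, pos - 1L) == substr(seqv, k, k)) {
      pos <- pos - 1L
      seqv <- paste0(base_at(cs, pos), substr(seqv, 1L, k - 1L))
    }
    alleles$pos[i] <- pos
    if (is_del[i]) alleles$ref[i] <- seqv else alleles$alt[i] <- seqv
  }
  alleles
}

#' Export consequence calls as one BED file per category
#'
#' Each non-empty fine category yields `<category>.bed` with 0-based
#' half-open records, the allele id in the name column, sorted by
#' (chrom, start, id). The number of records across files equals the number
#' of input calls.
#'
#' @param calls tibble of consequence calls (see [classify_alleles()]) with
#'   columns `chrom`, `pos`, `ref`, `fine_category`, `allele_id`.
#' @param out_dir output directory (created if missing).
#' @return tibble of written files and record counts, invisibly.
#' @export
write_bed <- function(calls, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!nrow(calls)) {
    return(invisible(tibble(category = character(0), path = character(0),
                            n = integer(0))))
  }
  bed <- calls %>%
    mutate(start = .data$pos,
           end = .data$pos + pmax(nchar(.data$ref), 1L)) %>%
    select("chrom", "start", "end", name = "allele_id",
           category = "fine_category") %>%
    arrange(.data$chrom, .data$start, .data$name)
  res <- bed %>%
    group_by(.data$category) %>%
    dplyr::group_map(function(d, key) {
      path <- file.path(out_dir, paste0(key$category, ".bed"))
      readr::write_tsv(d, path, col_names = FALSE)
      tibble(category = key$category, path = path, n = nrow(d))
    }) %>%
    dplyr::bind_rows()
  invisible(res)
}
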