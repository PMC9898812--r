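# fine categories ordered from most to least severe; drives isoform
# aggregation and tie-breaking
SEVERITY_ORDER <- c(
  "transcript_ablation", "frameshift", "stop_gained", "stop_lost",
  "start_lost", "inframe_deletion", "inframe_insertion", "missense",
  "splice_donor", "splice_acceptor", "splice_unclear", "synonymous",
  "five_prime_UTR", "three_prime_UTR", "intronic", "upstream",
  "downstream", "intergenic")

PROTEIN_CHANGING <- c(
  "transcript_ablation", "frameshift", "stop_gained", "stop_lost",
  "start_lost", "inframe_deletion", "inframe_insertion", "missense")

# within-transcript lookup precedence (coding beats splice beats UTRs ...)
KIND_RANK <- c(CDS = 1, splice_donor = 2, splice_acceptor = 3,
               five_prime_UTR = 4, three_prime_UTR = 5, intron = 6,
               upstream_flank = 7, downstream_flank = 8)

KIND_TO_CATEGORY <- c(
  five_prime_UTR = "five_prime_UTR", three_prime_UTR = "three_prime_UTR",
  intron = "intronic", upstream_flank = "upstream",
  downstream_flank = "downstream",
  splice_donor = "splice_donor", splice_acceptor = "splice_acceptor")

#' Map fine consequence categories to gene-level categories
#'
#' Protein-changing categories map to `coding`, splice-site categories to
#' `splicing`, `synonymous` stays its own class, UTR/intron/flank categories
#' map to `non_coding_regulatory`, and everything else to
#' `intergenic_unassigned`.
#'
#' @param fine character vector of fine categories.
#' @return character vector of gene categories.
#' @export
gene_category_of <- function(fine) {
  dplyr::case_when(
    fine %in% PROTEIN_CHANGING ~ "coding",
    fine %in% c("splice_donor", "splice_acceptor", "splice_unclear") ~ "splicing",
    fine == "synonymous" ~ "synonymous",
    fine %in% c("five_prime_UTR", "three_prime_UTR", "intronic",
                "upstream", "downstream") ~ "non_coding_regulatory",
    TRUE ~ "intergenic_unassigned")
}

#' Does a substitution create a new GT dinucleotide?
#'
#' The minimal motif test behind the ectopic-splice-donor flag: compare the
#' coding-strand sequence window around the edit before and after the
#' substitution and report whether a GT appears at an offset where the
#' reference had none. Vectorized over windows.
#'
#' @param ref_window,alt_window equal-length coding-strand windows (the
#'   edited base plus one base of context on each side).
#' @return logical vector.
#' @export
creates_gt <- function(ref_window, alt_window) {
  stopifnot(length(ref_window) == length(alt_window))
  gt_offsets <- function(w) {
    n <- nchar(w)
    if (n < 2) return(integer(0))
    which(vapply(seq_len(n - 1),
                 function(i) substr(w, i, i + 1) == "GT", logical(1)))
  }
  mapply(function(r, a) {
    length(setdiff(gt_offsets(a), gt_offsets(r))) > 0
  }, ref_window, alt_window, USE.NAMES = FALSE)
}

# coding-order genomic positions of a transcript's CDS bases
codon_positions <- function(ann, tid) {
  segs <- ann$cds[ann$cds$transcript_id == tid, , drop = FALSE]
  if (!nrow(segs)) return(integer(0))
  segs <- segs[order(segs$start), , drop = FALSE]
  if (segs$strand[1] == "+") {
    unlist(purrr::map2(segs$start, segs$end - 1L, seq.int))
  } else {
    segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
    unlist(purrr::map2(segs$end - 1L, segs$start, seq.int))
  }
}

#' Classify one allele against one transcript
#'
#' Substitutions in coding sequence are translated through the standard
#' codon table (missense / synonymous / stop gained / stop lost / start
#' lost); CDS indels are frameshift when the length change is not a multiple
#' of 3, otherwise in-frame; deletions spanning the whole transcript are
#' transcript ablations; splice-site, UTR, intron and flank positions take
#' their category from the overlap-resolved feature at the position; alleles
#' outside all features are intergenic. Synonymous substitutions that create
#' a GT dinucleotide are flagged as candidate ectopic splice donors.
#'
#' @param allele one-row allele tibble (`chrom`, `pos`, `ref`, `alt`, `id`).
#' @param transcript_id transcript to classify against.
#' @param annotation a `genome_annotation`.
#' @return one-row tibble: `allele_id`, `transcript_id`, `category`,
#'   `detail`, `ectopic_donor`.
#' @export
classify_against_transcript <- function(allele, transcript_id, annotation) {
  ann <- annotation
  tx <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, ]
  stopifnot(nrow(tx) == 1)
  a_start <- allele$pos
  a_end <- allele$pos + max(nchar(allele$ref), 1L)
  is_del <- allele$alt == "" & allele$ref != ""
  is_ins <- allele$ref == "" & allele$alt != ""
  is_sub <- nchar(allele$ref) == 1L & nchar(allele$alt) == 1L

  res <- function(category, detail = NA_character_, ectopic = FALSE) {
    tibble(allele_id = allele$id, transcript_id = transcript_id,
           category = category, detail = detail, ectopic_donor = ectopic)
  }

  if (is_del && a_start <= tx$start && a_end >= tx$end) {
    return(res("transcript_ablation"))
  }

  feats <- ann$resolved[ann$resolved$transcript_id == transcript_id &
                          ann$resolved$chrom == allele$chrom, , drop = FALSE]
  hit <- feats[feats$start < a_end & feats$end > a_start, , drop = FALSE]
  if (!nrow(hit)) return(res("intergenic"))
  top <- hit$kind[which.min(KIND_RANK[hit$kind])]

  if (top != "CDS") {
    return(res(unname(KIND_TO_CATEGORY[top])))
  }

  if (!is_sub) {
    shift <- abs(nchar(allele$ref) - nchar(allele$alt))
    if (shift == 0L) return(res("missense"))  # length-preserving MNV
    if (shift %% 3L != 0L) return(res("frameshift"))
    return(res(if (is_del) "inframe_deletion" else "inframe_insertion"))
  }

  # coding substitution: locate the codon and translate
  cpos <- codon_positions(ann, transcript_id)
  i <- match(allele$pos, cpos) - 1L
  if (is.na(i)) return(res("intergenic"))  # defensive; resolved CDS should match
  codon_i <- i %/% 3L
  off <- i %% 3L
  p3 <- cpos[(3L * codon_i + 1L):(3L * codon_i + 3L)]
  strand <- tx$strand
  cs <- ann$chrom_seq[[allele$chrom]]
  gb <- vapply(p3, function(p) base_at(cs, p), character(1))
  ref_codon <- paste(if (strand == "+") gb else comp_chr(gb), collapse = "")
  alt_coding <- if (strand == "+") allele$alt else comp_chr(allele$alt)
  alt_codon <- ref_codon
  substr(alt_codon, off + 1L, off + 1L) <- alt_coding
  ref_aa <- translate_codons(ref_codon)
  alt_aa <- translate_codons(alt_codon)
  detail <- sprintf("c.%d%s>%s(p.%d%s>%s)", i + 1L,
                    substr(ref_codon, off + 1L, off + 1L), alt_coding,
                    codon_i + 1L, ref_aa, alt_aa)

  category <- if (codon_i == 0L && alt_codon != "ATG") {
    "start_lost"
  } else if (ref_aa == "*" && alt_aa != "*") {
    "stop_lost"
  } else if (ref_aa != "*" && alt_aa == "*") {
    "stop_gained"
  } else if (ref_aa == alt_aa) {
    "synonymous"
  } else {
    "missense"
  }

  ectopic <- FALSE
  if (category == "synonymous") {
    w_ref <- seq_at(cs, allele$pos - 1L, allele$pos + 2L)
    w_alt <- w_ref
    substr(w_alt, 2L, 2L) <- allele$alt
    if (strand == "-") {
      w_ref <- revcomp_chr(w_ref)
      w_alt <- revcomp_chr(w_alt)
    }
    ectopic <- creates_gt(w_ref, w_alt)
  }
  res(category, detail, ectopic)
}

#' Aggregate per-transcript consequences to a gene-level call
#'
#' The most severe per-transcript category wins (ablation > frameshift >
#' stop gained > stop lost > start lost > in-frame indels > missense >
#' splice > synonymous > UTR > intron > flanks > intergenic); ties are
#' broken by lexicographic transcript id. The gene category is `coding` as
#' soon as *any* isoform yields a protein-changing category — the exclusion
#' direction used when curating non-coding alleles — and a synonymous winner
#' carrying an ectopic-splice-donor flag on any isoform is likewise
#' reclassified as `coding`.
#'
#' @param per_transcript tibble of per-transcript records
#'   (`allele_id`, `transcript_id`, `category`, `detail`, `ectopic_donor`).
#' @return one-row tibble: `allele_id`, `fine_category`, `gene_category`,
#'   `ectopic_donor`, `detail`, `n_transcripts`.
#' @export
aggregate_consequences <- function(per_transcript) {
  if (!nrow(per_transcript)) {
    stop("aggregate_consequences() needs at least one per-transcript record",
         call. = FALSE)
  }
  pt <- per_transcript %>%
    mutate(.sev = match(.data$category, SEVERITY_ORDER)) %>%
    arrange(.data$.sev, .data$transcript_id)
  win <- pt[1, ]
  any_protein <- any(pt$category %in% PROTEIN_CHANGING)
  any_ectopic <- any(pt$ectopic_donor)
  gene_cat <- gene_category_of(win$category)
  if (!any_protein && gene_cat == "synonymous" && any_ectopic) {
    gene_cat <- "coding"
  }
  if (any_protein) gene_cat <- "coding"
  tibble(allele_id = win$allele_id,
         fine_category = win$category,
         gene_category = gene_cat,
         ectopic_donor = any_ectopic,
         detail = win$detail,
         n_transcripts = nrow(per_transcript))
}

#' Classify alleles against a genome annotation
#'
#' For every allele, finds the genes whose transcript spans (plus flanks)
#' it touches, classifies it against each transcript of each such gene
#' using the overlap-resolved feature track, and aggregates across isoforms
#' to one call per (allele, gene). Alleles on chromosomes absent from the
#' annotation, or outside all features and flanks, are reported as
#' intergenic (with a warning for unknown chromosomes, not an error).
#'
#' @param alleles allele tibble (`chrom`, `pos` 0-based, `id`, `ref`, `alt`).
#' @param annotation a `genome_annotation`.
#' @return tibble with one row per (allele, gene): `allele_id`, `gene_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene_category`, `fine_category`,
#'   `ectopic_donor`, `detail`, `n_transcripts`, and a `per_transcript`
#'   list-column of the underlying records.
#' @export
classify_alleles <- function(alleles, annotation) {
  ann <- annotation
  if (!nrow(alleles)) {
    return(tibble(allele_id = character(0), gene_id = character(0),
                  gene_category = character(0), fine_category = character(0)))
  }
  unknown <- !(alleles$chrom %in% names(ann$genome))
  if (any(unknown)) {
    warning(sum(unknown), " allele(s) on chromosome(s) absent from the ",
            "annotation; classified as intergenic", call. = FALSE)
  }

  width <- pmax(nchar(alleles$ref), 1L)
  a_gr <- GenomicRanges::GRanges(
    seqnames = alleles$chrom,
    ranges = IRanges::IRanges(alleles$pos + 1L, alleles$pos + width))

  tx <- ann$transcripts
  tx_gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(pmax(tx$start - ann$flank_bp, 0L) + 1L,
                              tx$end + ann$flank_bp))
  suppressWarnings(
    ov <- GenomicRanges::findOverlaps(a_gr, tx_gr)
  )
  pairs <- tibble(a = S4Vectors::queryHits(ov), t = S4Vectors::subjectHits(ov))

  calls <- vector("list", nrow(alleles))
  for (ai in seq_len(nrow(alleles))) {
    allele <- alleles[ai, ]
    tids <- tx$transcript_id[pairs$t[pairs$a == ai]]
    if (!length(tids)) {
      calls[[ai]] <- tibble(
        allele_id = allele$id, gene_id = NA_character_,
        chrom = allele$chrom, pos = allele$pos, ref = allele$ref,
        alt = allele$alt, gene_category = "intergenic_unassigned",
        fine_category = "intergenic", ectopic_donor = FALSE,
        detail = NA_character_, n_transcripts = 0L,
        per_transcript = list(tibble()))
      next
    }
    per_tx <- dplyr::bind_rows(purrr::map(tids, function(tid) {
      classify_against_transcript(allele, tid, ann)
    }))
    per_tx$gene_id <- tx$gene_id[match(per_tx$transcript_id, tx$transcript_id)]
    calls[[ai]] <- per_tx %>%
      group_by(.data$gene_id) %>%
      dplyr::group_map(function(d, key) {
        agg <- aggregate_consequences(dplyr::bind_cols(
          d[, c("allele_id", "transcript_id", "category", "detail",
                "ectopic_donor")]))
        dplyr::bind_cols(
          agg[, "allele_id"],
          tibble(gene_id = key$gene_id, chrom = allele$chrom,
                 pos = allele$pos, ref = allele$ref, alt = allele$alt),
          agg[, c("gene_category", "fine_category", "ectopic_donor",
                  "detail", "n_transcripts")],
          tibble(per_transcript = list(d)))
      }) %>%
      dplyr::bind_rows()
  }
  dplyr::bind_rows(calls)
}
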