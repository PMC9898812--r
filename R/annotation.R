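#' Read a GFF3 annotation and genome FASTA into a transcript-centric model
#'
#' Parses gene/mRNA/exon/CDS records (linked by `Parent` attributes) into a
#' `genome_annotation` object. Coordinates are converted from GFF3 1-based
#' closed intervals to the internal 0-based half-open convention. UTRs,
#' introns, splice sites and upstream/downstream flanks are derived per
#' transcript, and overlapping features are resolved conservatively genome
#' wide (see [resolve_overlaps()]).
#'
#' @param gff3_path path to a GFF3 file with gene, mRNA (or transcript),
#'   exon and CDS records carrying `ID`/`Parent` attributes.
#' @param fasta_path path to a FASTA file containing every chromosome the
#'   annotation refers to.
#' @param flank_bp extent of the upstream/downstream flank features derived
#'   for each transcript, in bp. The default of 5000 bp covers the span in
#'   which the large majority of known transcriptional regulatory elements
#'   sit (the 95-percentile of element-to-TSS distances).
#' @param precedence feature precedence used for conservative overlap
#'   resolution; see [default_precedence()].
#' @return A `genome_annotation` object: a list with tibbles `genes`,
#'   `transcripts` (including the strand-aware `tss`), `exons`, `cds`,
#'   `features` (all derived intervals) and `resolved` (after precedence
#'   resolution), plus the genome as a [Biostrings::DNAStringSet].
#' @export
read_genome_annotation <- function(gff3_path, fasta_path, flank_bp = 5000,
                                   precedence = default_precedence()) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  gr <- rtracklayer::import(gff3_path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent_chr <- vapply(
    as.list(df$Parent),
    function(p) if (length(p)) paste(p, collapse = ",") else NA_character_,
    character(1)
  )
  df <- tibble::as_tibble(df[, c("seqnames", "start", "end", "strand", "type",
                                 "ID", "Parent_chr")])
  names(df) <- c("chrom", "start1", "end1", "strand", "type", "ID", "Parent")
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  # expand records with multiple parents (e.g. exons shared between isoforms)
  df <- tidyr::separate_rows(df, "Parent", sep = ",")

  problems <- character(0)
  genes_df <- dplyr::filter(df, .data$type == "gene")
  tx_df <- dplyr::filter(df, .data$type %in% c("mRNA", "transcript"))
  exon_df <- dplyr::filter(df, .data$type == "exon")
  cds_df <- dplyr::filter(df, .data$type == "CDS")

  bad_chrom <- setdiff(unique(df$chrom), names(genome))
  if (length(bad_chrom)) {
    problems <- c(problems, paste0("chromosome(s) absent from FASTA: ",
                                   paste(bad_chrom, collapse = ", ")))
  }
  if (any(is.na(tx_df$Parent)) || !all(tx_df$Parent %in% genes_df$ID)) {
    bad <- tx_df$ID[is.na(tx_df$Parent) | !(tx_df$Parent %in% genes_df$ID)]
    problems <- c(problems, paste0("mRNA record(s) without a valid gene Parent: ",
                                   paste(bad, collapse = ", ")))
  }
  for (nm in list(list(exon_df, "exon"), list(cds_df, "CDS"))) {
    sub <- nm[[1]]
    miss <- is.na(sub$Parent) | !(sub$Parent %in% tx_df$ID)
    if (any(miss)) {
      problems <- c(problems, paste0(
        nm[[2]], " record(s) without a valid mRNA Parent at ",
        paste(utils::head(paste0(sub$chrom[miss], ":", sub$start1[miss]), 5),
              collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("annotation validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  to0 <- function(d, id_col = FALSE) {
    tibble(chrom = d$chrom, start = as.integer(d$start1 - 1L),
           end = as.integer(d$end1), strand = d$strand)
  }
  genes <- dplyr::bind_cols(to0(genes_df), tibble(gene_id = genes_df$ID))
  tx_gene <- setNames(tx_df$Parent, tx_df$ID)
  transcripts <- dplyr::bind_cols(
    to0(tx_df),
    tibble(transcript_id = tx_df$ID, gene_id = unname(tx_gene[tx_df$ID]))
  )
  exons <- dplyr::bind_cols(
    to0(exon_df),
    tibble(transcript_id = exon_df$Parent,
           gene_id = unname(tx_gene[exon_df$Parent]))
  )
  cds <- dplyr::bind_cols(
    to0(cds_df),
    tibble(transcript_id = cds_df$Parent,
           gene_id = unname(tx_gene[cds_df$Parent]))
  )

  # CDS must sit inside an exon of its own transcript
  bad_cds <- purrr::pmap_lgl(cds, function(chrom, start, end, strand,
                                           transcript_id, gene_id) {
    ex <- exons[exons$transcript_id == transcript_id, ]
    !any(ex$start <= start & ex$end >= end)
  })
  if (any(bad_cds)) {
    stop("annotation validation failed:\n  - CDS outside exon for transcript(s): ",
         paste(unique(cds$transcript_id[bad_cds]), collapse = ", "),
         call. = FALSE)
  }

  build_annotation(genes, transcripts, exons, cds, genome,
                   flank_bp = flank_bp, precedence = precedence)
}

# assemble a genome_annotation from already-validated component tibbles;
# shared by the GFF3 reader and the synthetic-genome generator
build_annotation <- function(genes, transcripts, exons, cds, genome,
                             flank_bp = 5000, precedence = default_precedence()) {
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  transcripts <- transcripts %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L))

  feats <- purrr::map(transcripts$transcript_id, function(tid) {
    derive_transcript_features(
      exons[exons$transcript_id == tid, ],
      cds[cds$transcript_id == tid, ],
      flank_bp = flank_bp,
      chrom_length = chrom_len[[exons$chrom[exons$transcript_id == tid][1]]]
    )
  })
  features <- dplyr::bind_rows(feats)
  resolved <- resolve_overlaps(features, precedence = precedence)

  ann <- list(
    genes = tibble::as_tibble(genes),
    transcripts = tibble::as_tibble(transcripts),
    exons = tibble::as_tibble(exons),
    cds = tibble::as_tibble(cds) %>% arrange(.data$transcript_id, .data$start),
    features = features,
    resolved = resolved,
    genome = genome,
    chrom_seq = setNames(as.character(genome), names(genome)),
    flank_bp = flank_bp
  )
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", length(x$genome), " chromosome(s), ",
      nrow(x$genes), " gene(s), ", nrow(x$transcripts), " transcript(s); ",
      "flank_bp = ", x$flank_bp, "\n", sep = "")
  invisible(x)
}

#' Derive UTR, intron, splice-site and flank intervals for one transcript
#'
#' Introns are the gaps between consecutive exons. Splice donors are the
#' first two intronic bases at each intron's 5' end in transcript
#' orientation (the canonical GT), splice acceptors the last two at the 3'
#' end (AG). UTRs are the exonic bases outside the CDS, split by whether
#' they lie 5' or 3' of the CDS on the transcript's strand. Flank intervals
#' of `flank_bp` are emitted upstream and downstream of the transcript span,
#' clipped to the chromosome.
#'
#' @param exons tibble of one transcript's exons with columns `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `transcript_id`, `gene_id`.
#' @param cds the transcript's CDS intervals in the same format (may be
#'   empty for a non-coding transcript).
#' @param flank_bp flank extent in bp.
#' @param chrom_length chromosome length used to clip flanks.
#' @return tibble of feature intervals with a `kind` column (`CDS`,
#'   `five_prime_UTR`, `three_prime_UTR`, `intron`, `splice_donor`,
#'   `splice_acceptor`, `upstream_flank`, `downstream_flank`).
#' @export
derive_transcript_features <- function(exons, cds = NULL, flank_bp = 5000,
                                       chrom_length = Inf) {
  stopifnot(nrow(exons) >= 1)
  exons <- arrange(exons, .data$start)
  tid <- exons$transcript_id[1]
  if (nrow(exons) > 1 &&
      any(exons$end[-nrow(exons)] > exons$start[-1])) {
    stop("overlapping exons in transcript ", tid, call. = FALSE)
  }
  strand <- exons$strand[1]
  chrom <- exons$chrom[1]
  gid <- exons$gene_id[1]
  tx_start <- min(exons$start)
  tx_end <- max(exons$end)

  row <- function(start, end, kind) {
    tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
           strand = strand, kind = kind, transcript_id = tid, gene_id = gid)
  }
  out <- list()

  if (!is.null(cds) && nrow(cds)) {
    out$cds <- dplyr::bind_rows(purrr::pmap(
      cds[, c("start", "end")], function(start, end) row(start, end, "CDS")))
  }

  # introns and splice sites
  if (nrow(exons) > 1) {
    is_ <- exons$end[-nrow(exons)]
    ie_ <- exons$start[-1]
    for (i in seq_along(is_)) {
      out[[paste0("int", i)]] <- row(is_[i], ie_[i], "intron")
      if (strand == "+") {
        out[[paste0("don", i)]] <- row(is_[i], is_[i] + 2L, "splice_donor")
        out[[paste0("acc", i)]] <- row(ie_[i] - 2L, ie_[i], "splice_acceptor")
      } else {
        out[[paste0("don", i)]] <- row(ie_[i] - 2L, ie_[i], "splice_donor")
        out[[paste0("acc", i)]] <- row(is_[i], is_[i] + 2L, "splice_acceptor")
      }
    }
  }

  # UTRs: exon bases outside the CDS, sided strand-awarely
  if (!is.null(cds) && nrow(cds)) {
    ex_ir <- IRanges::IRanges(exons$start + 1L, exons$end)
    cds_ir <- IRanges::IRanges(cds$start + 1L, cds$end)
    utr_ir <- IRanges::setdiff(ex_ir, cds_ir)
    if (length(utr_ir)) {
      cds_lo <- min(cds$start)
      cds_hi <- max(cds$end)
      for (i in seq_along(utr_ir)) {
        s0 <- IRanges::start(utr_ir)[i] - 1L
        e0 <- IRanges::end(utr_ir)[i]
        left_of_cds <- e0 <= cds_lo
        kind <- if (left_of_cds == (strand == "+")) "five_prime_UTR" else "three_prime_UTR"
        if (!left_of_cds && s0 < cds_hi) next  # interstitial piece inside CDS span: skip
        out[[paste0("utr", i)]] <- row(s0, e0, kind)
      }
    }
  }

  # flanks
  up <- if (strand == "+") c(tx_start - flank_bp, tx_start) else c(tx_end, tx_end + flank_bp)
  dn <- if (strand == "+") c(tx_end, tx_end + flank_bp) else c(tx_start - flank_bp, tx_start)
  clip <- function(x) c(max(0L, x[1]), min(chrom_length, x[2]))
  up <- clip(up); dn <- clip(dn)
  if (up[2] > up[1]) out$up <- row(up[1], up[2], "upstream_flank")
  if (dn[2] > dn[1]) out$dn <- row(dn[1], dn[2], "downstream_flank")

  dplyr::bind_rows(out) %>% arrange(.data$start, .data$end)
}

#' Write a genome_annotation back to GFF3
#'
#' Emits gene, mRNA, exon and CDS records with 1-based closed coordinates and
#' `ID`/`Parent` attributes, suitable for re-reading with
#' [read_genome_annotation()].
#'
#' @param ann a `genome_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  mk <- function(d, type, id = NULL, parent = NULL) {
    gr <- GenomicRanges::GRanges(
      seqnames = d$chrom,
      ranges = IRanges::IRanges(d$start + 1L, d$end),
      strand = d$strand
    )
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id %||% rep(NA_character_, nrow(d))
    S4Vectors::mcols(gr)$Parent <- if (is.null(parent)) {
      IRanges::CharacterList(rep(list(character(0)), nrow(d)))
    } else {
      IRanges::CharacterList(as.list(parent))
    }
    S4Vectors::mcols(gr)$phase <- rep(NA_integer_, nrow(d))
    gr
  }
  # phase for CDS records, per transcript in coding order
  cds <- ann$cds %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(.ord = if (dplyr::first(.data$strand) == "+") row_number() else rev(row_number())) %>%
    arrange(.data$.ord, .by_group = TRUE) %>%
    mutate(phase = (3L - (cumsum(dplyr::lag(.data$end - .data$start, default = 0L)) %% 3L)) %% 3L) %>%
    ungroup() %>%
    select(-".ord")

  gr <- c(
    mk(ann$genes, "gene", id = ann$genes$gene_id),
    mk(ann$transcripts, "mRNA", id = ann$transcripts$transcript_id,
       parent = ann$transcripts$gene_id),
    mk(ann$exons, "exon", parent = ann$exons$transcript_id),
    {
      g <- mk(cds, "CDS", parent = cds$transcript_id)
      S4Vectors::mcols(g)$phase <- cds$phase
      g
    }
  )
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
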