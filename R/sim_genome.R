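#' Generate a synthetic genome with a multi-isoform annotation
#'
#' Builds random chromosomes carrying protein-coding genes with 5'/3'UTRs,
#' introns with canonical GT..AG boundaries, and CDSs that start with ATG,
#' end with a stop codon and translate without internal stops. Multi-isoform
#' genes vary in UTR extent (alternative TSS / 3' end) or carry an in-frame
#' N-terminal CDS extension into the long isoform's 5'UTR, so the
#' "protein-changing in any isoform" aggregation rule can be exercised.
#' With `overlap_pairs > 0`, pairs of genes are placed so that a
#' minus-strand gene's CDS overlaps its partner's 3'UTR, feeding the
#' conservative overlap-resolution stage. Output is deterministic for a
#' fixed config (byte-identical FASTA/GFF3 on re-runs).
#'
#' @param config a [sim_config()].
#' @return a `toy_genome` object: list with `genome`
#'   ([Biostrings::DNAStringSet]), `annotation` (`genome_annotation`),
#'   `plan` (generator internals used by [sim_alleles()]) and `config`.
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, build_toy_genome(config))
}

build_toy_genome <- function(cfg) {
  plans <- purrr::map(seq_len(cfg$n_genes), function(i) {
    plan_gene(cfg, sprintf("g%03d", i))
  })

  n_pair <- cfg$overlap_pairs
  pair_a <- if (n_pair) seq(1L, 2L * n_pair, by = 2L) else integer(0)
  pair_b <- pair_a + 1L
  for (i in pair_a) plans[[i]]$strand <- "+"
  for (i in pair_b) plans[[i]]$strand <- "-"
  singles <- setdiff(seq_len(cfg$n_genes), c(pair_a, pair_b))
  for (i in singles) {
    plans[[i]]$strand <- if (runif(1) < cfg$strand_mix) "-" else "+"
  }

  # units: a pair is placed as one block with overlap depth d
  units <- list()
  for (k in seq_len(n_pair)) {
    a <- plans[[pair_a[k]]]; b <- plans[[pair_b[k]]]
    d <- min(a$u3 - 10L, b$u3 + 30L)
    if (d < 5L) stop("overlap_pairs requires 3'UTRs of at least 15 bp", call. = FALSE)
    units[[length(units) + 1L]] <- list(idx = c(pair_a[k], pair_b[k]), d = d,
                                        len = a$len + b$len - d)
  }
  for (i in singles) {
    units[[length(units) + 1L]] <- list(idx = i, d = 0L, len = plans[[i]]$len)
  }

  # assign units to chromosomes round-robin and lay them out left to right
  chrom_names <- sprintf("chr%s", utils::head(c(as.roman(seq_len(cfg$n_chromosomes))),
                                              cfg$n_chromosomes))
  chrom_names <- as.character(chrom_names)
  unit_chrom <- rep(seq_len(cfg$n_chromosomes), length.out = length(units))
  min_gap <- 2L * cfg$flank_bp + 200L

  gaps <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    us <- which(unit_chrom == ci)
    ulen <- vapply(units[us], `[[`, integer(1), "len")
    needed <- sum(ulen) + min_gap * (length(us) + 1L)
    if (needed > cfg$chrom_length) {
      stop("cannot place ", length(us), " gene unit(s) on a ", cfg$chrom_length,
           " bp chromosome (needs >= ", needed,
           " bp); increase chrom_length or reduce n_genes", call. = FALSE)
    }
    extra <- cfg$chrom_length - needed
    bump <- as.integer(rmultinom(1, extra, rep(1, length(us) + 1L)))
    pos <- 0L
    for (j in seq_along(us)) {
      gap <- min_gap + bump[j]
      gaps[[length(gaps) + 1L]] <- tibble(
        chrom = chrom_names[ci], start = pos, end = pos + gap)
      pos <- pos + gap
      u <- units[[us[j]]]
      if (length(u$idx) == 2L) {
        a <- u$idx[1]; b <- u$idx[2]
        plans[[a]]$chrom <- chrom_names[ci]; plans[[a]]$offset <- pos
        plans[[b]]$chrom <- chrom_names[ci]
        plans[[b]]$offset <- pos + plans[[a]]$len - u$d
        plans[[a]]$overlap_d <- u$d; plans[[b]]$overlap_d <- u$d
        plans[[a]]$pair_role <- "A"; plans[[b]]$pair_role <- "B"
        plans[[a]]$can_down <- FALSE; plans[[b]]$can_down <- FALSE
      } else {
        i <- u$idx
        plans[[i]]$chrom <- chrom_names[ci]; plans[[i]]$offset <- pos
      }
      pos <- pos + u$len
    }
    gaps[[length(gaps) + 1L]] <- tibble(
      chrom = chrom_names[ci], start = pos,
      end = pos + min_gap + bump[length(us) + 1L])
  }
  gaps <- dplyr::bind_rows(gaps)

  # chromosome sequences: random background, then gene sequences pasted in
  # (for overlap pairs the later, minus-strand gene wins in the overlap zone)
  chrom_seq <- setNames(
    vapply(seq_len(cfg$n_chromosomes), function(i) random_dna(cfg$chrom_length),
           character(1)),
    chrom_names)
  for (p in plans) {
    s <- if (p$strand == "+") p$gseq else revcomp_chr(p$gseq)
    cs <- chrom_seq[[p$chrom]]
    substr(cs, p$offset + 1L, p$offset + p$len) <- s
    chrom_seq[[p$chrom]] <- cs
  }

  genome <- Biostrings::DNAStringSet(chrom_seq)

  # annotation tibbles in genomic coordinates
  l2g <- function(p, s, e) {
    if (p$strand == "+") c(p$offset + s, p$offset + e)
    else c(p$offset + p$len - e, p$offset + p$len - s)
  }
  genes <- dplyr::bind_rows(purrr::map(plans, function(p) {
    tibble(chrom = p$chrom, start = p$offset, end = p$offset + p$len,
           strand = p$strand, gene_id = p$gene_id)
  }))
  tx <- list(); ex <- list(); cd <- list()
  for (p in plans) {
    for (k in seq_along(p$isoforms)) {
      iso <- p$isoforms[[k]]
      tid <- sprintf("%s.t%d", p$gene_id, k)
      exg <- t(apply(iso$exons, 1, function(r) l2g(p, r[[1]], r[[2]])))
      cdg <- t(apply(iso$cds, 1, function(r) l2g(p, r[[1]], r[[2]])))
      ex[[tid]] <- tibble(chrom = p$chrom,
                          start = as.integer(pmin(exg[, 1], exg[, 2])),
                          end = as.integer(pmax(exg[, 1], exg[, 2])),
                          strand = p$strand, transcript_id = tid,
                          gene_id = p$gene_id)
      cd[[tid]] <- tibble(chrom = p$chrom,
                          start = as.integer(pmin(cdg[, 1], cdg[, 2])),
                          end = as.integer(pmax(cdg[, 1], cdg[, 2])),
                          strand = p$strand, transcript_id = tid,
                          gene_id = p$gene_id)
      tx[[tid]] <- tibble(chrom = p$chrom,
                          start = min(ex[[tid]]$start), end = max(ex[[tid]]$end),
                          strand = p$strand, transcript_id = tid,
                          gene_id = p$gene_id)
    }
  }
  annotation <- build_annotation(
    genes,
    dplyr::bind_rows(tx),
    dplyr::bind_rows(ex) %>% arrange(.data$transcript_id, .data$start),
    dplyr::bind_rows(cd) %>% arrange(.data$transcript_id, .data$start),
    genome, flank_bp = cfg$flank_bp)

  out <- list(genome = genome, annotation = annotation,
              plan = list(genes = plans, gaps = gaps), config = cfg)
  class(out) <- "toy_genome"
  out
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("<toy_genome> ", length(x$genome), " chromosome(s) x ",
      x$config$chrom_length, " bp, ", x$config$n_genes, " gene(s), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

# one gene in local (coding-orientation) coordinates
plan_gene <- function(cfg, gene_id) {
  n_int <- sample_range(cfg$intron_count)
  n_cod <- sample_range(cfg$cds_codons)
  u5 <- sample_range(cfg$utr5_length)
  u3 <- sample_range(cfg$utr3_length)
  ns <- nonstop_codons()
  codons <- c("ATG", sample(ns, n_cod - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
  cds_seq <- paste(codons, collapse = "")
  cds_len <- 3L * n_cod

  if (n_int > 0) {
    repeat {
      cuts <- sort(sample(seq.int(4L, cds_len - 4L), n_int))
      if (n_int == 1L || min(diff(cuts)) >= 6L) break
    }
  } else {
    cuts <- integer(0)
  }
  chunk_s <- c(0L, cuts)
  chunk_e <- c(cuts, cds_len)
  intron_len <- if (n_int > 0) sample_range(cfg$intron_length, n_int) else integer(0)
  intron_seq <- vapply(intron_len, function(l) {
    paste0("GT", random_dna(l - 4L), "AG")
  }, character(1))

  u5_seq <- random_dna(u5)
  u3_seq <- random_dna(u3)

  # isoform variants
  n_iso <- sample_range(cfg$isoforms_per_gene)
  ext_k <- 0L
  iso_types <- "primary"
  if (n_iso > 1L) {
    for (j in seq_len(n_iso - 1L)) {
      pool <- c("utr5_short", "utr3_short")
      if (ext_k == 0L && u5 >= 40L) pool <- c(pool, "cds_ext")
      ty <- sample(pool, 1L)
      if (ty == "cds_ext") {
        ext_k <- sample(seq.int(2L, min(8L, (u5 - 10L) %/% 3L)), 1L)
        ext_seq <- paste(c("ATG", sample(ns, ext_k - 1L, replace = TRUE)),
                         collapse = "")
        substr(u5_seq, u5 - 3L * ext_k + 1L, u5) <- ext_seq
      }
      iso_types <- c(iso_types, ty)
    }
  }

  # local layout: [u5][chunk1][intron1][chunk2]...[chunkM][u3]
  pos <- u5
  ex_s <- 0L; ex_e <- integer(0); exon_starts <- integer(0)
  chunks <- tibble(start = integer(0), end = integer(0))
  introns <- tibble(start = integer(0), end = integer(0))
  exon_starts <- 0L
  exon_ends <- integer(0)
  for (j in seq_along(chunk_s)) {
    clen <- chunk_e[j] - chunk_s[j]
    chunks <- dplyr::bind_rows(chunks, tibble(start = pos, end = pos + clen))
    pos <- pos + clen
    if (j < length(chunk_s)) {
      exon_ends <- c(exon_ends, pos)
      introns <- dplyr::bind_rows(introns,
                                  tibble(start = pos, end = pos + intron_len[j]))
      pos <- pos + intron_len[j]
      exon_starts <- c(exon_starts, pos)
    }
  }
  pos <- pos + u3
  exon_ends <- c(exon_ends, pos)
  len <- pos
  exons <- tibble(start = exon_starts, end = exon_ends)

  chunk_seqs <- substring(cds_seq, chunk_s + 1L, chunk_e)
  body <- character(0)
  for (j in seq_along(chunk_seqs)) {
    body <- c(body, chunk_seqs[j],
              if (j <= length(intron_seq)) intron_seq[j])
  }
  gseq <- paste0(u5_seq, paste(body, collapse = ""), u3_seq)
  stopifnot(nchar(gseq) == len)

  isoforms <- list()
  for (j in seq_along(iso_types)) {
    ty <- iso_types[j]
    iso_ex <- exons
    iso_cds <- chunks
    tss_local <- 0L
    if (ty == "utr5_short") {
      hi <- u5 - 10L - 3L * ext_k
      if (hi >= 10L) {
        d5 <- sample(seq.int(10L, hi), 1L)
        iso_ex$start[1] <- d5
        tss_local <- d5
      }
    } else if (ty == "utr3_short") {
      if (u3 >= 20L) {
        d3 <- sample(seq.int(10L, u3 - 10L), 1L)
        iso_ex$end[nrow(iso_ex)] <- len - d3
      }
    } else if (ty == "cds_ext") {
      iso_cds$start[1] <- u5 - 3L * ext_k
    }
    isoforms[[j]] <- list(type = ty, exons = iso_ex, cds = iso_cds,
                          tss_local = tss_local)
  }

  list(gene_id = gene_id, strand = NA_character_, chrom = NA_character_,
       offset = NA_integer_, len = len, u5 = u5, u3 = u3, ext_k = ext_k,
       n_int = n_int, n_codons = n_cod, codons = codons, gseq = gseq,
       chunks = chunks, introns = introns, exons = exons,
       isoforms = isoforms, overlap_d = 0L, pair_role = NA_character_,
       can_down = TRUE)
}

#' Write a toy genome to FASTA and GFF3 files
#'
#' @param toy a `toy_genome` from [sim_genome()].
#' @param dir output directory (created if missing).
#' @return named character vector with the `fasta` and `gff3` paths.
#' @export
write_genome <- function(toy, dir) {
  stopifnot(inherits(toy, "toy_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  Biostrings::writeXStringSet(toy$genome, fa)
  write_gff3(toy$annotation, gff)
  c(fasta = fa, gff3 = gff)
}
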