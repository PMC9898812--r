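# fixtures are built in code at test time; nothing binary is stored

# write a GFF3 + FASTA pair and return their paths
fixture_files <- function(gff_lines, seqs) {
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  writeLines(c("##gff-version 3", gff_lines), gff)
  list(gff = gff, fasta = fa)
}

# a hand-built two-exon plus-strand gene on a 600 bp chromosome, with every
# coordinate known exactly:
#   gene span          [100,188)   (GFF 101..188)
#   5'UTR              [100,110)   = TTTTTTTTTT
#   CDS                ATG CTT GGA CAA TGG TAA  (M L G Q W *)
#     exon1 CDS part   [110,115)   = ATGCT
#     intron           [115,165)   = GT + C*46 + AG
#     exon2 CDS part   [165,178)   = TGGACAATGGTAA
#   3'UTR              [178,188)   = CCCCCCCCCC
# codon 2 (CTT) spans the intron: bases at 113, 114, 165.
hand_gene <- function(flank_bp = 5000) {
  intron <- paste0("GT", strrep("C", 46), "AG")
  chrT <- paste0(strrep("A", 100), strrep("T", 10), "ATGCT", intron,
                 "TGGACAATGGTAA", strrep("C", 10), strrep("A", 600 - 188))
  stopifnot(nchar(chrT) == 600)
  gff <- c(
    "chrT\ttest\tgene\t101\t188\t.\t+\t.\tID=gA",
    "chrT\ttest\tmRNA\t101\t188\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chrT\ttest\texon\t101\t115\t.\t+\t.\tParent=gA.t1",
    "chrT\ttest\texon\t166\t188\t.\t+\t.\tParent=gA.t1",
    "chrT\ttest\tCDS\t111\t115\t.\t+\t0\tParent=gA.t1",
    "chrT\ttest\tCDS\t166\t178\t.\t+\t1\tParent=gA.t1"
  )
  fx <- fixture_files(gff, c(chrT = chrT))
  list(ann = read_genome_annotation(fx$gff, fx$fasta, flank_bp = flank_bp),
       seq = chrT, files = fx)
}

# one-row allele tibble
allele_row <- function(pos, ref, alt, id = "x1", chrom = "chrT",
                       source = "forward_genetics") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), id = id,
                 ref = ref, alt = alt, source = source)
}

# classify one allele against the hand gene and return the fine category
fine_of <- function(hg, pos, ref, alt) {
  calls <- classify_alleles(allele_row(pos, ref, alt), hg$ann)
  calls$fine_category[calls$gene_id %in% "gA" | is.na(calls$gene_id)][1]
}

# independent CDS extraction + translation oracle (Biostrings only; never
# touches the classifier's codon arithmetic)
extract_protein <- function(genome, cds_segs) {
  segs <- cds_segs[order(cds_segs$start), , drop = FALSE]
  pieces <- substring(as.character(genome[[segs$chrom[1]]]),
                      segs$start + 1L, segs$end)
  if (segs$strand[1] == "-") {
    pieces <- rev(vapply(pieces, function(x) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    }, character(1)))
  }
  cds <- paste(pieces, collapse = "")
  # no.init.codon: read the first codon literally, otherwise alternative
  # initiators (TTG/CTG) would mask start-loss mutations as Met
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

# genome with one substitution applied (named character -> named character)
mutate_genome_chr <- function(chrom_seq, chrom, pos, alt) {
  cs <- chrom_seq[[chrom]]
  substr(cs, pos + 1L, pos + 1L) <- alt
  chrom_seq[[chrom]] <- cs
  chrom_seq
}

# mirror a toy genome: reverse-complement every chromosome and flip all
# annotation coordinates; used for strand-symmetry properties
mirror_toy <- function(toy) {
  L <- toy$config$chrom_length
  genome <- Biostrings::reverseComplement(toy$genome)
  flip <- function(d) {
    d2 <- d
    d2$start <- L - d$end
    d2$end <- L - d$start
    d2$strand <- ifelse(d$strand == "+", "-", "+")
    d2
  }
  ann <- toy$annotation
  build_annotation(flip(ann$genes), flip(ann$transcripts), flip(ann$exons),
                   flip(ann$cds), genome, flank_bp = ann$flank_bp)
}

mirror_alleles <- function(alleles, L) {
  w <- nchar(alleles$ref)
  out <- alleles
  out$pos <- ifelse(alleles$ref == "", L - alleles$pos,
                    L - alleles$pos - pmax(w, 1L))
  out$ref <- ifelse(alleles$ref == "", "", revcomp_chr(alleles$ref))
  out$alt <- ifelse(alleles$alt == "", "", revcomp_chr(alleles$alt))
  out
}

# per-bp brute-force labelling oracle for overlap resolution
per_bp_kinds <- function(features, precedence, L) {
  rank <- stats::setNames(rep(seq_along(precedence), lengths(precedence)),
                          unlist(precedence))
  best <- rep(Inf, L)
  kind <- rep(NA_character_, L)
  for (i in seq_len(nrow(features))) {
    r <- rank[[features$kind[i]]]
    idx <- seq.int(features$start[i] + 1L, features$end[i])
    better <- r < best[idx]
    best[idx[better]] <- r
    kind[idx[better]] <- features$kind[i]
  }
  kind
}

coverage_kinds <- function(resolved, L) {
  kind <- rep(NA_character_, L)
  multi <- FALSE
  for (i in seq_len(nrow(resolved))) {
    idx <- seq.int(resolved$start[i] + 1L, resolved$end[i])
    clash <- !is.na(kind[idx]) & kind[idx] != resolved$kind[i]
    if (any(clash)) multi <- TRUE
    kind[idx] <- resolved$kind[i]
  }
  list(kind = kind, multi = multi)
}
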