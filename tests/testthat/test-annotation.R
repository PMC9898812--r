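test_that("GFF3 coordinates convert to 0-based half-open and UTRs are inferred", {
  # single-exon plus-strand mRNA 201-530 with CDS 231-470
  chr <- strrep("A", 700)
  gff <- c(
    "chrT\tt\tgene\t201\t530\t.\t+\t.\tID=g1",
    "chrT\tt\tmRNA\t201\t530\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrT\tt\texon\t201\t530\t.\t+\t.\tParent=g1.t1",
    "chrT\tt\tCDS\t231\t470\t.\t+\t0\tParent=g1.t1"
  )
  fx <- fixture_files(gff, c(chrT = chr))
  ann <- read_genome_annotation(fx$gff, fx$fasta)

  expect_equal(ann$exons$start, 200L)
  expect_equal(ann$exons$end, 530L)
  utr5 <- ann$features[ann$features$kind == "five_prime_UTR", ]
  utr3 <- ann$features[ann$features$kind == "three_prime_UTR", ]
  expect_equal(c(utr5$start, utr5$end), c(200L, 230L))
  expect_equal(c(utr3$start, utr3$end), c(470L, 530L))
  expect_equal(ann$transcripts$tss, 200L)
})

test_that("minus-strand TSS is the strand-aware 5' end", {
  chr <- strrep("A", 700)
  gff <- c(
    "chrT\tt\tgene\t201\t530\t.\t-\t.\tID=g1",
    "chrT\tt\tmRNA\t201\t530\t.\t-\t.\tID=g1.t1;Parent=g1",
    "chrT\tt\texon\t201\t530\t.\t-\t.\tParent=g1.t1",
    "chrT\tt\tCDS\t231\t470\t.\t-\t0\tParent=g1.t1"
  )
  fx <- fixture_files(gff, c(chrT = chr))
  ann <- read_genome_annotation(fx$gff, fx$fasta)
  expect_equal(ann$transcripts$tss, 529L)
  # UTR sides swap on the minus strand
  utr5 <- ann$features[ann$features$kind == "five_prime_UTR", ]
  expect_equal(c(utr5$start, utr5$end), c(470L, 530L))
})

test_that("introns and splice sites are derived strand-awarely", {
  ex <- tibble::tibble(chrom = "c", start = c(200L, 380L),
                       end = c(320L, 470L), strand = "+",
                       transcript_id = "t1", gene_id = "g1")
  f <- derive_transcript_features(ex, flank_bp = 100, chrom_length = 1000)
  intron <- f[f$kind == "intron", ]
  don <- f[f$kind == "splice_donor", ]
  acc <- f[f$kind == "splice_acceptor", ]
  expect_equal(c(intron$start, intron$end), c(320L, 380L))
  expect_equal(c(don$start, don$end), c(320L, 322L))
  expect_equal(c(acc$start, acc$end), c(378L, 380L))

  # mirror: on the minus strand donor and acceptor swap ends
  ex$strand <- "-"
  f2 <- derive_transcript_features(ex, flank_bp = 100, chrom_length = 1000)
  don2 <- f2[f2$kind == "splice_donor", ]
  acc2 <- f2[f2$kind == "splice_acceptor", ]
  expect_equal(c(don2$start, don2$end), c(378L, 380L))
  expect_equal(c(acc2$start, acc2$end), c(320L, 322L))

  # single exon: no introns, no splice sites
  f3 <- derive_transcript_features(ex[1, ], flank_bp = 100, chrom_length = 1000)
  expect_false(any(f3$kind %in% c("intron", "splice_donor", "splice_acceptor")))

  # overlapping exons are rejected
  bad <- tibble::tibble(chrom = "c", start = c(200L, 300L),
                        end = c(320L, 470L), strand = "+",
                        transcript_id = "t1", gene_id = "g1")
  expect_error(derive_transcript_features(bad), "overlapping exons")
})

test_that("annotation validation reports offending records", {
  chr <- strrep("A", 700)
  # mRNA with a bogus gene parent
  gff1 <- c(
    "chrT\tt\tgene\t201\t530\t.\t+\t.\tID=g1",
    "chrT\tt\tmRNA\t201\t530\t.\t+\t.\tID=g1.t1;Parent=nope",
    "chrT\tt\texon\t201\t530\t.\t+\t.\tParent=g1.t1"
  )
  fx1 <- fixture_files(gff1, c(chrT = chr))
  expect_error(read_genome_annotation(fx1$gff, fx1$fasta), "Parent")

  # CDS outside its exon
  gff2 <- c(
    "chrT\tt\tgene\t201\t530\t.\t+\t.\tID=g1",
    "chrT\tt\tmRNA\t201\t530\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrT\tt\texon\t201\t400\t.\t+\t.\tParent=g1.t1",
    "chrT\tt\tCDS\t231\t470\t.\t+\t0\tParent=g1.t1"
  )
  fx2 <- fixture_files(gff2, c(chrT = chr))
  expect_error(read_genome_annotation(fx2$gff, fx2$fasta), "CDS outside exon")

  # chromosome absent from the FASTA
  gff3 <- c(
    "chrX\tt\tgene\t201\t530\t.\t+\t.\tID=g1",
    "chrX\tt\tmRNA\t201\t530\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrX\tt\texon\t201\t530\t.\t+\t.\tParent=g1.t1"
  )
  fx3 <- fixture_files(gff3, c(chrT = chr))
  expect_error(read_genome_annotation(fx3$gff, fx3$fasta), "absent from FASTA")
})

test_that("GFF3 write-back round-trips semantically", {
  toy <- sim_genome(sim_config(n_genes = 4, seed = 5, chrom_length = 50000))
  dir <- write_genome(toy, tempfile())
  ann <- read_genome_annotation(dir["gff3"], dir["fasta"], flank_bp = 500)
  g2 <- tempfile(fileext = ".gff3")
  write_gff3(ann, g2)
  ann2 <- read_genome_annotation(g2, dir["fasta"], flank_bp = 500)
  expect_equal(ann$exons, ann2$exons)
  expect_equal(ann$cds, ann2$cds)
  expect_equal(ann$transcripts, ann2$transcripts)
})
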