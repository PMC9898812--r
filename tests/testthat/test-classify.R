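hg <- hand_gene()

test_that("coding substitutions translate to the right categories", {
  # codon 2 (CTT, Leu) spans the intron; its third base sits at 165
  expect_equal(fine_of(hg, 165, "T", "C"), "synonymous")   # CTT -> CTC
  expect_equal(fine_of(hg, 113, "C", "G"), "missense")     # CTT -> GTT (wait: 113 is first base)
  expect_equal(fine_of(hg, 174, "G", "A"), "stop_gained")  # TGG -> TGA
  expect_equal(fine_of(hg, 177, "A", "T"), "stop_lost")    # TAA -> TAT
  expect_equal(fine_of(hg, 110, "A", "T"), "start_lost")   # ATG -> TTG
})

test_that("splice, UTR, intron, flank and intergenic positions classify by feature", {
  expect_equal(fine_of(hg, 115, "G", "A"), "splice_donor")
  expect_equal(fine_of(hg, 164, "G", "C"), "splice_acceptor")
  expect_equal(fine_of(hg, 104, "T", "G"), "five_prime_UTR")
  expect_equal(fine_of(hg, 182, "C", "G"), "three_prime_UTR")
  expect_equal(fine_of(hg, 140, "C", "G"), "intronic")
  expect_equal(fine_of(hg, 95, "A", "G"), "upstream")
  expect_equal(fine_of(hg, 300, "A", "G"), "downstream")
})

test_that("CDS indels split into frameshift, in-frame and ablation", {
  # 4 bp deletion in exon2 CDS
  expect_equal(fine_of(hg, 166, substr(hg$seq, 167, 170), ""), "frameshift")
  # 3 bp codon-aligned deletion (codon GGA at 166..168)
  expect_equal(fine_of(hg, 166, substr(hg$seq, 167, 169), ""),
               "inframe_deletion")
  # 3 bp insertion inside the CDS
  expect_equal(fine_of(hg, 167, "", "ACT"), "inframe_insertion")
  # deletion spanning the whole transcript
  expect_equal(fine_of(hg, 95, substr(hg$seq, 96, 200), ""),
               "transcript_ablation")
})

test_that("frameshift vs in-frame agrees with brute-force re-translation", {
  ref_prot <- extract_protein(hg$ann$genome,
                              hg$ann$cds[hg$ann$cds$transcript_id == "gA.t1", ])
  # apply the 3 bp codon-aligned deletion by editing the spliced CDS directly
  cds <- paste0(substr(hg$seq, 111, 115), substr(hg$seq, 166, 178))
  del3 <- paste0(substr(cds, 1, 6), substr(cds, 10, nchar(cds)))
  p3 <- as.character(Biostrings::translate(Biostrings::DNAString(del3)))
  expect_equal(nchar(p3), nchar(ref_prot) - 1)   # one amino acid lost
  expect_false(grepl("\\*", substr(p3, 1, nchar(p3) - 1)))
  del4 <- paste0(substr(cds, 1, 6), substr(cds, 11, nchar(cds)))
  expect_true(nchar(del4) %% 3 != 0)             # frame broken
})

test_that("ectopic splice donor creation is detected by the GT motif test", {
  # published-style examples: AGT with G->T removes rather than creates GT;
  # AAT with the middle A->G creates AGT
  expect_false(creates_gt("AGT", "ATT"))
  expect_true(creates_gt("AAT", "AGT"))
  expect_equal(creates_gt(c("AGT", "AAT"), c("ATT", "AGT")), c(FALSE, TRUE))

  # full path: GGA -> GGT is synonymous (Gly) but writes a GT into the exon
  calls <- classify_alleles(allele_row(168, "A", "T"), hg$ann)
  expect_equal(calls$fine_category, "synonymous")
  expect_true(calls$ectopic_donor)
  expect_equal(calls$gene_category, "coding")  # reclassified
  # while the wobble at 165 does not create a GT and stays non-coding
  calls2 <- classify_alleles(allele_row(165, "T", "C"), hg$ann)
  expect_false(calls2$ectopic_donor)
  expect_equal(calls2$gene_category, "synonymous")
})

test_that("isoform aggregation takes the most severe category and the
           any-isoform protein-change rule", {
  pt <- tibble::tibble(
    allele_id = "a", transcript_id = c("t1", "t2"),
    category = c("five_prime_UTR", "missense"),
    detail = NA_character_, ectopic_donor = FALSE)
  agg <- aggregate_consequences(pt)
  expect_equal(agg$fine_category, "missense")
  expect_equal(agg$gene_category, "coding")

  pt2 <- tibble::tibble(
    allele_id = "a", transcript_id = c("t1", "t2"),
    category = "synonymous", detail = NA_character_,
    ectopic_donor = c(TRUE, FALSE))
  agg2 <- aggregate_consequences(pt2)
  expect_equal(agg2$fine_category, "synonymous")
  expect_equal(agg2$gene_category, "coding")

  single <- tibble::tibble(allele_id = "a", transcript_id = "t1",
                           category = "intergenic", detail = NA_character_,
                           ectopic_donor = FALSE)
  expect_equal(aggregate_consequences(single)$gene_category,
               "intergenic_unassigned")

  expect_error(aggregate_consequences(single[0, ]), "at least one")

  # ties across isoforms break by lexicographic transcript id
  tie <- tibble::tibble(allele_id = "a", transcript_id = c("t9", "t1"),
                        category = "missense",
                        detail = c("d9", "d1"), ectopic_donor = FALSE)
  expect_equal(aggregate_consequences(tie)$detail, "d1")
})

test_that("alleles on unknown chromosomes warn and classify as intergenic", {
  al <- allele_row(10, "A", "G", chrom = "chrZ")
  expect_warning(calls <- classify_alleles(al, hg$ann), "absent")
  expect_equal(calls$fine_category, "intergenic")
  expect_equal(calls$gene_category, "intergenic_unassigned")
})

test_that("every allele of a simulated set gets exactly one call per gene and
           counts are conserved", {
  toy <- sim_genome(sim_config(n_genes = 8, seed = 31, chrom_length = 80000))
  sa <- sim_alleles(toy, n = 120)
  calls <- classify_alleles(sa$alleles, toy$annotation)
  expect_equal(anyDuplicated(calls[, c("allele_id", "gene_id")]), 0L)
  expect_setequal(unique(calls$allele_id), sa$alleles$id)
  # each allele has exactly one gene category per gene row
  expect_true(all(calls$gene_category %in%
                    c("coding", "splicing", "synonymous",
                      "non_coding_regulatory", "intergenic_unassigned")))
})

test_that("classification is invariant under genome mirroring", {
  toy <- sim_genome(sim_config(n_genes = 6, seed = 17, chrom_length = 70000))
  sa <- sim_alleles(toy, n = 80)
  calls <- classify_alleles(sa$alleles, toy$annotation) %>%
    dplyr::arrange(allele_id, gene_id)
  ann_m <- mirror_toy(toy)
  al_m <- mirror_alleles(sa$alleles, toy$config$chrom_length)
  calls_m <- classify_alleles(al_m, ann_m) %>%
    dplyr::arrange(allele_id, gene_id)
  expect_equal(calls$allele_id, calls_m$allele_id)
  expect_equal(calls$gene_id, calls_m$gene_id)
  expect_equal(calls$fine_category, calls_m$fine_category)
  expect_equal(calls$gene_category, calls_m$gene_category)
})
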