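test_that("category breakdown percentages are half-up to one decimal and
           recomputed from counts", {
  calls <- tibble::tibble(
    gene_category = c(rep("coding", 8), rep("synonymous", 1),
                      rep("non_coding_regulatory", 1)),
    fine_category = c(rep("missense", 8), "synonymous", "five_prime_UTR"))
  bd <- category_breakdown(calls)
  grp <- bd[bd$level == "group", ]
  expect_equal(grp$percent[grp$category == "coding"], 80.0)
  expect_equal(grp$percent[grp$category == "non_coding"], 20.0)
  expect_equal(sum(grp$n), 10)

  # empty input: empty breakdown, not a division error
  expect_equal(nrow(category_breakdown(calls[0, ])), 0)

  # single category: 100.0
  solo <- category_breakdown(tibble::tibble(gene_category = rep("coding", 10),
                                            fine_category = "missense"))
  expect_equal(solo$percent[solo$level == "group"], 100.0)
})

test_that("breakdown on simulated alleles recovers the requested mix", {
  toy <- sim_genome(sim_config(n_genes = 8, seed = 23, chrom_length = 80000))
  sa <- sim_alleles(toy, n = 500,
                    proportions = c(missense = 0.5, splice_donor = 0.2,
                                    five_prime_UTR = 0.3))
  calls <- classify_alleles(sa$alleles, toy$annotation)
  best <- calls %>%
    dplyr::inner_join(sa$truth, by = c("allele_id" = "id",
                                       "gene_id" = "gene_id"))
  bd <- category_breakdown(best)
  fine <- bd[bd$level == "fine_category", ]
  expect_equal(fine$percent[fine$category == "missense"], 50.0,
               tolerance = 0.004)
  expect_equal(fine$percent[fine$category == "splice_donor"], 20.0,
               tolerance = 0.01)
  expect_equal(fine$percent[fine$category == "five_prime_UTR"], 30.0,
               tolerance = 0.007)
})

test_that("distance summary: nearest-rank percentile, degenerate CI, errors", {
  ds <- distance_stats(c(0, 0, 100, 900, 1500, 5000), B = 1000, seed = 2)
  expect_equal(ds$min, 0)
  expect_equal(ds$max, 5000)
  expect_equal(ds$percentile_95, 5000)  # ceiling(0.95 * 6) = 6th value
  expect_true(ds$ci_low <= ds$median && ds$median <= ds$ci_high)
  expect_true(ds$ci_reliable)

  same <- distance_stats(rep(700, 12), B = 1000, seed = 3)
  expect_equal(c(same$ci_low, same$ci_high), c(700, 700))

  expect_error(distance_stats(numeric(0)), "at least one")
  tiny <- distance_stats(c(10, 20), B = 1000, seed = 4)
  expect_false(tiny$ci_reliable)
})

test_that("distance summary is deterministic per seed, including CI endpoints", {
  x <- rlnorm(100, log(1200), 0.87)
  a <- distance_stats(x, B = 2000, seed = 11)
  b <- distance_stats(x, B = 2000, seed = 11)
  expect_identical(glance(a), glance(b))
  expect_equal(tidy(a)$statistic[4], "median")
})

test_that("activity percentages per region sum to 100 and split denominators
           by region coverage", {
  st <- tibble::tibble(
    study_id = c("s1", "s2", "s3", "s4", "s5"),
    regions = c("transcriptional_cis_regulatory",
                "transcriptional_cis_regulatory",
                "transcriptional_cis_regulatory",
                "transcriptional_cis_regulatory,five_prime_UTR",
                "five_prime_UTR"),
    conclusion = c("activating", "activating", "activating", "both",
                   "repressive"))
  ab <- activity_breakdown(st)
  tcr <- ab[ab$region == "transcriptional_cis_regulatory", ]
  expect_equal(tcr$percent[tcr$conclusion == "activating"], 75.0)
  expect_equal(tcr$percent[tcr$conclusion == "both"], 25.0)
  expect_equal(sum(tcr$percent), 100)
  # s4 also counts in the 5'UTR denominator
  utr <- ab[ab$region == "five_prime_UTR", ]
  expect_equal(utr$n_region[1], 2)
  # single-study region: 100% in its class
  solo <- activity_breakdown(tibble::tibble(study_id = "s9",
                                            regions = "three_prime_UTR",
                                            conclusion = "repressive"))
  expect_equal(solo$percent, 100)
})

test_that("throughput totals, maxima and means per technique", {
  st <- tibble::tibble(
    technique = c(rep("forward_genetics", 5), "crispr", rep("reporter", 3)),
    n_mutations = c(1, 1, 2, 1, 2, 1000, 100, 20, 5))
  tp <- study_throughput(st)
  fw <- tp[tp$technique == "forward_genetics", ]
  expect_equal(fw$mean, 1.4)
  expect_equal(fw$total, 7)
  cr <- tp[tp$technique == "crispr", ]
  expect_equal(cr$max, 1000)
  expect_equal(cr$max, cr$total)  # singleton study
  rep_ <- tp[tp$technique == "reporter", ]
  expect_equal(rep_$total, 125)
  expect_equal(rep_$max, 100)
})
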