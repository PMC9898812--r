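test_that("exclusion partitions the input with exactly one reason each", {
  calls <- tibble::tibble(
    allele_id = sprintf("a%02d", 1:10),
    gene_category = c(rep("coding", 2), rep("synonymous", 3),
                      rep("non_coding_regulatory", 5)),
    ectopic_donor = c(rep(FALSE, 4), TRUE, rep(FALSE, 5)))
  table <- tibble::tibble(
    item_id = c("a06", "a07", "a08"),
    protein_change = c(TRUE, FALSE, FALSE),
    passenger = c(TRUE, TRUE, FALSE),       # a06 also passenger: first rule wins
    insufficient_info = c(FALSE, FALSE, TRUE))
  out <- apply_exclusion_rules(calls, table)
  expect_equal(nrow(out), nrow(calls))                       # partition
  expect_true(all(out$included == is.na(out$exclusion_reason)))
  expect_equal(sum(!out$included), 6)
  expect_equal(out$exclusion_reason[out$allele_id == "a05"],
               "protein_changing_any_isoform")               # ectopic donor
  expect_equal(out$exclusion_reason[out$allele_id == "a06"],
               "protein_changing_any_isoform")               # rule order a > b
  expect_equal(out$exclusion_reason[out$allele_id == "a07"], "passenger")
  expect_equal(out$exclusion_reason[out$allele_id == "a08"],
               "insufficient_information")
  expect_true(all(is.na(out$exclusion_reason[out$included])))
})

test_that("table ids missing from the calls produce a warning, not an error", {
  calls <- tibble::tibble(allele_id = "a1",
                          gene_category = "non_coding_regulatory",
                          ectopic_donor = FALSE)
  tab <- tibble::tibble(item_id = c("a1", "ghost"), passenger = c(FALSE, TRUE))
  expect_warning(out <- apply_exclusion_rules(calls, tab), "ghost")
  expect_true(out$included)
})

test_that("no flags and all non-coding calls means nothing is excluded", {
  calls <- tibble::tibble(allele_id = letters[1:4],
                          gene_category = "non_coding_regulatory",
                          ectopic_donor = FALSE)
  out <- apply_exclusion_rules(calls)
  expect_true(all(out$included))
})

test_that("regulatory class assignment follows the core-promoter/enhancer rules", {
  rec <- tibble::tibble(
    context = c("upstream", "upstream", "upstream", "upstream", "upstream",
                "five_prime_UTR", "three_prime_UTR", "intronic", "downstream"),
    distance_raw = c(40L, 100L, 101L, 2000L, 800L, 30L, 50L, 0L, 60L),
    source_label = c(NA, NA, NA, "enhancer", NA, NA, NA, NA, NA))
  out <- assign_regulatory_class(rec)
  expect_equal(out$region_class,
               c("core_promoter", "core_promoter", "promoter", "enhancer",
                 "promoter", "five_prime_UTR", "three_prime_UTR", "intron",
                 "downstream"))
  expect_equal(out$transcriptional_cis_regulatory,
               c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # the window is configurable
  out2 <- assign_regulatory_class(rec, core_promoter_bp = 150)
  expect_equal(out2$region_class[3], "core_promoter")
})

test_that("TSS distances are strand-aware, zero inside the transcript, and
           rounded in 50/100/500 steps", {
  # plus strand, TSS at 1000: element ending at 127 bp upstream
  expect_equal(tss_distance(800L, 873L, 1000L, "+"), 127L)
  # element overlapping or downstream of the TSS (intronic): 0
  expect_equal(tss_distance(1200L, 1300L, 1000L, "+"), 0L)
  expect_equal(tss_distance(950L, 1050L, 1000L, "+"), 0L)
  # minus strand mirror
  expect_equal(tss_distance(1128L, 1200L, 1000L, "-"), 127L)
  expect_equal(tss_distance(700L, 800L, 1000L, "-"), 0L)

  expect_equal(round_distance(873L), 850L)
  expect_equal(round_distance(8463L), 8500L)
  expect_equal(round_distance(c(0L, 24L, 25L, 1049L, 4951L, 5200L)),
               c(0L, 0L, 50L, 1000L, 5000L, 5000L))
  # monotonicity: display never drifts more than 250 bp from raw
  x <- as.integer(seq(0, 12000, by = 7))
  expect_true(all(abs(round_distance(x) - x) <= 250))
  expect_true(all(round_distance(x) >= 0))
})

test_that("activity inference maps down to activating and up to repressive", {
  expect_equal(infer_activity(c("down", "down", "up")),
               c("activating", "activating", "repressive"))
  expect_warning(out <- infer_activity(c("down", "sideways")), "unknown")
  expect_true(is.na(out[2]))
})

test_that("study conclusions aggregate by unanimity, with an NMD filter", {
  rec <- tibble::tibble(
    study_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
    effect = c("down", "down", "down", "up", "down", "up"),
    mechanism = c(NA, NA, NA, NA, "NMD", NA))
  agg <- aggregate_study_activity(rec)
  expect_equal(agg$conclusion[agg$study_id == "s1"], "activating")
  expect_equal(agg$conclusion[agg$study_id == "s2"], "both")
  # s3 is a 3'UTR-style study: {activating (NMD), repressive}
  expect_equal(agg$conclusion[agg$study_id == "s3"], "both")
  agg2 <- aggregate_study_activity(rec, nmd_filter = TRUE)
  expect_equal(agg2$conclusion[agg2$study_id == "s3"], "repressive")

  # a study left with no records gets conclusion "none"
  only_nmd <- tibble::tibble(study_id = "s9", effect = "down",
                             mechanism = "NMD")
  expect_equal(aggregate_study_activity(only_nmd, nmd_filter = TRUE)$conclusion,
               "none")
})

test_that("swapping up and down flips every conclusion and fixes 'both'", {
  withr::with_seed(5, {
    rec <- tibble::tibble(
      study_id = rep(sprintf("s%02d", 1:20), each = 2),
      effect = sample(c("down", "up"), 40, replace = TRUE),
      mechanism = NA_character_)
  })
  a <- aggregate_study_activity(rec)
  rec2 <- rec %>%
    dplyr::mutate(effect = ifelse(effect == "down", "up", "down"))
  b <- aggregate_study_activity(rec2)
  flip <- c(activating = "repressive", repressive = "activating",
            both = "both", none = "none")
  expect_equal(unname(flip[a$conclusion]), b$conclusion)
})
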