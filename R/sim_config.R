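#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the simulator: genome geometry, gene structure,
#' the consequence-category mix of generated alleles, and the distributions
#' behind the curated element/study tables. All randomness downstream flows
#' from the single `seed`.
#'
#' The default category mix uses the published census proportions where the
#' census prints them (missense 47.4%, stop gains 27.7%, the remaining coding
#' classes 5.3% in total, splice acceptor 10.8%, splice donor 4.6%); the
#' remaining 4.2% is spread across the non-coding categories so that the
#' regulatory arm of the pipeline sees usable counts at the default
#' `n_alleles`. The default distance distribution is log-normal with median
#' 1,200 bp and `sdlog` 0.87 (putting the theoretical 95th percentile near
#' 5,000 bp); study-table defaults reproduce the published throughput
#' marginals exactly (50 reporter studies totalling 1,625 tested mutations,
#' the largest 195; 87 endogenous mutations with forward screens averaging
#' 1.4 per study).
#'
#' @param n_chromosomes,chrom_length genome geometry (bp).
#' @param n_genes number of genes to place (non-overlapping unless
#'   `overlap_pairs > 0`).
#' @param isoforms_per_gene,intron_count,cds_codons,utr5_length,utr3_length,intron_length
#'   inclusive `c(lo, hi)` ranges for gene structure.
#' @param strand_mix fraction of genes on the minus strand.
#' @param flank_bp upstream/downstream flank extent used when annotating and
#'   classifying; gene placement guarantees intergenic gaps wide enough that
#'   flanks of neighbouring genes never touch.
#' @param overlap_pairs number of gene pairs placed so that the second
#'   (minus-strand) gene's CDS overlaps the first gene's 3'UTR, to exercise
#'   conservative overlap resolution.
#' @param category_proportions named non-negative fractions over consequence
#'   categories, summing to 1.
#' @param n_alleles number of alleles for [sim_alleles()].
#' @param n_elements,dist_median,dist_sdlog regulatory-element table size and
#'   log-normal distance distribution (bp).
#' @param n_reporter,reporter_total,reporter_max,n_forward,forward_mean,n_crispr,endogenous_total
#'   study-table composition; totals/means are made exact by construction.
#' @param p_down named probabilities that a mutation in each region type
#'   shows reduced expression ("down").
#' @param records_per_study `c(lo, hi)` activity records per study.
#' @param seed integer seed driving all generation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 120000L,
                       n_genes = 20L,
                       isoforms_per_gene = c(1L, 2L),
                       intron_count = c(1L, 3L),
                       cds_codons = c(60L, 150L),
                       utr5_length = c(60L, 250L),
                       utr3_length = c(60L, 250L),
                       intron_length = c(45L, 120L),
                       strand_mix = 0.5,
                       flank_bp = 500L,
                       overlap_pairs = 0L,
                       category_proportions = default_category_proportions(),
                       n_alleles = 1000L,
                       n_elements = 100L,
                       dist_median = 1200,
                       dist_sdlog = 0.87,
                       n_reporter = 50L,
                       reporter_total = 1625L,
                       reporter_max = 195L,
                       n_forward = 30L,
                       forward_mean = 1.4,
                       n_crispr = 5L,
                       endogenous_total = 87L,
                       p_down = c(transcriptional_cis_regulatory = 0.95,
                                  five_prime_UTR = 0.95,
                                  three_prime_UTR = 0.05),
                       records_per_study = c(1L, 2L),
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    isoforms_per_gene = isoforms_per_gene,
    intron_count = intron_count,
    cds_codons = cds_codons,
    utr5_length = utr5_length,
    utr3_length = utr3_length,
    intron_length = intron_length,
    strand_mix = strand_mix,
    flank_bp = as.integer(flank_bp),
    overlap_pairs = as.integer(overlap_pairs),
    category_proportions = category_proportions,
    n_alleles = as.integer(n_alleles),
    n_elements = as.integer(n_elements),
    dist_median = dist_median,
    dist_sdlog = dist_sdlog,
    n_reporter = as.integer(n_reporter),
    reporter_total = as.integer(reporter_total),
    reporter_max = as.integer(reporter_max),
    n_forward = as.integer(n_forward),
    forward_mean = forward_mean,
    n_crispr = as.integer(n_crispr),
    endogenous_total = as.integer(endogenous_total),
    p_down = p_down,
    records_per_study = records_per_study,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Supported consequence categories of the allele generator
#' @return character vector of category names.
#' @export
supported_categories <- function() {
  c("missense", "synonymous", "stop_gained", "stop_lost", "start_lost",
    "frameshift", "inframe_deletion", "inframe_insertion",
    "transcript_ablation", "splice_donor", "splice_acceptor",
    "five_prime_UTR", "three_prime_UTR", "intronic",
    "upstream", "downstream", "intergenic")
}

#' @rdname sim_config
#' @export
default_category_proportions <- function() {
  c(missense = 0.474, stop_gained = 0.277,
    frameshift = 0.018, start_lost = 0.008, stop_lost = 0.008,
    inframe_deletion = 0.009, inframe_insertion = 0.008,
    transcript_ablation = 0.002,
    splice_acceptor = 0.108, splice_donor = 0.046,
    synonymous = 0.005,
    five_prime_UTR = 0.008, three_prime_UTR = 0.008, intronic = 0.007,
    upstream = 0.007, downstream = 0.004, intergenic = 0.003)
}

validate_sim_config <- function(cfg) {
  p <- cfg$category_proportions
  if (any(p < 0)) stop("category_proportions must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("category_proportions must sum to 1 (got ", sum(p), ")", call. = FALSE)
  }
  bad <- setdiff(names(p), supported_categories())
  if (length(bad)) {
    stop("unsupported consequence categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rngs <- cfg[c("isoforms_per_gene", "cds_codons", "utr5_length",
                "utr3_length", "intron_length")]
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (any(r < 1) || r[[1]] > r[[length(r)]]) {
      stop("invalid range for ", nm, call. = FALSE)
    }
  }
  if (any(cfg$intron_count < 0) ||
      cfg$intron_count[[1]] > cfg$intron_count[[length(cfg$intron_count)]]) {
    stop("invalid range for intron_count", call. = FALSE)
  }
  if (cfg$strand_mix < 0 || cfg$strand_mix > 1) {
    stop("strand_mix must be in [0, 1]", call. = FALSE)
  }
  if (cfg$overlap_pairs > 0 && 2L * cfg$overlap_pairs > cfg$n_genes) {
    stop("overlap_pairs requires at least 2 genes per pair", call. = FALSE)
  }
  invisible(cfg)
}
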