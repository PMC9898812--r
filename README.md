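# regbash

Classification and curation of gene-regulatory alleles in *C. elegans*-style
genomes.

## The problem

Decades of forward-genetics screens, CRISPR editing and reporter-bashing
experiments have produced a scattered catalogue of mutations in non-coding
DNA. Building a census of the gene-regulatory sequences behind them requires
three things done carefully:

1. **Consequence classification.** Every allele (point mutation or small
   indel) must be categorized by its impact on the host gene — missense,
   synonymous, stop gain/loss, start loss, frameshift, in-frame indel,
   transcript ablation, splice donor/acceptor, 5'/3'UTR, intronic,
   upstream/downstream, intergenic — against *every* isoform, because an
   allele that changes protein sequence in any isoform is not a clean
   regulatory allele. Overlapping annotation features (the classic case: a
   3'UTR running into another gene's coding sequence) are first resolved
   conservatively, keeping at each base the feature that would *disqualify*
   an allele from being called regulatory (CDS and splice sites outrank
   UTRs, which outrank introns and flanks).
2. **Curation rules.** Candidates are excluded, in a fixed order of
   reasons, when they are protein-changing in any isoform (including
   nominally synonymous changes that create an ectopic GT splice donor),
   passenger mutations, or records with insufficient information.
   Transcriptional elements within ±100 bp of the TSS are core promoters;
   elements called "enhancer" by their original publication keep that
   label; the rest are promoters. A mutation causing downregulation implies
   the native element *activates* (null and reduced effects both count as
   "down"); upregulation implies it *represses*.
3. **Census statistics.** Category breakdowns (printed-style half-up
   percentages), element distance-to-TSS summaries (nearest-rank 95th
   percentile, percentile-bootstrap 95% CI of the median), per-region
   percentages of study-level activity conclusions, and per-technique
   throughput (total, maximum and mean tested mutations per study).

Because the real inputs are a genome-scale annotation plus hand-curated
literature tables, the package ships a **synthetic-data generator**:
random genomes with multi-isoform genes (5'/3'UTRs, GT..AG introns, CDSs
that translate ATG..stop), alleles whose category is forced by
construction, and study tables drawn from declared distributions — all with
known ground truth, so every pipeline stage is testable end to end with no
download.

## Worked example

```r
library(regbash)
library(dplyr)

cfg  <- sim_config(n_genes = 8, n_alleles = 200, seed = 42,
                   chrom_length = 80000)
toy  <- sim_genome(cfg)                      # FASTA/GFF3-ready toy genome
sa   <- sim_alleles(toy)                     # alleles + ground truth
calls <- classify_alleles(sa$alleles, toy$annotation)
best  <- inner_join(calls, sa$truth, by = c(allele_id = "id", "gene_id"))

bd <- category_breakdown(best)
bd[bd$level == "group", ]
#>   level category   parent     n percent total
#> 1 group coding     <NA>     161    80.5   200
#> 2 group splicing   <NA>      31    15.5   200
#> 3 group non_coding <NA>       8     4     200
```

80.5% of the simulated alleles change protein sequence, 15.5% hit splice
sites and 4% are non-coding candidates — the realized version of the
configured category mix (the generator defaults put 80.4% of probability
mass on coding categories). Study tables and element distances follow the
same pattern:

```r
tabs <- sim_study_tables(cfg)
el   <- filter(tabs$elements, region == "transcriptional_cis_regulatory")
distance_stats(el$distance_raw, B = 2000, seed = 42)
#> <distance summary> n = 74, median = 1111 bp (bootstrap 95% CI 837.5-1306.5),
#>   95th percentile = 4029 bp, range 89-4727 bp

study_throughput(tabs$studies)
#>   technique        n_studies total   max  mean
#> 1 crispr                   5    45    11   9
#> 2 forward_genetics        30    42     2   1.4
#> 3 reporter                50  1625   195  32.5
```

The median element sits ~1.1 kb upstream of the TSS with the bulk of
elements inside 5 kb (the generating log-normal has median 1,200 bp);
reporter studies dominate throughput (1,625 tested mutations in total, the
largest study 195), while forward screens average 1.4 mutations per study.
Per-study activity conclusions and their per-region percentages come from
`aggregate_study_activity()` + `activity_breakdown()`, and
`write_report()` emits a schema-validated JSON report plus per-figure TSV
tables.

To work from files instead of in-memory objects: `write_genome()` /
`write_alleles()` emit FASTA + GFF3 + TSV, `read_genome_annotation()` /
`read_alleles()` read and validate them (ref-mismatch rejection, duplicate
collapsing, indel left-alignment), and `write_bed()` exports one BED track
per consequence category.

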