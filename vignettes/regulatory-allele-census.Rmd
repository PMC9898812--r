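---
title: "Methods: classifying and curating gene-regulatory alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and curating gene-regulatory alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regbash)
library(dplyr)
```

# Overview

`regbash` implements a census pipeline for gene-regulatory sequences: it
classifies alleles against a transcript annotation, applies
literature-curation rules to isolate genuine cis-regulatory candidates, and
summarises the resulting catalogue. This vignette documents the model and
its assumptions, the tunable parameters, the synthetic-data generator used
for validation, and the numerical choices that are open to debate.

# Coordinate conventions

All internal coordinates are 0-based half-open, which makes interval
arithmetic unambiguous (`end - start` is a length; adjacent intervals share
a boundary). The standard formats keep their native conventions at the
boundaries: GFF3 is read and written 1-based closed, BED is written 0-based
half-open, allele TSVs carry 1-based positions in the file. The TSS is the
strand-aware 5' end of a transcript: `start` on the plus strand, `end - 1`
on the minus strand.

# Conservative overlap resolution

Transcript annotations overlap — isoforms of one gene, and features of
neighbouring genes (a 3'UTR running into the coding sequence of the next
gene is the canonical case). Before classification, `resolve_overlaps()`
reduces all derived features to a track in which every base carries only
the highest-precedence feature kind that covered it:

> CDS > splice donor = splice acceptor > 5'UTR > 3'UTR > intron >
> upstream/downstream flank

"Conservative" means: when two kinds claim a base, keep the kind that would
make an allele there *not* count as regulatory. This is the same direction
as the curation rule that discards alleles changing protein sequence in any
isoform. The published precedence is not spelled out beyond the
3'UTR-versus-CDS example, so the order above is a design choice of this
package, exposed as the `precedence` argument. Kinds of equal rank (the two
splice-site kinds, the two flank kinds) never truncate each other. The
property suite verifies the interval-level implementation against a per-bp
brute-force labelling on random fixtures.

One consequence worth knowing: a transcript-span base whose own feature was
truncated away (because another gene's CDS claimed it) classifies as
*intergenic* for the losing gene. The overlapping allele still gets its
coding call for the winning gene, which is what the conservative direction
requires.

# Consequence classification

Per transcript, substitutions in CDS are located in their codon (codons may
span introns; the coding-order base map handles this) and translated with
the standard nuclear code: synonymous, missense, stop gained, stop lost, or
start lost when the annotated initiator codon is disrupted. Downstream
in-frame ATGs are not rescued — start loss is assessed against the
annotated first codon only. CDS indels are frameshift when the length
change is not a multiple of three, otherwise in-frame; deletions covering
the whole transcript span are transcript ablations. Positions in the 2-bp
splice dinucleotides (canonical GT/AG; width fixed at 2 bp) give splice
categories; other positions take UTR/intron/flank categories from the
resolved track; everything else is intergenic. Variants 3–6 bp into an
intron are *intronic* by default — an "unclear splice" class can only come
annotated from the source, it is not computed.

A nominally synonymous substitution can still change protein sequence by
creating an ectopic splice donor. The flag uses the minimal motif test: did
the edit write a GT dinucleotide (coding strand) into the ±1 window around
the edited base where the reference had none? No splice-strength model is
used — the census needs the phenomenon flagged, not scored.

Across isoforms, the most severe per-transcript category wins (ties break
by lexicographic transcript id), and the gene-level category is `coding` as
soon as any isoform yields a protein-changing category — including a
flagged ectopic donor under a synonymous winner. An allele overlapping two
genes is classified independently per gene and reported once per gene, so
counts stay explicit.

# Curation rules

Exclusion reasons apply in a fixed order so each record carries exactly
one: (1) protein-changing in any isoform (computed, flagged, or reported by
the original publication), (2) passenger mutation, (3) insufficient
information. Passenger status and mechanisms are *inputs*, as they are in
any literature-curated catalogue — the package encodes the rules, not the
judgement.

Region classes: transcriptional elements within `core_promoter_bp` of the
TSS (default 100 bp) are core promoters. The window is applied
symmetrically (|distance| ≤ 100); the "+100 bp" convention is ambiguous
about the strictly-downstream reading, so the choice is exposed as
configuration rather than asserted. Elements labelled "enhancer" by their
source keep the label; remaining transcriptional elements are promoters.
All three carry the umbrella flag `transcriptional_cis_regulatory`, which
sidesteps the promoter/enhancer definitional dispute.

Distances to the TSS are measured upstream from the element boundary
nearest the TSS; elements at or downstream of the TSS (intronic elements in
particular) get 0, which reconciles a "distance to the TSS" axis with
intronic elements "at 0 bp". Display rounding mimics how such distances are
read off browser shots: nearest 50 under 1 kb, nearest 100 between 1 and
5 kb, nearest 500 beyond (a concrete reading of "rounding to 50s and 100s,
or several 100s"); raw distances are always retained.

Activity: "down" (reduction or loss of expression; null and reduced alike)
implies the native element activates; "up" (expression in extra cells,
tissues or stages) implies it represses. Study conclusions are unanimity
over records — `both` otherwise. The optional NMD filter removes
3'UTR records whose mechanism is nonsense-mediated decay before
aggregation, since ectopic NMD causes downregulation without implying a
native activating element; a study left empty concludes `none` and drops
out of the percentage denominators.

# Summary statistics

Percentages are printed half-up to one decimal (so families of percentages
can miss 100 by up to 0.1 per category — the tests allow exactly that
tolerance). The 95th percentile of distances uses the nearest-rank method;
the central interval is a percentile bootstrap (2.5/97.5) of the sample
median, deterministic per seed, with `B = 1000` as the floor for reported
CIs. Whether "central interval" should instead be a density-mode interval
is genuinely open; the median-CI reading is the package's choice and the
bootstrap machinery is agnostic to it. Degenerate inputs: zero distances
error; fewer than five give point estimates with the CI marked unreliable;
a constant sample gives a width-zero CI.

# The synthetic-data generator

The generator exists so that every stage has inputs with known truth. What
it emulates:

* genes with 5'/3'UTRs, 1–3 introns (GT..AG, length 45–120 bp), CDSs of
  60–150 codons that start ATG, end at a stop and translate with no
  internal stop, placed without overlap on random-background chromosomes,
  half on the minus strand;
* multi-isoform genes, via shortened UTRs (alternative TSS / 3' end) or an
  in-frame N-terminal CDS extension into the long isoform's 5'UTR — the
  construction that lets one genomic sequence satisfy every isoform's CDS
  while exercising the any-isoform protein-change rule;
* an overlap mode placing a minus-strand gene's CDS over a neighbour's
  3'UTR, feeding the resolution stage its canonical case;
* alleles whose category is forced by construction (e.g. a synonymous
  allele is a wobble substitution that provably creates no GT; a missense
  allele changes the amino acid in coding sequence shared by all isoforms),
  with largest-remainder apportionment making realized counts exact;
* study tables whose per-technique totals are exact by construction
  (50 reporter studies totalling 1,625 tested mutations with a 195-mutation
  maximum; 87 endogenous mutations with forward screens at exactly 1.4 per
  study) and element distances drawn log-normal.

Default parameter choices, and why:

* **Category mix**: the coding and splicing proportions follow the
  published census of classical alleles (47.4% missense, 27.7% stop gains,
  5.3% other coding; 10.8%/4.6% splice acceptor/donor). The remaining 4.2%
  is spread over the non-coding categories rather than reproducing their
  real-world rarity (0.8%), so the regulatory arm of the pipeline sees
  usable counts at `n_alleles = 1000`. The "unclear splice" class is
  source-annotated, not computable, and is not generated.
* **Distances**: log-normal with median 1,200 bp and `sdlog = 0.87`, which
  places the theoretical 95th percentile near 5,000 bp — the span within
  which known transcriptional elements overwhelmingly sit. No generative
  model is published for these distances; this is a declared simulation
  choice, as are all distributional forms here.
* **Activity rates**: per-record "down" probabilities of 0.95
  (transcriptional, 5'UTR) and 0.05 (3'UTR), with 1–2 records per study and
  10% of studies spanning two regions. These per-record rates are not
  published; they are set so that the study-level outcome matches the
  reported marginals (over three quarters of studies concluding activating
  for transcriptional elements and 5'UTRs, repressive for 3'UTRs).
* **Flank extent**: 500 bp in simulations (placement guarantees intergenic
  gaps of at least twice the flank plus 200 bp, so flanks never collide);
  5,000 bp when reading real-scale annotations, matching the element
  distance span above.

What the generator does *not* emulate: realistic sequence composition,
operons and trans-splicing, non-coding RNA genes, UTR introns,
alternative splicing beyond the isoform constructions above, and multi-hit
positions. Passing tests therefore demonstrate correctness of the
*rules* — coordinate arithmetic, codon handling, precedence, aggregation,
curation logic, statistics — not robustness to every oddity of a real
transcriptome.

# Problem sizes and determinism

The shipped test-suite and acceptance runs use 6–20 genes on 50–150 kb
chromosomes, 60–1,000 alleles, 100-replicate calibration of the bootstrap
CI (n = 200, B = 1000 each), and 100 random fixtures for the per-bp
resolution oracle — sizes chosen so a full validation runs in minutes on a
laptop while keeping every count assertion exact. All randomness flows
from single integer seeds (`withr::with_seed`), and the generator,
bootstrap and JSON report are byte-reproducible per seed.

# Known limitations

* Indels partially overlapping a CDS boundary are classified by their full
  length change; no attempt is made to split the consequence across the
  boundary.
* Left-alignment is applied to pure insertions/deletions only; complex
  substitutions (equal-length MNVs) are out of scope for the allele model.
* Start loss is annotation-bound: a mutation creating a usable downstream
  start is still start-lost here.
* The ectopic-donor motif test has no notion of splice-site strength and
  will not flag GT-creating changes outside the ±1 window of the edit.
* `aggregate_study_activity()` treats records as exchangeable; weighting
  by the number of examined mutations or genes would likely sharpen the
  per-region contrasts but needs inputs the catalogue schema does not
  require.
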