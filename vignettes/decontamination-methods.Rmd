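---
title: "Negative-control-based virome decontamination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative-control-based virome decontamination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroclean)
```

## The problem

Virome sequencing of low-biomass specimens — infant stool after viral-like
particle (VLP) enrichment is the canonical case — is acutely sensitive to
contamination from reagents, kits and cross-sample carry-over. Because
whole-genome amplification (MDA) amplifies whatever DNA is present,
contaminant phages can masquerade as genuine community members. Negative
controls (NCs): blank extractions and library preparations sequenced
alongside the samples, capture this "negativeome" and allow it to be
subtracted. The subtlety is that a virus *species* detected in both a
sample and an NC is not automatically a contaminant: infants and reagents
can legitimately carry different strains of the same phage species. The
method implemented here therefore distinguishes species-level sharing
(same vOTU) from strain-level identity (near-perfect population ANI), and
removes abundance only where the strain itself is shown to be shared with
an NC.

## The pipeline

1. **vOTU table.** Contigs are dereplicated into species-level viral
   operational taxonomic units at the MIUViG cut-offs: ANI of at least 95%
   over an alignment fraction of at least 85% of the shorter sequence
   (`greedy_cluster()`, both thresholds inclusive). Mapped-read counts per
   vOTU are zeroed when breadth of coverage is strictly below 75% of the
   contig (`breadth_filter()`), transformed to RPKM
   (count / kb of contig / million mapped reads, `to_rpkm()`), and vOTUs
   are dropped when shorter than 1000 bp, when they have strictly fewer
   viral than host genes, or when flagged as plasmids (`qc_filter_votus()`).
2. **Strain comparison.** Per sample and vOTU, an allele profile is built
   from the pileup with a minimum coverage of 1 (`build_allele_profile()`):
   every base observed at a covered position is an allele, and the modal
   base is the consensus. For two samples carrying the same vOTU, the
   mutually covered positions are compared (`compare_strains()`): a
   position is a popANI difference only when the two allele sets are
   disjoint, and a conANI difference when the consensus bases differ, so
   popANI ≥ conANI always. Strains are *shared* when popANI ≥ 99.999%
   over the compared region (`is_shared_strain()`); for exploratory
   analyses and trees at least 75% of the genome must be mutually covered,
   while decontamination waives the fraction requirement so that shallowly
   sequenced NCs still count.
3. **Decontamination.** The negativeome is the set of (vOTU, study) pairs
   with nonzero abundance in at least one of the study's NCs
   (`build_negativeome()`). Strain-level decontamination
   (`strain_decontaminate()`) zeroes a sample's RPKM for a vOTU only when
   the sample's strain is identical to an NC strain of the same study;
   species-level decontamination (`species_decontaminate()`) zeroes every
   own-study negativeome vOTU regardless of strain. Strain-level removals
   are by construction a subset of species-level removals, so per-sample
   richness after strain-level cleaning can never be below the
   species-level result — the quantitative form of the claim that
   strain-aware cleaning preserves resident ecology.
4. **Estimation without internal NCs.** Against an external negativeome
   catalog (leave-one-study-out scope), two per-sample metrics are
   computed: the percentage of detected vOTUs present in other studies'
   NC entries (`estimate_by_votu_sharing()`), and the percentage of reads
   on catalog contigs with breadth strictly greater than 50% or 75%
   (`estimate_by_read_mapping()`). The vOTU-sharing metric is the
   recommended estimator; the read-mapping metric is retained but flagged
   as weaker because spurious and multimapped alignments inflate it.
   `concordance()` reports their study-wise Spearman correlation against
   the internal strain-sharing metric.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `ani_min` / `af_min` | 95 / 85 | % | species-level dereplication cut-offs (inclusive) |
| `breadth_min` | 0.75 | fraction | count retained iff breadth ≥ 0.75 (strict "less than" zeroing) |
| `min_length` | 1000 | bp | minimum vOTU representative length |
| `min_cov` | 1 | reads | minimum depth for a covered position |
| `popani_min` | 99.999 | % | strain-identity threshold, inclusive |
| `min_fraction` | 0.75 | fraction | minimum genome fraction compared (analysis mode only) |
| `linkage` | complete | — | agglomeration for 1 − popANI trees |

All are consolidated in `run_config()` and serializable to YAML.

## Numerical and design choices

* **Threshold inclusivity and floating point.** Strain identity is decided
  on the computed popANI percentage with an absolute guard of 1e-9
  percentage points, so the exact boundary case — one disjoint-allele
  difference over 100,000 compared positions, popANI = 99.999 — is
  accepted regardless of binary rounding of the printed threshold, while
  two differences (99.998) are rejected. Difference counts and compared
  totals are kept as integers end to end.
* **Consensus tie-break.** At min_cov 1, depth ties are common; the modal
  base is resolved lexicographically (A < C < G < T). This is a
  documented convention, deterministic and symmetric across samples.
* **ANI dialect.** Per contig pair, ANI is the alignment-length-weighted
  mean of per-record identity without overlap trimming; the alignment
  fraction merges overlapping aligned intervals projected on the shorter
  sequence before taking the union. Greedy clustering scans contigs by
  length descending with id-ascending tie-break, so representatives are
  deterministic and always the longest member. These follow common
  practice for ANI-based dereplication; the upstream tools that inspired
  the cut-offs do not pin these details, so they are package conventions.
* **Internal alignment.** `align_pair()` performs Smith–Waterman local
  alignment (match +1, mismatch −1, gap open 5, extend 2) on both strands
  and reports the best alignment per strand. A single best local alignment
  per strand is sufficient at the scale this package targets; externally
  produced 12-column alignment tables can be substituted anywhere.
* **RPKM denominator.** "Per million reads mapped" uses the per-sample
  mapped-read total *before* breadth zeroing: the breadth filter corrects
  the numerator's spurious assignments, not the library's mapping depth.
  Callers can pass their own `mapped_total` to adopt the other convention.
* **Trees.** Hierarchical clustering on d = 1 − popANI/100 uses
  `stats::hclust()` with complete linkage by default (the general-purpose
  default of the clustering routine this mirrors), converted to an
  ultrametric phylogeny via `ape::as.phylo()`. Pairs excluded by the 75%
  comparable-fraction rule are never imputed; an incomplete distance
  matrix is a hard error listing the missing pairs, and callers restrict
  the leaf set instead.
* **Missing strain comparisons** (e.g. no pileup for an NC) degrade to
  "not promoted" with a warning: without evidence of identity, abundance
  is not removed.
* **Permutation test.** The rank-sum statistic is permuted with the +1
  correction, so p ∈ [1/(n_perm+1), 1] and a fixed seed gives bit-identical
  results. Quantiles everywhere are linear-interpolation (type 7).
* **"% abundance shared"** is the per-sample sum of relative RPKM shares
  of shared vOTUs; presence is nonzero RPKM after QC. Both are
  package-level definitions of quantities that are reported downstream
  without a universal formula.

## The synthetic generator

`simulate_study()` emulates the statistical structure the method assumes,
not any particular cohort: several studies, each with biological samples
and NCs; a global "kitome" pool of contaminant vOTUs from which each
study's NCs draw (creating the partial cross-study overlap that external
estimation relies on); contaminated samples receiving the NC strain
*identically*; resident strains of the same species diverged by 50–200
SNPs; and log-normal contaminant abundance shares with median 1%,
reflecting the long-tailed contamination loads reported for low-biomass
viromes. Infant richness is log-normal with median 8 vOTUs against a
50-vOTU pool — a deliberate scale-down (by roughly a factor of 25) of the
published infant-virome richness distribution (median ≈ 230, IQR 64–594),
keeping its skew while making full test runs take seconds. Mothers get a
higher median (15) and NC content is sparser than samples, mirroring the
low-biomass observation that NCs typically carry fewer viruses.

Pileups are error-free with full coverage by default so that boundary
properties (planted SNP counts, exact popANI values) are testable without
tolerance; coverage gaps (`gap_fraction`) and per-base errors
(`error_rate`) are opt-in for robustness checks. `simulate_profiles()`
builds allele profiles directly from the truth labels on the error-free
path; `simulate_pileups()` materializes the tabular pileup and is verified
to yield identical profiles.

What the generator does *not* model — and what passing tests therefore do
not establish about real data: amplification bias, assembly artefacts and
chimeras, shared ancestry between resident and contaminant strains at
popANI levels near the threshold, index hopping, RNA viruses, and
compositional noise in read counts. Recovery of planted contaminants with
sensitivity 1 shows the decision logic is exact under the model's
assumptions, not that real contamination is always this separable.

## Problem sizes used in verification

The default simulated design is 3 studies × (12 samples + 2 NCs) over 50
vOTUs of 10–15 kb. The test suite runs the planted-contaminant recovery
over 20 seeds, the strain-vs-species ordering over 100 seeds, the popANI
brute-force oracle over 200 random profile pairs up to 20 kb, the
clustering oracle over 100 random instances, permutation-test calibration
over 1000 null replicates at n = 20/20 with 2000 permutations, and the
estimator-sign check over 100 seeds. These sizes were chosen to give
stable Monte-Carlo estimates while keeping a full run in minutes on one
core.

## Limitations

* Decontamination is binary zeroing, as in the source method; partial
  abundance correction and prevalence-model approaches (decontam-style)
  are out of scope.
* Strain comparison requires pileups; samples without mapped reads over a
  shared vOTU cannot be tested for identity and are conservatively left
  untouched.
* The internal aligner targets desk-scale inputs (up to a few hundred
  contigs); corpus-scale dereplication should import alignments from a
  dedicated search tool through `read_alignments()`.
* Contamination estimates against an external catalog are covariates for
  downstream modelling (`attach_estimates()`); the package deliberately
  stops short of fitting correction models.
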