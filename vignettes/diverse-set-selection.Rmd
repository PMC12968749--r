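---
title: "Diverse-set selection for SNP-genotyped germplasm collections"
author: "divset package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diverse-set selection for SNP-genotyped germplasm collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large genebank collections of selfing crops carry substantial redundancy:
the same line deposited several times under different names, near-isogenic
derivatives, and locally duplicated landraces. A researcher who can grow a
few dozen to a few hundred accessions wants a *diverse set* (DS): a subset
that keeps as much of the collection's allelic diversity as possible while
avoiding genetically identical entries. divset implements the stratified
workflow used for such collections — genome-wide identity-by-state (IBS)
distances, clustering on genetic similarity, one pick per cluster — together
with the evaluation machinery to show what a subset retains, and a
simulator so the whole pipeline is testable without any external dataset.

## The distance model

For accessions $i$ and $j$ genotyped at biallelic SNPs, the distance is

$$d_{ij} = \frac{\sum_l g_{ij,l}}{N_{ij}},$$

where the per-locus difference $g$ is 0 for identical homozygotes, 1 for
opposite homozygotes, 0.5 for a heterozygote against a homozygote, and 1 for
two heterozygotes, and $N_{ij}$ counts the loci where both calls are
non-missing; a locus missing in either accession contributes to neither the
numerator nor $N_{ij}$. A pair sharing no non-missing locus has no defined
distance and is reported as an error rather than silently imputed.

The heterozygote-vs-heterozygote weight deserves a note. Under *genotypic
identity* two heterozygotes at a biallelic locus carry the same two alleles,
so one could equally argue for $g = 0$; classic IBS allele-sharing (e.g. the
PLINK `--genome` DST statistic) takes that view. divset's default follows
the convention above ($g = 1$) and exposes `het_het = 0` as an explicit
alternative in `pairwise_distance()`; no intent is guessed. All reported
behaviour is otherwise identical between the two modes, and distances are
invariant to which allele is labelled 0 or 2 at any locus.

An important consequence of the default: *an exact duplicate pair sharing a
heterozygous call does not sit at distance 0.* In a selfing crop this
matters little because processed array data carry very few heterozygous
calls, but it is why the simulator's default residual heterozygosity is
tiny (see below).

## Redundancy groups

Accessions are joined by an edge wherever similarity $1 - d$ strictly
exceeds a threshold (default 0.999, i.e. ">99.9% identity") and the
connected components of size two or more are the redundancy groups. Single
linkage is used deliberately: it is the only linkage under which "similar to
at least one other accession above the threshold" is exactly equivalent to
group membership, so the reported group count, the per-group sizes and the
count of accessions 100% identical to another accession are all mutually
consistent.

## Clustering

`kmeans_cluster()` partitions accessions by iterative reassignment on
genetic similarity. Each accession's feature vector is its row of the
similarity matrix, so a cluster center is the vector of average similarities
between the cluster's members and every accession, and "assign each
accession to the center with the highest average similarity" is a single
indexed lookup. Numerical choices, all deterministic given the seed:

* **Initialization** — seeded farthest-point: the first center is a
  uniformly drawn accession, each next center the accession farthest from
  its nearest chosen center. This spreads initial centers across the
  collection's structure and makes duplicate-heavy regions claim one
  center, not several.
* **Ties** — broken toward the lowest cluster index, making label vectors
  reproducible across platforms.
* **Stopping** — iteration ends when no label changes or after `max_iter`
  (default 100) passes. A pass that would *increase* the mean
  within-cluster dissimilarity is rejected and iteration stops with the
  previous labels; this guarantees the recorded objective trace is
  non-increasing, which reassignment on average similarity does not
  guarantee by itself.
* **Zero-distance merge** — after convergence, accessions at distance
  exactly 0 are forced into one label; any cluster emptied by the merge is
  reseeded with the distinct-genotype unit least similar to its current
  center. When `k` exceeds the number of distinct genotypes the merge is
  impossible without emptying clusters, so it is skipped with a warning.
* **Empty clusters** during iteration are refilled with the
  weakest-affiliated member of a multi-member cluster, so every label is
  always in use.

## Selection

Maturity-group (MG) windows follow the adjacency rule of photoperiod
adaptation: a target MG pools accessions from itself and its immediate
neighbours, clipped at the `000` and `X` boundaries (`000` → {000, 00},
`00` → {000, 00, 0}, ..., `X` → {IX, X}). `UNDETERMINED` accessions join
whole-collection columns but never an MG window.

`build_diverse_set()` takes one accession per cluster: the user-preferred
member when present and not excluded, otherwise a seeded uniform draw among
non-excluded, seed-available members. A cluster with no eligible member is
reported *exhausted* — the set shrinks rather than borrowing a second pick
from another cluster, preserving the one-per-cluster guarantee. Later
failures (seed did not germinate) are handled by `replace_picks()`, which
re-draws within the same cluster and marks the pick `replacement`.
`export_selector_table()` writes the spreadsheet-style table — one
cluster-label column per (scope, k) — that lets a user make those choices
by sorting columns.

## Evaluation

A SNP is *retained* by a subset when at least two distinct alleles are
observed among the subset's non-missing calls; a heterozygous call
contributes both alleles, because allele capture — not genotype variety —
is what conservation of diversity means. Two denominator conventions are
explicit because both are standard: the full panel SNP count
(whole-collection reporting) and the count of SNPs polymorphic within a
reference set (MG-scoped reporting, where the window's own polymorphic SNPs
are the natural 100%).

`compare_ds_rs()` clusters once per sample size, draws independently seeded
replicate diverse sets and random sets (default 10 per arm), and reports
per-arm mean/min/max/SD plus a two-sample Welch t-test. Welch's unpaired
test was chosen because the two arms are independent draws with no pairing
structure and often unequal variances at 10 replicates; when both arms are
degenerate-constant the comparison is reported as non-significant rather
than undefined. Distance histograms use a dedicated bin for exact zeros
(identical accessions are a category of their own, not merely "small
distance") and lower-open/upper-closed interval bins so labels such as
"0–0.05 / 0.05–0.10" never double-count an edge value. The retention
plateau is defined as the smallest sample size after which every later
consecutive step gains less than `epsilon` percentage points; the last
point never qualifies vacuously, so a still-climbing curve has no plateau.

## The simulator

`simulate_collection()` emulates the features of a structured, redundant
selfing-crop collection that drive every behaviour above:

* **Allele frequencies** — ancestral frequencies uniform on
  `[maf_floor, 1 - maf_floor]`; each of `n_subpops` subpopulations draws
  per-locus frequencies from a Balding–Nichols beta around the ancestral
  value with spread set by `fst`. One interpretable knob controls how
  separable the subpopulations are and how many subpopulation-private
  alleles exist.
* **Skewed strata** — subpopulation sizes decay geometrically (largest to
  smallest roughly 20:1), as real genebank strata do. This matters: the
  small strata carry the rare private alleles that random sets miss and
  stratified sets capture, which is precisely the regime in which
  diverse-set selection earns its keep. With balanced strata and common
  alleles a 5,000-SNP panel saturates and the two methods are
  indistinguishable.
* **Duplicates** — `duplicate_fraction` is the share of accessions that
  belong to duplicate groups (group heads plus their copies). Group sizes
  are geometric with minimum 2 — many pairs, few large groups — and each
  copy descends from a random earlier member of its group with per-locus
  re-randomization probability `near_dup_error_rate`, so group-size and
  within-group divergence profiles are skewed rather than clique-like.
* **Heterozygosity and missingness** — residual heterozygosity
  `het_rate = 1e-4` per call and `missing_rate = 0.02`. The het default is
  deliberately tiny: under the het/het = 1 distance rule a shared
  heterozygous call keeps even exact duplicates off distance 0, and
  processed selfing-crop array data — where thousands of accession pairs
  show 100% identity — are only consistent with heterozygous calls being
  effectively absent.
* **Maturity groups** — subpopulations map onto the MG scale with small
  (±1 level, 10%) spillover; duplicates inherit their source's MG, so MG
  structure correlates with genetic structure as it does in practice.

Defaults (500 accessions, 5,000 SNPs, 10 subpopulations, `fst = 0.25`,
`duplicate_fraction = 0.25`, `maf_floor = 0.005`) were chosen once to place
the collection in that regime — random sets visibly losing rare alleles at
sample sizes 25–50, diverse sets significantly ahead, the gap closing as
sample size grows and vanishing on a weakly structured duplicate-free
collection — and are frozen as the package's study conditions.

What the simulator does **not** emulate: linkage disequilibrium and
haplotype structure (loci are independent given subpopulation), pedigree
relatedness between distinct accessions, hierarchical population structure
below the subpopulation level, genotyping batch effects, and
non-random missingness. Passing tests therefore demonstrate the method's
behaviour under idealized structure and redundancy, not its performance on
any particular real collection.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at the simulator's default scale
(500 × 5,000 for the selection-vs-random comparisons; 500 × 20,000 for the
SNP-subset consistency check; 10 independent simulator seeds for the
redundancy-share and zero-distance-pair properties) and at small crafted
scales wherever an exact oracle is asserted. These sizes were chosen as the
smallest at which the structural effects are unambiguous.

## Known limitations

* Only biallelic markers and the PLINK 1 dialects are read; multi-allelic
  sites, phased data, VCF and PGEN are out of scope.
* The distance matrix is dense: collections beyond a few thousand
  accessions need blockwise handling that divset does not attempt.
* Clustering is the reassignment heuristic described above, not a global
  optimizer; composition of the resulting diverse sets is robust in
  practice but no optimality is claimed.
* The significance machinery assumes independent replicates; it makes no
  multiple-testing adjustment across sample sizes.
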