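---
title: "Inferring ancestral nematode linkage groups and telomere-end structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancestral nematode linkage groups and telomere-end structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nigontools)
```

## The problem

Rhabditid nematode karyotypes are remarkably stable (most species have
n = 6 holocentric chromosomes) even though local gene order is scrambled
between species. The durable units are not chromosomes but *ancestral
linkage groups* — sets of orthologous loci that have travelled together
through hundreds of millions of years of fusions and fissions. In
nematodes these are the seven Nigon elements (A–E, N and X). `nigontools`
implements an objective pipeline that recovers such elements from
chromosome-level assemblies, paints extant chromosomes by element content,
and — as a separate toolkit — characterises the dual telomere-repeat
addition sites that distinguish short- and long-form chromosome ends in
telomere-to-telomere assemblies.

## The colocation model

The substrate is the **ortholog × species chromosomal allocation matrix**:
for each fuzzy single-copy ortholog (exactly one copy in at least
`min_single_copy_species` of the roster, default 12 of 15) and each
species, the chromosome on which its unique copy lies, or missing when the
species has zero or multiple copies. Chromosome labels are opaque strings;
co-assembled scaffolds can be merged into one chromosome unit through an
alias table before collation.

Two orthologs $i, j$ placed in $n_i$ and $n_j$ species, co-chromosomal in
$a$ species, have Dice colocation similarity

$$ s(i,j) \;=\; \frac{2a}{n_i + n_j}, \qquad d(i,j) = 1 - s(i,j). $$

A pair on the same chromosome in every species scores 1; a pair never
co-chromosomal scores 0. Missing placements shrink the denominator rather
than counting as disagreement, which is what makes the filter "fuzzy"
single-copy tolerant.

The distance matrix is clustered by **k-medoids**. `nigon_pam()` is
classic PAM: a greedy cost-minimising BUILD phase followed by
best-improvement SWAP until no swap lowers the summed distance to
medoids. All ties — the initial medoid, BUILD candidates, SWAP
candidates, and point assignment — break to the lowest index, so the
result is fully deterministic. `nigon_clara()` is the subsampling variant:
PAM on each of `n_subsamples` (default 5) independent subsamples of
`fraction` (default 10%) of the loci, with every candidate medoid set
scored by its cost over *all* loci and the cheapest kept. With one
subsample at fraction 1 it reduces exactly to PAM.

The number of clusters is selected by **average silhouette width**,
$s(i) = (b_i - a_i)/\max(a_i, b_i)$, scanned over k = 1..10. A silhouette
is undefined at k = 1, which is reported `NA` and excluded from the
argmax; ties go to the smaller k; singleton clusters score 0.

Clusters become **elements** under two thresholds: an ortholog is labeled
only if at least `min_agree_taxa` (default 7) species place it on the same
chromosome as its cluster's medoid, and only clusters of more than 20
orthologs (default `min_cluster_size = 21`) receive labels. Agreement is
defined against the medoid because the medoid is the clustering
objective's own representative and makes the count deterministic; an
alternative majority-of-members definition is available via
`agreement = "majority"`. Cluster labels come from anchor evidence —
anchor ortholog lists per element and/or a reference-species chromosome
map — by majority vote, and the mapping must be injective; unresolved
clusters get synthetic labels `U1, U2, ...`. A reference-species map alone
cannot split elements that are fused in the reference (e.g. the two
X-resident elements of *C. elegans*), which is why anchor gene lists take
precedence for those.

Downstream, `paint_chromosomes()` counts labeled loci in non-overlapping
0.5 Mb windows (1-based inclusive, binned by start coordinate, final
window short), `project_labels_rbh()` transfers labels to further genomes
through reciprocal best BLAST hits (both e-values strictly below 1e-6;
ties broken by bit score, then the protein on the longer scaffold, then
lexicographically), and `neighborhood_divergence()` contrasts inter-gene
distances of consecutive reference orthologs against their separation in
a query genome (pairs more than 50 kb apart in the reference are excluded
and counted; Spearman p-values use the exact distribution below 20 pairs
and the t-approximation above).

## What the simulator emulates — and what it does not

`nigon_preset_figure6()` encodes, as terminal states, the documented
element compositions of the ten chromosomally assembled species used for
element inference (the N+X X chromosome of *C. elegans* and
*H. contortus*, the E+X X of *O. tipulae*, the A+N chromosome I of
*P. pacificus*, the B+D+X X chromosomes of *S. ratti* and
*S. carpocapsae*, the C+X X of *B. xylophilus*, the D+X+N X of
*B. malayi*, the A+N OM1 of *O. volvulus*, and the blocky A/C/N autosome
mosaic of *A. rhodensis*). Where published panels do not pin block
boundaries (the *A. rhodensis* and *S. ratti* mosaics), the boundaries are
fixed package choices at one-half of each element. *M. hapla*, whose real
assembly yielded no definitive assignments, is an optional eleventh
species intended for high-noise stress tests. `simulate_history()`
additionally evolves arbitrary scripted histories (fusion, fission at a
gene-rank fraction, translocation, shuffle) pre-order along any species
tree, for hypothesis-driven tests.

`realize_genomes()` instantiates `genes_per_element` gene stubs per
element (default 100, giving the ~700-locus matrices used throughout the
tests) with per-species gene loss, duplication, intra-chromosomal order
shuffling, and optional spacing jitter. `simulate_allocation_matrix()`
adds *placement noise*: each cell is reassigned to a random wrong
chromosome of its species with probability `noise`. The default study
condition used in the acceptance analyses is 100 genes per element and 5%
placement noise — the kind of low-level error that orthology mistakes and
assembly misjoins contribute in real data.

The simulator makes no attempt at sequence-level realism: gene stubs have
no sequence, there is no indel or repeat model, and chromosome ends are
simulated separately. Consequently, passing tests demonstrate that the
inference machinery recovers a known truth under controlled noise — they
do not certify performance on real annotations, where missingness is
structured (clade-biased gene loss) rather than uniform.

One behaviour worth knowing: with *literally zero* placement noise, the
silhouette criterion can prefer more than seven clusters, splitting
elements along recent fission boundaries — those fragments are genuinely
distinct colocation patterns with zero internal distance, so the split
costs nothing and gains separation. Any realistic noise level (the 5%
default included) restores k = 7. This is a property of the silhouette
statistic, not of the clustering, and mirrors why real analyses of this
kind operate on noisy biological matrices.

```{r pipeline, eval = FALSE}
h <- nigon_preset_figure6()
M <- simulate_allocation_matrix(h, genes_per_element = 100,
                                noise = 0.05, seed = 1)
dd <- dice_similarity(M)
scan <- silhouette_scan(dd$distance, k_range = 1:10, seed = 1)
scan$best_k   # 7
truth <- attr(M, "truth")
asn <- assign_elements(scan$best_fit, M,
                       anchors = list(genes = lapply(
                         split(names(truth), truth), head, 3)))
```

## The telomere-end model

Telomere-to-telomere nanopore assemblies of *O. tipulae* show **two**
telomere-repeat (TTAGGC) addition sites at every chromosome end: an
internal site supported by ~80% of long reads (the short-form chromosome)
and an external site supported by the ~20% minority (the long form),
bounding a subtelomeric extension present only in the long form.

`simulate_end_reads()` builds a left-arm reference
`[telomere][extension][core]` and draws each read as one chromosome copy:
short-form with probability `short_form_fraction` (default 0.8), its
telomeric tail soft-clipped at the internal site (the first core base);
long-form otherwise, clipped at the external site (the first extension
base). Substitution errors apply to the unique portion; tails stay
error-free unless `noisy_tails = TRUE`, so site detection has an exact
mode. `detect_addition_sites()` inverts this from any SAM: a read
contributes a candidate site when its soft clip is telomeric — at least 3
motif copies, and at most a 10% mismatch fraction against the best-phase
tandem repeat of the motif or its reverse complement — and its aligned
block anchors at least 50 bp of reference. Candidate coordinates cluster
within 5 bp; clusters with at least 5 supporting reads are reported with
support fractions over all telomere-bearing reads on the arm, and on arms
with several sites the one nearest the chromosome midpoint is designated
internal. Sites are reported as the first (left arm) or last (right arm)
aligned base adjacent to the clipped repeat, so in error-free simulations
detected positions equal planted positions exactly.

Two coordinate-arithmetic helpers mirror published chromosome-end tables,
with an **arm-dependent convention** (prominently: left arms are
inclusive, right arms are plain differences — the only convention that
reproduces every row of the *O. tipulae* table bundled as
`otipulae_telomere_extensions()`):

* left arm: `extension_span = extension_start_site −
  external_addition_site + 1`; `external_repeat_span =
  external_addition_site − 1`;
* right arm: `extension_span = extension_start_site −
  external_addition_site`; the external repeat span requires the full
  chromosome length and is taken from input.

Collapsed-repeat arithmetic completes the toolkit:
`size_collapsed_repeat_gap(111, 6848)` sizes the N-run gap standing in for
111 missing copies of the 6.8-kb rRNA cistron unit (760,128 N), and
`estimate_repeat_copies()` recovers total copy number as the rounded
ratio of mean read depth over the collapsed repeat to mean background
depth (117× in the bundled preset, `nigon_preset_rrna()`).

## Numerical choices and degenerate inputs

* PAM/CLARA ties break to the lowest index everywhere; SWAP accepts a
  swap only if it improves cost by more than 1e-12, preventing cycling on
  tied configurations. Distance matrices must be symmetric to 1e-8 with a
  zero diagonal.
* Silhouette at k = 1 is `NA`; singleton clusters score 0; equal-distance
  data score ~0 at every k.
* Orthologs placed in no species are excluded from Dice with a warning;
  zero-background depth, degenerate arms (internal = external site),
  events naming absent chromosomes, sub-k subsamples and malformed BLAST
  lines are hard errors.
* Windows are 1-based inclusive; loci bin by start coordinate (midpoint
  binning would move a locus at most one window and is not offered).
* Fission breakpoints are fractions of gene rank, not bp, because the
  matrix stage only ever sees gene-to-chromosome membership.

## Problem sizes used in tests and analyses

The test-suite and the acceptance analyses run at deliberately desk-scale
sizes chosen to exercise every code path with comfortable statistical
margins: 700-locus allocation matrices (100 genes per element) for model
selection, 1,000 end-spanning reads for the two-form mixture (binomial SE
≈ 1.3 percentage points), 100-kb depth tracks for copy-number recovery,
and exhaustive k-medoids enumeration up to n = 12. The published analyses
this package's methods address operate on 2,000–3,500 loci and full
read sets; the algorithms are the same and scale quadratically in loci
(Dice and silhouette) — about a minute for 3,000 loci.

## Known limitations

* The fuzzy single-copy filter implements only the exactly-one-in-≥-t
  rule; upstream isoform selection (one protein per gene) is assumed
  done.
* The simulator's missingness is uniform per cell, not phylogenetically
  structured; recovery numbers on it are best-case.
* `simulate_end_reads()` emits left-arm ends; right-arm detection is
  exercised against hand-built alignments.
* Addition-site detection trusts the aligner's soft clips; it does not
  re-align clipped tails, so reference errors at the clip boundary shift
  sites by their own offset.
* The optional 2-D embedding some analyses use for visualisation is out
  of scope here; clustering and assignment never depend on it.
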