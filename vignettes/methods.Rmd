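---
title: "Models and methods behind panmito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panmito}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmito)
```

panmito implements the analysis chain of a control-region mtDNA
phylogeography survey: variant notation, motif-based haplogroup
classification, regional frequency tables, median-joining networks,
coalescence dating, diversity summaries, and pedigree-based
deduplication, together with a seeded generator of synthetic cohorts
that makes the whole chain testable without restricted sample data.
This vignette records the models, the tunable parameters and their
defaults, the numerical decisions, and the limits of what the synthetic
validation shows.

## Variant notation and coordinates

All variants are named relative to a 16,569-bp reference with 1-based
circular coordinates. Transitions are bare positions (`16360`),
transversions and heteroplasmies carry the derived base (`16182C`,
`152Y`), insertions carry a point index (`309.1C`), deletions a `d`
suffix with an optional span (`106-111d`), and a trailing `@` marks a
back mutation to the reference state. Both hyphen and en-dash are
accepted in spans on input; the canonical serialisation uses the hyphen.
The default sequenced range is the control region, nps 16000–580,
wrapping the origin; closed circular intervals are stored as ordered
pairs with an implicit wrap when start exceeds end.

Indel placement follows the usual mtDNA nomenclature: when
`call_variants()` aligns a genome against the reference, gaps inside
repeats are slid to their 3'-most position before naming. The
convention for C-stretch insertions is not universally fixed; 3'-most
placement is assumed throughout.

Three site-filter profiles bundle the exclusion conventions. The
`"network"` profile excludes 16182C, 16183C, 16194C and 16519,
disregards length variation in the C-stretches 303–315 and
16184–16193, and drops insertions, heteroplasmies and deletions —
except the 6-bp deletion at 106–111, which is diagnostic in the A2
sub-clades of interest and is scored as a single character; for the same
reason the 2-bp deletion at 522–523, although parsed and counted by the
general distance when no profile drops it, is removed by the network
profile. The `"stats"` profile keeps substitutions only, the convention
for diversity summaries computed "excluding gaps and ambiguous sites".
Reversion tokens denote the reference state and never contribute to
distances.

## Haplogroup classification

A `haplogroup_tree` places a mutation motif on each edge; the root
(either the reference itself or an interior haplogroup such as A2)
carries none. For a sample and a candidate node, every motif entry on
the root-to-node path contributes an expectation: present, or — after a
reversion — absent. Three rules make the procedure behave sensibly on
partial data:

* Entries outside the sample's sequenced range are *unobservable*: they
  are excluded from both the matched and the expected counts, so a
  control-region sample is never penalised for coding-region motif
  entries (e.g. the A2af-defining 5460).
* The call may only descend through edges with *positive evidence*: at
  least one observable, non-reversion entry present in the sample. An
  edge whose observable content is only a reversion (such as the 64
  back mutation defining a major sub-branch) or nothing at all cannot
  by itself pull a sample deeper; absence of evidence is not treated as
  evidence of membership.
* The call is the deepest node maximising matched/expected, tie-broken
  by depth, then fewer unexplained private mutations, then label; calls
  scoring below the `demote_below` threshold (default 1: motif-exact)
  fall back toward the parent.

The bundled A2 fixture tree encodes the sub-clades used throughout the
package's examples: A2af (73@, 106–111d, 5460, 16360), A2af1 (64@,
6794, 7960) with A2af1a (89) and A2af1b (11482), and A2ad (16175,
16300). The complete coding-region motif of A2ad is not part of the
fixture; only its control-region pair is encoded, which is sufficient
for control-region classification but would under-specify a
whole-genome tree.

Frequency tables collapse sub-haplogroup labels onto major-clade
columns by longest prefix and aggregate per collection region, with
marginal rows for provinces, comarcas and the grand total, and
continent-level groups (Native American = A2+B2+C1+D1, Africa = L0–L3,
West Eurasia = HV+JT+N1'2+U, East Asia = G). The chi-square test of
geographic structure is Pearson's, without continuity correction.

## Median-joining networks

`median_joining()` operates on a binary character matrix (identical
haplotypes merged with multiplicities; per-character positive integer
weights, default 1 for every retained character including 106–111d).
Each round:

1. builds the minimum spanning network — every edge whose weighted
   Hamming distance is within `epsilon` of the bottleneck (minimax-path)
   distance between its endpoints, computed by single-linkage merging of
   MST edges;
2. takes every mutually linked triplet (triangle) and forms its
   quasi-median, the per-character majority state; among new candidates
   only those within `epsilon` of the minimal connection cost (summed
   distance to the generating triplet) are added, the staged addition of
   the published algorithm;
3. prunes sequenceless median vectors with fewer than three links,

iterating to a fixpoint (`epsilon = 0` by default, the common choice
when the tolerance is not stated). A final cleanup removes median
vectors that are not exactly *between* some pair of observed haplotypes
— such vectors can never be threaded into a spanning tree of the
observed data at no extra cost — followed by the degree rule again.
The tests verify, against an independent MST construction, that the
finished network always realises at least one minimum spanning tree of
the observed haplotypes, that spanning the observed haplotypes through
medians never costs more than their own MST, and that `epsilon = 0`
node patterns persist at wider tolerances. The literal containment of
*every* MST is not asserted: when several MSTs tie, the network
guarantees one of them.

Node ages over a network (`network_node_ages()`) use the
multiplicity-weighted mean shortest-path distance from a chosen root
node to every observed haplotype. Where several equally short paths
exist through a reticulation, the length — the only quantity used — is
unaffected. The network route carries no genealogy, so no heuristic
standard error is reported there; use `rho_sigma()` on a resolved tree
for σ.

## Coalescence dating

For a rooted genealogy with edge lengths in mutations, `rho_sigma()`
computes ρ, the mean root-to-tip mutational distance (identical sampled
sequences count once each; represent frequency by duplicated tips), and
the heuristic standard error σ² = Σ_e l_e (n_e/N)², summing over edges
with n_e sampled tips below the edge. A star genealogy is represented
as a basal polytomy; the basal node of the `phylo` object is taken as
the clade root. (The `phylo` encoding cannot distinguish a deliberately
unrooted tree from a rooted polytomy, so rootedness of the basal node
is a documented convention rather than a checked error.)

Ages in years are ρ times a per-mutation rate from a `clock_config`.
The whole-molecule calibration — one mutation per 3,624 years — is the
only hard-coded rate. Control-region calibrations differ between
published clocks and the package deliberately does not pick one: the
config ships a placeholder of 9,058 years per control-region mutation,
flagged `confirmed = FALSE`, which is of the right order for published
control-region clocks but must be confirmed by the user before
control-region ages are quoted.

`ml_branch_lengths()` fits branch lengths on a fixed topology under
HKY85 with empirical base frequencies, gamma-distributed among-site
rates approximated by 32 equal-probability categories (category rate =
within-category mean), and three partitions — HVS-I (16051–16400),
HVS-II (68–263) and the remainder — with free per-partition rate
multipliers normalised to a site-weighted mean of 1 (the linking is not
dictated by the partition scheme itself; free multipliers with a mean
constraint is the common usage of the reference ML software). Indels
and the positions 16182, 16183, 16194 and 16519 are excluded. The
likelihood is computed by Felsenstein pruning; optimisation is bounded
quasi-Newton (L-BFGS-B) on log-transformed parameters to a relative
log-likelihood tolerance of 1e-8, with non-convergence flagged on the
returned object rather than silently accepted. Correctness anchors in
the tests: exhaustive summation over internal states on small trees
(1e-10), the Jukes–Cantor closed form in the κ = 1/equal-frequency
limit (1e-6), agreement with an independent phylogenetics package, and
parameter recovery on simulated alignments. `ml_age()` converts the
mean root-to-tip distance (substitutions/site × genome length) to years
with the whole-molecule clock.

## Diversity

`diversity_stats()` works at the level of filtered variant sets: k is
the mean pairwise symmetric-difference count (computed exactly from
per-variant carrier counts, since a variant carried by c of n samples
separates c(n−c) pairs), π = k/L where L is the number of compared
sites — the covered range minus every column affected by an indel or a
heteroplasmic ambiguity anywhere in the cohort, derived from the data
rather than hard-coded — S counts positions whose variant pattern
actually segregates within the cohort, and Hd uses the n/(n−1)
correction. Indels are excluded from S, π and k by default, the
DnaSP-style convention; the filter is configurable.

## Pedigree deduplication

Relatedness clusters (maternally related extended families) are an
input, not an inference — in the original study design they came from a
genealogical database search, not from a described algorithm. One
member per cluster is retained; the retained member is the
lexicographically smallest sample id, a deterministic stand-in for the
study's unstated choice. The pipeline reports its own arithmetic
(input → foreign-TMA removal → dedup → final) and does not force any
particular published totals, whose reconciliation is underdetermined.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes. Per region, haplogroup labels are drawn with the bundled
Panamanian composition — counts recovered from the published regional
frequency percentages (round(pct × n/100) reproduces every row sum and
marginal exactly) — either by exact quota (`mode = "exact"`, the
deterministic composition used for table-reconstruction checks) or
multinomially. Each sample starts from its haplogroup's founding motif
and gains Poisson(age/rate) private transitions at *distinct* random
control-region positions, weighted 5× at the classic hypermutable
sites; the distinctness makes the simulation infinite-sites-like so
mutation counts are exactly Poisson and the ρ estimator can be checked
for unbiasedness without recurrent-mutation bias. Private positions
avoid every motif position of the classification tree, so
classification of a simulated cohort is exact by construction — a
generator design choice (diagnostic sites are a tiny fraction of the
control region) that makes table-reconstruction checks deterministic.

Default clade ages are field-plausible founder ages (Native American
clades 15.5–17 ka, African L clades 50–70 ka, West Eurasian clades
22–45 ka); they are the generator's study conditions, not estimates.
The default cohort adds 149 foreign-TMA samples with haplogroups
typical of their origin area and injects 42 pair and 13 triplet
relatedness clusters whose members share a haplotype; cluster copies
sort after their seed so the deterministic dedup recovers the core
cohort exactly. Generated totals (1350 + 149 + 68 = 1567) follow the
generator's own arithmetic; the original study's corresponding totals
cannot be exactly reconstructed from its printed counts, and no attempt
is made to force them.

What the synthetic cohorts do *not* emulate: recurrent and back
mutation at hypervariable sites (beyond the hotspot weighting of where
mutations land), rate heterogeneity between transitions and
transversions in the control region (all private mutations are
transitions), population structure within regions, coalescent
genealogies deeper than the star approximation, and sequencing or
phasing error. Passing the end-to-end checks therefore demonstrates
the correctness of the pipeline's bookkeeping and estimators under the
stated model — not robustness of the classification to homoplasy in
real data.

`simulate_alignment()` provides the oracle for the ML machinery: sites
evolve independently under HKY85 with the same discrete-gamma and
partition structure the fitter assumes.

## Problem sizes and determinism

All randomness flows from explicit seeds; identical configurations give
bit-identical cohorts, and pipeline reruns write byte-identical
artifacts. The validation suite uses exhaustive enumeration where it
is cheap — all 11,000-odd rooted binary topologies on up to seven
leaves for the ρ/σ oracle, exhaustive internal-state summation on up to
five leaves for the likelihood — and seeded Monte Carlo elsewhere (200
random binary matrices for the network properties; 500 replicates of a
200-lineage star clade at a true age of 23,240 years for the
calibration check, which resolves the estimator's bias to within about
30 years). The default end-to-end cohort is the full 1,567-sample
design; it classifies, tabulates and networks in well under a minute.

## Known limitations

* The classifier is motif-exact by default; it has no probabilistic
  scoring for partially matching haplotypes beyond the demotion
  threshold, and no handling of recurrent mutation across lineages.
* The median-joining implementation targets binary characters (the
  control-region presence/absence encoding); multi-state quasi-medians
  and the reduced-median preprocessing of the original software are out
  of scope, as is graphical layout.
* `ml_branch_lengths()` fits a fixed topology; there is no topology
  search.
* The bundled reference sequence generator produces a random synthetic
  stand-in of the correct length for tests and simulations; analyses of
  real data must supply the actual reference FASTA.
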