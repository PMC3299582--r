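---
title: "Models and methods: maternal admixture from HVS-I haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: maternal admixture from HVS-I haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvsadmix)
```

## The problem

Admixed populations founded by forced or voluntary migration carry, in
their mitochondrial gene pool, a record of where their maternal ancestors
came from. Because mtDNA is matrilineal and non-recombining, every lineage
can be compared directly with candidate source populations. The first
hypervariable segment (HVS-I) of the control region is the marker most
densely sampled across the African literature, so an admixed population
typed for HVS-I can be confronted with region-level aggregates of
published source samples, and the resulting ancestry estimates compared
with documentary records of the migration itself — for Caribbean
populations, the disembarkation registers of the trans-Atlantic slave
trade (a per-decade, per-coast table of which is packaged here; see
`load_disembarkation_table()`).

This package implements that workflow end to end: haplotype parsing and
comparison, haplogroup classification, two admixture estimators,
diversity and demography statistics, an exact test of differentiation,
and a synthetic-data generator with known truth so that the whole chain
is testable without any external download.

## Haplotypes, the reference window, and distance

A haplotype is the set of differences from the revised Cambridge
Reference Sequence (rCRS, NC_012920.1) inside the analysis window,
written in the standard literature notation (`C16223T`, `A16166d`,
`16193.1C`). The default window is rCRS 16024–16365; it is a superset of
the positions commonly reported in HVS-I surveys and is configurable
(`hvs_window()`), since published studies rarely state one uniform
sequenced span.

Two numerical conventions matter:

* **Poly-cytosine tract 16184–16193.** Length variation in this tract is
  a sequencing-unstable homopolymer artefact, so insertions and
  deletions there are dropped at parse time. Substitutions in the tract
  (e.g. `C16184T`, `T16189C`) are genuine characters and are kept.
* **Per-position mismatch counting.** `mismatch_distance()` counts
  positions at which two lineages carry different states; two different
  derived states at one position count one mismatch, not two. Indels
  outside the excluded tract count one each — the common HVS-I
  convention. Under these rules the distance is a true metric on variant
  sets, which the test suite checks by random enumeration.

## Haplogroup assignment and macro-categories

Lineages are assigned by motif matching against a user-replaceable tree
table: each named haplogroup carries a set of diagnostic HVS-I variants,
and a haplotype is scored per haplogroup as

```
score = (motif variants present) − penalty × (motif variants absent)
```

with `penalty = 1` by default. Private variants — positions in no
motif — never change a score, so assignment is robust to the private
mutations that accumulate on every lineage. Ties go to the deeper tree
node, then to the lexicographically first label, and are flagged in the
output. An rCRS-identical haplotype maps to the root label.

The packaged motif table is a deliberately small, curated set for the
macro-clades relevant to sub-Saharan admixture work (L0–L5 clades, U6,
and representative Eurasian/American clades). It is a configuration
artefact, not a phylogeny: full-resolution classification requires
coding-region information and a full reference tree, both outside the
scope of an HVS-I desk analysis, and users with richer tables can load
them with `read_motif_table()`. One consequence of HVS-I-only data is
that haplogroup M (defined by coding-region sites, `C16223T` in HVS-I)
cannot be separated from the L3 paragroup; the default table therefore
carries no bare-M entry, so such lineages classify as L3.

Labels collapse into macro-categories by longest-prefix match
(`collapse_to_category()`): named L clades, two residual buckets
("Other L0'1'2", "Other L3"), U6 kept separate (it re-entered sub-Saharan
Africa long before the Atlantic trade), and a non-L/U6 paragroup for
everything else. L4 is routed to "Other L3" and L5 to "Other L0'1'2" as
the closest coarse placement; the scheme is a YAML file and fully
user-replaceable.

## Admixture estimator 1: multinomial mixture MCMC on profiles

Let `y` be the hybrid population's category counts (total `N`), and
`x_c` the counts of source `c`. The model is

* `y ~ Multinomial(N, q)` with `q = Σ_c m_c p_c`;
* `p_c ~ Dirichlet(x_c + 1)` — source frequencies are treated as
  uncertain, not fixed, so small source samples widen the posterior;
* `m ~ Dirichlet(1, …, 1)` — flat prior on the mixing vector.

Sampling is Metropolis-within-Gibbs: `m` moves by a Gaussian random walk
on the softmax (log-ratio) scale with the Jacobian correction, and each
`p_c` by an independence proposal from its prior, accepted on the
likelihood ratio. Defaults are 50,000 iterations, 10,000 burn-in,
thinning 10, proposal standard deviation 0.3, and a mandatory seed.
Convergence is monitored by split-chain agreement of the posterior
means; a gap above 0.05 triggers a warning and a `converged = FALSE`
flag rather than a silent return. With a single source the estimate is
exactly 1 (the simplex is a point, no chain is run).

Before estimation, hybrid lineages whose macro-category is the non-L/U6
paragroup are removed (`census_and_filter()`): they cannot descend from
the sub-Saharan source pool, and retaining them would force spurious
weight onto whichever source happens to be least unlike them. They stay
in the census percentages, mirroring the usual practice of reporting the
full sample composition alongside the filtered analysis.

## Admixture estimator 2: Bayesian haplotype sharing

The sharing matrix (`build_sharing_matrix()`) records, for each hybrid
lineage `i` and source `c`, the frequency in source `c` of haplotypes
within `m` mismatches of lineage `i` (`m` = 0, 1 or 2). Match sets are
nested in `m` by construction, so every entry is non-decreasing in the
tolerance.

`ancestry_proportions()` turns the matrix into per-source ancestry:
row-normalised weights `w_ic = S_ic / Σ_c' S_ic'`, averaged over
lineages. Lineages matching no source are excluded and counted in an
`unmatched` statistic — spreading them uniformly would manufacture
ancestry signal out of absence of evidence. The 95% interval comes from
posterior simulation (2,000 replicates by default): source haplotype
frequencies redrawn from `Dirichlet(counts + 1)`, hybrid lineages
bootstrap-resampled, the estimator recomputed, and percentiles taken.
This interval construction is a declared choice of this package — the
sharing literature does not fix one — and is recorded in the output
metadata together with the seed.

The two estimators answer subtly different questions (category-level
composition vs haplotype-level identity) and their disagreement is
informative: sharing estimates are flatter whenever haplotypes cross
category boundaries or are pan-regional.

## Diversity, demography, and differentiation

`diversity_summary()` reports the Arlequin-style battery: distinct
haplotypes `k`, segregating sites `S`, mean pairwise differences `θπ`
with the total-variance SD of Tajima (1983) — chosen because "θπ ± SD"
in the survey literature almost always means that estimator — and
Tajima's D from the 1989 constants, with a two-sided p-value from the
beta approximation and conventional stars at 0.05/0.01. When `S = 0`, D
is reported as undefined with an explicit flag, never as 0.

The mismatch distribution (`mismatch_distribution()`) is fitted to the
Rogers–Harpending sudden-expansion expectation `F_j(τ, θ0, θ1)` (finite
post-expansion `θ1`) by bounded least squares from multiple seeded
restarts; the fit minimises `SSD = Σ (x_j − F_j)²`. Significance of SSD
and of Harpending's raggedness index uses a parametric bootstrap:
replicate histograms are drawn as multinomials of all `n(n−1)/2` pairs
from the fitted expectation and refitted. Pairs are not independent, so
this bootstrap is somewhat anti-conservative relative to coalescent
resampling; it is cheap, fully seeded, and adequate for flagging gross
misfit, which is how the statistics are used here.

The exact test of population differentiation is the Raymond–Rousset
probability test on category-count contingency tables: the p-value is
the total hypergeometric probability of all tables with the observed
margins no more probable than the observed one. Small universes are
enumerated exactly (the test suite cross-checks against
`stats::fisher.test`); larger ones use a Metropolis chain over tables
with fixed margins (100,000 steps, 10,000 dememorisation by default)
with a batch-means Monte Carlo standard error. A cheap combinatorial
bound decides between the two routes before any work is done.

## The synthetic generator

`generate_sources()` and `generate_admixed()` produce data with known
truth. Generation is star-like: each haplogroup contributes a few
founder haplotypes (motif plus two fixed founder-private variants), and
each lineage copies a founder and adds Poisson-distributed private
substitutions (mean 2.5) at positions used by no motif. Hybrid lineages
copy source lineages exactly by default, so exact-match sharing is
non-degenerate by construction; a post-admixture mutation rate exists as
a stress-test knob.

Defaults were chosen once, as plausible regional-pool conditions: three
sources of 500 lineages with well-separated profiles sharing one
low-weight haplogroup, a hybrid of 1,000, mixing (0.5, 0.3, 0.2). The
star-like scheme reproduces the two structures the analysis consumes —
category profiles and haplotype sharing — with analytically known truth,
and leaves the expansion signature (negative Tajima's D, smooth unimodal
mismatch distribution) that real HVS-I samples show. What it does not
emulate: genealogical correlation beyond shared founders, back-mutation
and hotspot heterogeneity, or realistic coalescent tree shapes — so its
pairwise diversity runs somewhat higher than a single real regional pool
and its demographic parameters should be read qualitatively. Passing
recovery tests on this generator shows the estimators are correct under
the model they assume; it does not certify performance on sources whose
profiles overlap heavily, where any profile-based estimator loses
identifiability.

## Problem sizes and numerical choices

The validation suite runs the full recovery study at the default study
conditions (3 sources × 500, hybrid 1,000, 20 replicates across a grid
of mixing vectors), requires mean absolute error ≤ 0.05 with ≥ 18/20
coverage of the 95% posterior interval, checks every statistic against
an independent oracle (brute-force pair enumeration for θπ, symmetric
difference for distances, full enumeration and `fisher.test` for the
exact test), and calibrates the exact test's null rejection rate on 500
simulated tables. Null-calibration and bootstrap replicate counts in the
tests are sized to keep the whole suite in a few minutes; all seeds are
fixed in the code.

Degenerate inputs are handled explicitly rather than silently: zero
hybrids, empty sources, single-class mismatch distributions, all-zero
sharing rows, `S = 0` diversity, and non-converged chains all either
raise classed errors or return flagged results.

## Known limitations

* HVS-I alone cannot resolve fine haplogroup structure; the packaged
  motif table is coarse by design and classification quality is bounded
  by the table supplied.
* The sharing estimator's interval is a declared construction, not a
  community standard; treat cross-study comparisons of its widths with
  care.
* The profile-MCMC assumes the hybrid is a finite mixture of the listed
  sources; missing true sources bias weight onto the nearest listed one.
* Historical comparison is only as good as the region labels: genetic
  regions absent from the documentary table (e.g. East Africa, untouched
  by the Atlantic trade) are reported unmatched rather than forced into
  the comparison.
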