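# hvsadmix

Maternal admixture and diversity analysis of mitochondrial HVS-I
haplotypes.

## What it is for

Admixed populations — Caribbean populations founded during the
trans-Atlantic slave trade are the motivating case — carry in their
mitochondrial gene pool a record of the regions their maternal ancestors
came from. The first hypervariable segment (HVS-I, rCRS positions
16024–16365) is the mtDNA marker most densely sampled across the
African literature, so an admixed sample typed for HVS-I can be compared
against regional aggregates of published source populations, and the
genetic ancestry estimates confronted with the documentary record of the
migration. `hvsadmix` implements that workflow for population
geneticists and interdisciplinary demographers:

* parse HVS-I haplotypes in rCRS variant notation (`C16223T …`) or from
  aligned FASTA, with the poly-C tract (16184–16193) length polymorphism
  controlled for;
* assign haplogroups by motif matching against a user-replaceable tree
  and collapse them into macro-categories (L clades, U6, non-L/U6);
* estimate per-source maternal ancestry of a hybrid population two
  ways, with the non-sub-Saharan paragroup excluded from (but censused
  alongside) the analysis;
* compute Arlequin-style diversity and demography statistics and the
  exact test of population differentiation;
* compare ancestry estimates with the packaged historical
  disembarkation table for Jamaica (1651–1810, seven coastal regions);
* generate synthetic source/hybrid populations with known mixing
  proportions, so every stage is testable end to end.

## The two estimators

**Profile MCMC.** Hybrid haplogroup-category counts are modelled as
`y ~ Multinomial(N, q)` with `q = Σ_c m_c p_c`, where `m` is the mixing
vector (flat Dirichlet prior) and each source frequency vector `p_c`
carries Dirichlet uncertainty from its observed counts. A
Metropolis-within-Gibbs sampler (random walk on the softmax scale for
`m`; prior independence proposals for `p_c`) returns posterior mean ± SD
per source, with split-chain convergence checks.

**Haplotype sharing.** For tolerance `m ∈ {0, 1, 2}`, the sharing matrix
entry `S[i, c]` is the frequency in source `c` of haplotypes within `m`
mismatches of hybrid lineage `i`. Row-normalised weights averaged over
lineages give the ancestry proportions `P(m)`; 95% intervals come from
seeded posterior simulation (Dirichlet-resampled source frequencies plus
a lineage bootstrap). Unmatched lineages are excluded and counted, never
spread uniformly.

Diversity statistics are the standard battery: distinct haplotypes `k`,
segregating sites `S`, mean pairwise differences `θπ` ± SD (Tajima 1983
total variance), Tajima's D with beta-approximation p-values, and the
mismatch distribution fitted to the Rogers–Harpending sudden-expansion
model `F_j(τ, θ0, θ1)` with SSD and Harpending's raggedness index tested
by parametric bootstrap. Differentiation uses the Raymond–Rousset exact
probability test (full enumeration for small tables, a Metropolis chain
over fixed-margin tables otherwise).

## Worked example

```r
library(hvsadmix)

# three synthetic source pools (500 lineages each) with distinct
# haplogroup profiles, and a hybrid of 1000 drawn with true mixing
# proportions 0.5 / 0.3 / 0.2
cfg <- generator_config(seed = 42, source_sizes = c(500L, 500L, 500L),
                        mixing = c(0.5, 0.3, 0.2), hybrid_size = 1000L)
src <- generate_sources(cfg)
hyb <- generate_admixed(src$samples, cfg$mixing, 1000L, seed = 43)

profs <- lapply(src$samples, profile_counts)
fit <- fit_admixture_mcmc(profile_counts(hyb$sample), unname(profs),
                          mcmc_config(seed = 1))
fit
#> Admixture estimate (profile-mcmc)
#>    source   n   mean      sd  lower  upper
#> 1 SourceA 500 0.5095 0.02157 0.4687 0.5522
#> 2 SourceB 500 0.2920 0.02097 0.2510 0.3344
#> 3 SourceC 500 0.1985 0.01445 0.1721 0.2271

S <- build_sharing_matrix(hyb$sample, unname(src$samples), m = 0)
ancestry_proportions(S, seed = 2)
#> Admixture estimate (sharing-m0)
#>    source   n   mean  lower  upper
#> 1 SourceA 500 0.5126 0.4801 0.5424
#> 2 SourceB 500 0.2858 0.2589 0.3146
#> 3 SourceC 500 0.2016 0.1767 0.2283

diversity_summary(hyb$sample)
#> Hybrid: n=1000 k=675 S=322 theta_pi=14.79 +/- 7.32 D=-1.90*
```

Both estimators recover the true mixing proportions (0.5, 0.3, 0.2)
within their posterior intervals; the negative, significant Tajima's D
is the expansion signature built into the star-like generator. For real
data, read samples with `read_population_table()` (variant-list TSV or
aligned FASTA), and drive the whole analysis — regional aggregation,
exclusion iterations, both admixture tables, diversity, exact tests,
historical comparison — from one YAML config with `run_pipeline()`
(a thin command-line wrapper lives at
`inst/scripts/hvsadmix-pipeline.R`).

The historical record itself is available directly:

```r
dt <- load_disembarkation_table()
sum(dt)                                  # 701389 persons, 1651-1810
round(100 * regional_fractions(dt), 1)   # Gold Coast 28.6%, Biafra 32.3%, ...
```

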