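---
title: "Sex-partitioned nestedness in flower–visitor networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-partitioned nestedness in flower-visitor networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexnest)
```

## The question and the data model

Flower-visiting insects of the two sexes behave differently: females
forage for nectar and pollen to provision reproduction, males spend much
of their flower time searching for mates. If male visitation tracks
encounter probability (which flowers are abundant) while female
visitation tracks preference (which flowers a species favors), the two
sexes should leave different signatures in network architecture — in
particular in *nestedness*, the tendency of specialists to interact with
subsets of the partners of generalists.

`sexnest` works from **specimen records**: one row per collected insect,
carrying the visitor taxon label, its sex, the plant it was collected on,
and the collection site and year. Records missing any of these labels,
or whose sex could not be determined, are discarded (with per-reason
counts in a filter report); genus-level labels such as `"Lasioglossum sp."`
are kept as distinct morphospecies. Taxon identity is the verbatim label
string — museum labels are assumed pre-cleaned, and no synonymy or name
resolution is attempted. The filtered records are partitioned into
**origins** (site × year combinations); each origin yields a plant ×
visitor count matrix (the *species network*) and two **subnetworks**
built from only the female or only the male specimens. By construction
the female and male matrices add up, cell by cell, to the species
matrix, and species with no interactions under a sex filter simply do
not appear in that subnetwork.

Because the species network pools exactly the sexed specimens, every
count appears in one subnetwork and the species network; unknown-sex
specimens are removed before any network is built.

## Indices

All indices operate on the count matrix and are invariant to row and
column permutation (matrices are stored with lexicographic taxon order
purely for presentation).

**Weighted NODF.** For an ordered pair of columns whose marginal totals
strictly decrease, the pair's contribution is $100\,k/N$, where $N$ is
the number of non-empty cells of the poorer column and $k$ counts its
cells that are non-empty and strictly lower than the corresponding cells
of the richer column; row pairs are treated symmetrically, and

$$\mathrm{WNODF} = \frac{2(\mathrm{WNODF_c} + \mathrm{WNODF_r})}{m(m-1) + n(n-1)}.$$

Two conventions deserve note. First, pairs with *tied* marginal totals
contribute zero — the decreasing-fill condition — so a matrix whose
margins are all equal scores 0, and a strictly nested triangular matrix
scores 100. Second, some published implementations condition pairs on
binary fill (the number of non-empty cells) rather than on marginal
totals; this package conditions on marginal totals, the definition under
which the index was introduced for quantitative matrices. The test suite
cross-checks against `vegan::nestednodf(weighted = TRUE)` exactly on the
matrices where the two conventions coincide, and against a naive
pair-enumeration oracle everywhere.

**Connectance** is the fraction of observed links, non-zero cells over
$mn$.

**Niche overlap** at one guild level is the mean, over all unordered
species pairs, of the Chao abundance-based Jaccard similarity
$\hat U \hat V / (\hat U + \hat V - \hat U \hat V)$, where $\hat U$
estimates the total relative abundance in community $A$ of the species
shared with $B$, with the shared-singleton/doubleton correction for
unseen shared species. When the shared-doubleton count $f_{+2}$ is zero,
1 is substituted in the correction denominator (the standard
bias-correction practice), and $\hat U$ is truncated at 1. High overlap
means species at that level use similar partner sets. The label
"1 − Chao" in some summaries refers to overlap as one minus the Chao
*dissimilarity*; the quantity computed here is the similarity, high when
diets match.

**Partner diversity** is the abundance-weighted mean Shannon entropy
$H'_0 = \tfrac{1}{S}\sum_j n_j H'_j$, with $n_j$ a species' interaction
total, $S = \sum_j n_j$, and natural logarithms. The normalizer is $S$
(the weights sum to $S$), which makes the statistic a weighted mean;
singleton-margin species contribute $H' = 0$ with weight 1. A useful
identity follows from expanding the entropies:

$$S\,H'_0(\text{visitor}) - S\,H'_0(\text{plant})
  = \sum_j n_j \ln n_j - \sum_i m_i \ln m_i,$$

a function of the margins alone. Under fixed-margin nulls the two levels
therefore differ by a constant, their z scores coincide (a property the
tests verify to floating tolerance), and the package reports them as a
single standardized metric, `partner_diversity`.

## Null model and standardization

The null family is the uniform conditional distribution over integer
tables with the observed row and column sums — the encounter-probability
expectation for species that keep their observed interaction totals.
Draws use the Patefield algorithm (`stats::r2dtable`); an independent
multiset-pairing sampler (`shuffle_pairing_sample()`) with the same
distribution exists purely as a cross-check, and the tests compare both
samplers against exactly enumerated table probabilities.

Each network's indices are standardized as
$z = (\text{obs} - \text{mean(nulls)})/\text{sd(nulls)}$ against **one
shared set** of null networks per network (default 1000; the
sample standard deviation uses the $n-1$ denominator). Sharing the null
set across metrics is what makes the two partner-diversity levels
collapse to one z score; it also means a single seed per network
reproduces every standardized index. Seeds are derived deterministically
from a master seed with a labelled child-seed stream
(`derive_seeds()`), so any one network's standardization can be rerun in
isolation. Degenerate cases are reported, not extrapolated: a metric
undefined on the observed matrix, or a null distribution with zero
standard deviation (e.g. any pure margin function such as network size),
yields `z = NA` with `z_defined = FALSE`; nulls on which a metric is
undefined are excluded and counted in `n_failed`.

## Comparisons across network types

Standardized indices are compared across the three network types with a
Gaussian mixed model, `z ~ network_type + (1 | origin)`, the origin
random intercept absorbing site-and-year differences. The omnibus fixed
effect is a Satterthwaite F (via lmerTest). When it is significant at
0.05, each of the three pairwise type contrasts is refit on its two-type
subset and flagged against the Bonferroni threshold 0.05/3. Sex
composition (counts of all-female, all-male, and both-sex visitor
species) is compared with a Poisson mixed model with a log offset of
each origin's visitor richness; its omnibus and pairwise tests are
likelihood-ratio tests. Covariate models
(`z ~ covariate * network_type + (1 | origin)`) ask whether network
size, connectance, overlap, or diversity explains standardized
nestedness differences.

Mixed models on 11 origins can produce singular fits. Rather than
report a statistic from a degenerate covariance estimate, the package
falls back — with a warning and a flag in the result — to simpler
deterministic procedures: the omnibus test becomes the fixed-effect OLS
F with origin as a blocking factor; a pairwise contrast with complete
origin pairs becomes an exhaustive within-origin sign-flip permutation
test on origin-matched differences (all $2^{n}$ sign patterns, hence
fully reproducible without a random seed). Wald/F statistics from mixed
models are known to depend on the denominator-degrees-of-freedom
approximation and the software generation; analyses here are interpreted
through direction and significance pattern, not through exact F values.
Standardized modularity (sMOD) is accepted only as an external input
(`pearson_swnodf_smod()`); the package does not compute modularity.

## The synthetic specimen generator

The generator exists so that every stage — filtering, network assembly,
standardization, comparison — can be exercised on data whose generating
mechanism is known. It encodes, per origin:

* **Heavy-tailed abundances.** Plant and visitor relative abundances are
  normalized log-normals with shape parameters
  `plant_abundance_shape` (default 2.0) and `visitor_abundance_shape`
  (default 2.2).
* **Preferences.** Each visitor species draws a Dirichlet preference
  vector over plants with parameter
  `preference_concentration * n_plants * base`. The base measure is the
  plant-abundance profile by default, so a species' preference is a
  random deviation from floral availability and the concentration
  parameter (default 0.02) sets how specialized species are; a
  `"uniform"` base (preferences blind to abundance) is available, and
  under it large concentrations shrink preferences to uniform. The
  abundance base is the ecologically meaningful default: with a uniform
  base, aggregate plant margins become nearly flat and the
  strict-inequality weighting in WNODF then rewards the observed
  columns' internal concentration, masking the placement signal the
  mechanism is supposed to carry.
* **The sex mechanism.** Each sex's realized flower-choice distribution
  is the convex mixture `lambda * abundance + (1 - lambda) * preference`
  with a per-sex neutrality `lambda`: `neutrality_male = 1` (pure
  encounter) and `neutrality_female = 0` (pure preference) by default.
  At `lambda = 1` the sampled network is, conditional on its margins,
  exactly a draw from the Patefield null, so male z scores are expected
  to center on zero — a built-in ground truth the acceptance tests use.
* **Sampling design.** Specimens are drawn one at a time (species ∝
  visitor abundance, sex Bernoulli with the default female fraction
  3256/5212, plant from the species–sex choice distribution). The
  default design is 11 origins named for three sites × four years with
  one site–year absent and per-origin totals (687, 362, 616, 1098, 458,
  168, 531, 217, 384, 468, 223; 5212 specimens in all); a uniform
  `n_origins × n_specimens_per_origin` design is available for
  controlled experiments. The defaults (40 plants, a 1500-species
  visitor pool) yield realized per-network richness of roughly a few
  hundred visitor species with abundant singletons, the regime the
  specimen data occupy.

What the generator deliberately does **not** emulate: phenology and
seasonal compartments (a major source of modularity in real networks),
spatial structure within a site, per-species sex-ratio heterogeneity
(sex is a single Bernoulli rate, so the generated fraction of both-sex
species runs above what strongly sex-polarized real communities show),
and any correlation between a species' abundance and its degree of
specialization. Passing tests on synthetic data therefore demonstrate
that the pipeline recovers a *known* sex-differentiated mechanism
against the correct null — not that real museum data must show the same
effect sizes.

## Numerical and design choices

* Tie-breaks in WNODF: pairs with exactly tied marginal totals
  contribute zero from either side, which keeps the index
  permutation-invariant without relying on a sort order.
* Chao correction: $f_{+2} = 0$ is replaced by 1 in the denominator;
  $\hat U, \hat V$ truncated at 1; pairs sharing no species score 0.
* Child seeds come from a labelled stream per consumer
  (`"community"`, `"specimens"`, `"standardize"`), so adding a stage
  never shifts another stage's random numbers.
* All-pairs Chao overlap is computed with four cross-products rather
  than an explicit pair loop, making overlap standardization feasible at
  hundreds of species; the naive pairwise loop remains in the test suite
  as the oracle.
* Problem sizes in the shipped tests: null-distribution checks use
  20,000 draws on exactly enumerable margins; the type-I-error
  simulation uses 1000 replicates of the 11-origin design; mechanism
  recovery standardizes 22 subnetworks against 200 nulls each. The
  pipeline default of 1000 nulls is used when the full analysis is run
  on a dataset.

## Known limitations

* The fallback estimators for singular fits are conservative
  conveniences, not a substitute for a careful case-by-case mixed-model
  diagnosis on real data.
* Origins are treated as independent; communities that share species
  across sites or years get no cross-origin structure, in the generator
  or in the models beyond the random intercept.
* The weighted-NODF convention difference described above means values
  from fill-conditioned implementations are not numerically comparable
  on matrices where fill order and margin order disagree; z scores are
  the comparable quantity.
* Visitor species observed in a network only as one sex are genuinely
  ambiguous between behavioral absence and sampling; the sex-composition
  model quantifies the pattern but cannot separate those explanations.
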