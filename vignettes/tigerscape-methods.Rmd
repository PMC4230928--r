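---
title: "Landscape genetics and habitat connectivity with tigerscape: models and methods"
author: "tigerscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape genetics and habitat connectivity with tigerscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigerscape)
```

# The scientific problem

Large territorial carnivores in fragmented landscapes persist as small
populations connected — or not — by habitat corridors. Whether a corridor is
*functional* (whether animals actually move and breed across it) cannot
usually be observed directly. tigerscape implements a complete inferential
chain that answers this question from two independent data streams:

1. **Non-invasive genetics.** Microsatellite genotypes amplified from scat
   identify individuals, measure population differentiation, and detect
   recent immigrants.
2. **Occupancy surveys.** Replicated sign surveys on a landscape grid,
   corrected for imperfect detection, estimate where the species actually
   lives; occupancy probability parameterizes a movement-cost surface.

The validation step asks whether genetic differentiation between
populations is better explained by cost-weighted corridor distances
(least-cost and circuit-theory resistance) than by straight-line geography.
A positive answer is evidence that the mapped corridors carry gene flow.

Because the motivating field data (587 scat samples, 11 loci, thousands of
survey grids) are not deposited anywhere, the package ships a seeded
synthetic-data generator whose outputs have the same statistical structure,
and every statistical claim in the test suite is made against either an
analytic oracle or that generator's known truth.

# Module by module

## Synthetic data (`sim_config`, `gen_*`, `plant_migrants`)

The generator emulates the study design the analysis assumes:

* **Landscape** — disjoint circular habitat patches carved into a
  non-habitat matrix on a raster of 10 km cells, spatially autocorrelated
  covariates (box-kernel smoothed white noise, kernel width 3 cells — wide
  enough that the PCA stage sees correlated covariates), and an optional
  impermeable settlement band. Settlements are always non-habitat.
* **Metapopulation** — forward-time Wright–Fisher demes founded from one
  ancestral pool, exchanging gene copies at configurable per-generation
  rates. Mutation follows the two-phase model (TPM): with probability 0.95 a
  single repeat step, otherwise a geometric multi-step whose variance is 12
  — the same model the bottleneck test assumes, so simulator and test share
  one mutation model by construction. Defaults (11 loci with 4–12 founding
  alleles, deme size 50, migration 0.02, 100 generations) drift to pairwise
  F~ST~ in the 0.05–0.25 band typical of recently fragmented carnivore
  populations.
* **Migrants** — first-generation migrants are individuals lifted from the
  source deme after drift, immediately before sampling (so "first
  generation" is well defined at sampling time); second-generation migrants
  are fresh offspring of one source and one destination parent.
* **Genotyping noise** — per replicate, a locus fails entirely with
  probability 0.07 (so roughly 93% of loci are typed, matching published
  completeness levels for scat genotyping) and each allele of a heterozygote
  drops out independently with probability 0.1. No published per-study error
  rates exist for the motivating data, so these defaults are plausible
  rather than calibrated, and both are configurable.
* **Detection histories** — occupancy state is drawn once per grid
  (closure) and detections are Bernoulli draws at occupied grids only, with
  3–35 replicate surveys per grid at base detectability 0.2.

What the generator does *not* emulate: null alleles and stutter artefacts,
related individuals within demes (beyond drift itself), spatially
heterogeneous sampling effort, multi-season dynamics, and real geodesy
(coordinates are planar km). Tests passing on these synthetic data therefore
demonstrate correctness of the estimators under the stated model, not
robustness to every field pathology.

## Genotypes: from scats to individuals

Consensus calling follows the replicate-confirmation rule used in
non-invasive genotyping: a heterozygote needs the same allele pair in two
independent replicates, a homozygote needs five concordant replicates
(allelic dropout makes false homozygotes much likelier than false
heterozygotes). Individual matching merges samples identical at all shared
loci; pairs mismatching at one or two loci merge only when every mismatch
is *dropout-consistent* (homozygote versus a heterozygote containing that
allele). The original laboratory workflow re-amplified such pairs; an
automated pipeline cannot, so dropout-consistency is the programmatic
surrogate — a deliberate design choice. Matching is performed by
union–find over the pairwise merge relation, which makes the partition
independent of sample order.

Identification power is summarized by the cumulative sibling probability of
identity, per locus

$$PI_{sib} = 0.25 + 0.5\sum p_i^2 + 0.5\left(\sum p_i^2\right)^2 -
0.25\sum p_i^4,$$

the probability that two full siblings share a genotype — a conservative
bound because siblings are the hardest pair to tell apart. The unrelated-pair
PI uses the small-sample unbiased form (a cubic in the number of sampled
gene copies that tends to $2(\sum p_i^2)^2 - \sum p_i^4$ as samples grow).
Expected heterozygosity carries the $n/(n-1)$ gene-copy correction because
groups as small as two individuals occur by design.

Hardy–Weinberg tests are Monte-Carlo exact tests: the statistic is the
conditional probability of the genotype array given the allele counts, the
null re-pairs permuted gene copies, and the p-value counts arrays no more
probable than the observed one (with the +1 correction, so p is never 0).
Linkage disequilibrium uses the G² statistic of association between
single-locus genotype classifications, permuting one locus across
individuals. Both tests are exact-conditional and therefore slightly
conservative at very low allele counts; calibration checks use
polymorphic (microsatellite-like) loci where the discreteness is mild.

## Population structure

F~ST~ is the Weir–Cockerham variance-components estimator (components *a*,
*b*, *c* summed over alleles and loci); the test suite proves it equal, to
10 decimal places, to an independently coded nested random-effects ANOVA on
allele indicator variables. R~ST~ applies the analogous decomposition to
allele *size* (repeat count). AMOVA partitions the squared inter-individual
distance — the count of allele differences over shared loci, the codominant
genotypic distance convention — among clusters, among populations within
clusters, and within populations, with permutation tests appropriate to each
level (whole populations permuted among clusters; individuals permuted
within clusters). Negative variance components are floored at zero for the
percentage report with raw values retained. The permutation scheme for
R~ST~ permutes individuals (whether the original tools permute individuals
or allele sizes is not documented; individuals is the more conservative
choice and matches the F~ST~ scheme).

Differentiation is linearized as $d/(1-d)$ before any regression on
distance. PCoA is the double-centering eigendecomposition; negative
eigenvalues of non-Euclidean inputs are reported, never silently dropped.

Bottleneck diagnostics: the M-ratio (mean over loci of $k/(r+1)$, depressed
when rare alleles are lost faster than the allele size range shrinks), the
mode-shift test on 0.05-wide allele-frequency classes, and the
heterozygosity-excess test. The latter needs the equilibrium distribution of
gene diversity conditional on the observed allele count and sample size,
which tigerscape obtains by coalescent simulation with mutations placed on
the genealogy (SMM or TPM), adaptively steering the mutation parameter until
simulated allele counts match and accepting only matching simulations. The
desk-scale default is 1,000 accepted simulations per locus (configurable;
published analyses often use 10,000).

## Assignment and migrants

The admixture model is the standard one: allele copies originate from `K`
clusters, cluster allele frequencies carry an uncorrelated Dirichlet(1)
prior and memberships a symmetric Dirichlet(alpha) prior with alpha learned
by a Metropolis step. The uncorrelated-frequencies prior is a simplification
of the correlated model often used in field studies; at the differentiation
levels simulated here (F~ST~ 0.05–0.25) it separates demes cleanly, which is
what the tests verify. Model support is summarized as
$\mathrm{mean}(\log L) - \mathrm{var}(\log L)/2$ over post-burn-in sweeps,
and the Evanno second-order statistic
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / \mathrm{sd}(L(K))$
selects the cluster number. Desk-scale MCMC defaults (2,000 sweeps, 500
burn-in) replace the production-scale millions; all are arguments.

Assignment likelihoods are Bayesian posterior predictives with a
Dirichlet(1/k) allele prior, leave-one-out for the home population. The
exclusion statistic is $\log_{10} L_{max} - \log_{10} L_{home}$, so a value
of 2.0 means the home population is a hundred times less likely than the
best one. First-generation migrants are flagged when the Monte-Carlo
exclusion p-value falls below alpha *and* the statistic reaches 2.0. The
null distribution is built by gene-drop resampling: each batch of simulated
genotypes is scored against an independently resampled home reference, so a
simulated individual pays the same sampling-error penalty as a real
left-out individual. (Scoring simulated genotypes against the very counts
they were drawn from — the shortcut — is measurably anti-conservative; the
resampled scheme restores validity, which the calibration tests check.)
Note that resident p-values are *sub*-uniform with an atom at 1, mirroring
the statistic's atom at 0 for correctly assigned residents; validity, not
exact uniformity, is the testable property.

Two-generation immigrant ancestry is a Gibbs sampler over per-individual
states {resident, first-generation immigrant from j, second-generation
(one immigrant parent) from j} and population allele frequencies, with
prior migrant mass `migprior = 0.05` split evenly over immigrant states
(the analysis is insensitive to this prior over 0.001–0.1 in the motivating
study, and the package exposes it). Recent migration rates aggregate the
ancestry posterior — `m[dest <- src]` is the mean posterior immigrant mass
(gen1 + gen2/2) — an acknowledged approximation of the full
Wilson–Rannala migration-rate model that avoids a second large MCMC while
preserving the migration-matrix contract (rows sum to 1, credible intervals
from posterior draws). Groups under five individuals are excluded, as
small-sample assignment rates are unreliable.

Parentage uses the summed per-locus log likelihood ratio (LOD) of the
candidate-parent hypothesis against a random parent, with a simple
stochastic-error mixture keeping LOD finite under genotyping error, and
Monte-Carlo confidence thresholds (strict 95% / relaxed 80%) from simulated
offspring–candidate pools (defaults scaled to 1,000 offspring).

The **consensus designation rule** integrates the evidence: *migrant*
requires (i) exclusion p < 0.01 with statistic ≥ 2.0, (ii) posterior
migrant probability above 0.5 in both Bayesian analyses, and (iii)
first-generation state above 0.5 in both; high membership in a single
non-home cluster (Q > 0.8) corroborates but is not required — the published
evidence table this rule is validated against contains a migrant with
Q = 0.527, so requiring criterion (iv) would contradict the printed
designations. Individuals with immigrant evidence from at least two
sources (exclusion significant at 0.05, or posterior migrant mass above
0.1 in either Bayesian analysis, or Q > 0.8 non-home) that fail the full
rule are *admixed* — second-generation-dominant posteriors land here by
construction. Everyone else is a resident. The packaged evidence table
(`inst/extdata/table3_evidence.csv`) encodes printed significance classes
as representative p-values (0.009, 0.04, 1) and a below-threshold statistic
as 1.9; only the ordering relative to the rule's cutoffs matters.

## Occupancy

The single-season zero-inflated detection likelihood is

$$P(y_i) = \psi_i \prod_j p_{ij}^{y_{ij}} (1-p_{ij})^{1-y_{ij}}
  + (1-\psi_i)\,\mathbf 1\{\text{all } y_{ij} = 0\},$$

with logit links on occupancy ($\psi$, covariates via a model formula) and
detection ($p$: constant, survey-specific, or linear in a grid-level
abundance index — the index enters once per grid, constant across
replicates, because it is a property of the site). The likelihood is
vectorized over sites through per-site sufficient statistics and maximized
by multi-start BFGS (three starts, tolerance 1e-8 on the log-likelihood);
standard errors come from the inverse observed information, inflated by
$\sqrt{\hat c}$ when overdispersion is estimated. Ragged replicate counts
and NA replicates are supported throughout; all-zero and all-one data push
$\hat\psi$ to a boundary, which is flagged rather than hidden.

Model selection is by AIC with Akaike weights; per-grid occupancy is
averaged over models within 4 AIC units of the best (renormalized weights).

**Goodness of fit.** Histories of unequal length are not directly
comparable, so sites are cohorted by survey count; within each cohort the
statistic compares observed frequencies of *detection counts* (d = 0..k)
with their expected frequencies under the fitted model, the per-site
distribution of d given occupancy coming from the Poisson-binomial
recursion (exact under survey-specific detection). Adjacent classes are
pooled until each pooled class has expected count at least 0.5 — without
pooling, a rare class observed once against a vanishing expectation
produces explosive statistic values that wreck the bootstrap mean.
Each parametric-bootstrap replicate is *refit* (warm-started at the parent
estimates) before its statistic is computed, so observed and bootstrap
statistics enjoy the same overfitting; $\hat c$ is the observed statistic
over the bootstrap mean and the standard-error inflation is $\sqrt{\hat c}$.
The original PRESENCE cohorting details are not restated anywhere public;
this detection-count construction is the package's documented stand-in, and
its calibration ($\hat c \in [0.8, 1.2]$ on self-simulated data) is tested.
The bootstrap default is 1,000 replicates (production analyses use tens of
thousands).

Area summaries convert per-grid occupancy to landscape figures: naive
occupancy (fraction of surveyed grids with a detection), model occupancy
(mean $\hat\psi$), and occupied habitat (habitat area weighted by
$\hat\psi$), with increments reported in percentage points.

## Connectivity

The cost surface is `1 - psi` on habitat cells (occupancy probability as
habitat suitability), a flat higher cost on permeable non-habitat (default
3 — the original supplementary cost schedule is not publicly available, so
this is configuration, not reproduction), and impermeable human settlements
excluded from every graph. Costs are floored at 1e-6 to keep conductances
finite.

Least-cost paths run Dijkstra (via igraph) on the 8-connected lattice with
edge weight = mean of the two cell costs × step length (1 or $\sqrt 2$) ×
cell size; region-to-region distance is minimized over boundary cells by
attaching zero-weight virtual terminals. Corridors are the path buffered by
1.5 km; the corridor cost is the least-cost distance recomputed on the
graph restricted to the corridor. Because the corridor always contains the
optimal path, the recomputed corridor cost equals the raw path cost under
this definition — the alternative reading (corridor cost as an aggregate of
within-corridor cell costs) was rejected as less interpretable, and the
equality is asserted, not hidden, in the tests.

Circuit-theory resistance uses the 4-connected lattice (the convention of
the standard circuit software), per-edge resistance = mean cell cost × cell
size, source regions collapsed to supernodes, and pairwise effective
resistance from sparse Laplacian solves (Matrix). Current maps inject unit
current at one terminal; per-cell current is half the summed absolute
incident edge currents, so a serial-path cell carries exactly 1. Bottleneck
cells are those above a percentile (default 95) of current within the
corridor mask. Tests verify the series/parallel laws, agreement with a
dense pseudoinverse oracle at 1e-10, Rayleigh monotonicity, and flow
conservation.

## Mantel validation

The spatial model set is GGD (Euclidean centroid distance), log10 GGD,
LCPD, LCCD and RD; the genetic side is linearized F~ST~ (or Phi~PT~).
The Mantel statistic is the Pearson correlation of the vectorized
off-diagonals under simultaneous row/column permutation, one-tailed for
positive association (the directional hypothesis throughout), with
`p = (count + 1)/(n_perm + 1)`. Partial Mantel tests residualize both
matrices on the controls and permute the residual matrix (Freedman–Lane),
which has better type-I control than raw-matrix permutation. Infinite
distances (disconnected pairs) drop pairwise with an explicit count.
Controls numerically identical to a tested matrix yield a flagged zero
partial correlation rather than noise. A binary between/within-cluster
matrix lets isolation-by-distance be tested while holding hierarchical
structure fixed. Model comparison reports the percentage change in Mantel r
against the straight-line baseline.

`run_pipeline()` chains everything: landscape → resistance-driven
migration (emigration decaying with inter-patch resistance, capped at 15%
per generation) → drift → noisy replicates → consensus genotypes →
individuals → F~ST~ → occupancy fit → cost surface → LCP/RD → Mantel
comparison, with a manifest of seeds and headline numbers, and optional
CSV/ASCII-grid artifacts.

# Numerical choices and problem sizes

* All randomness flows through explicit `seed` arguments; a fixed seed
  reproduces every output bit-for-bit.
* Permutation and Monte-Carlo p-values always use the +1 correction.
* Dijkstra ties are resolved deterministically by the graph library's
  stable ordering; same input, same path.
* Zero-cost cells are floored at 1e-6; likelihood terms at 1e-300.
* The test suite runs simulations at desk scale — demes of 10–50
  individuals, 5–11 loci, grids up to 24×24, hundreds of survey sites,
  999 or fewer permutations, 20-replicate power checks — sizes chosen so
  the full suite completes in minutes while leaving each statistical check
  adequately powered.

# Known limitations

* The admixture sampler uses uncorrelated allele-frequency priors and a
  simplified locality prior; very weak structure (F~ST~ < 0.03) may need
  the correlated model the package does not implement.
* Recent migration rates are an ancestry-posterior aggregate, not the full
  joint migration-rate likelihood; credible intervals are conditional on
  the two-generation state space.
* The heterozygosity-excess null is simulation-based and inherits
  Monte-Carlo noise at small `n_sim`.
* Coordinates are planar; no geodesic corrections.
* The exclusion-test p-values are valid but conservative for correctly
  assigned residents (mass at 1), so resident-level uniformity diagnostics
  must account for the atom.
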