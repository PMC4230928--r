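# tigerscape

Landscape genetics and habitat connectivity for fragmented carnivore
populations, in one R package.

## The problem

Source populations of large territorial carnivores — tigers are the
motivating case — survive in small habitat patches linked by corridors
whose *functionality* (do animals actually disperse and breed across them?)
is rarely backed by data. tigerscape implements the full inferential chain
that answers this from two field-data streams:

* **Non-invasive microsatellite genetics** (scat genotypes): consensus
  calling from replicate amplifications, individual identification with
  probability-of-identity statistics (the sibling form
  `PIsib = 1/4 + S2/2 + S2²/2 − S4/4`, `Sk = Σ pᵢᵏ`), diversity and
  HWE/LD testing, Weir–Cockerham *F*~ST~, allele-size *R*~ST~, hierarchical
  AMOVA with Phi statistics, PCoA, and bottleneck diagnostics (M-ratio,
  heterozygosity excess under SMM/TPM, mode shift).
* **Bayesian assignment**: admixture clustering with the Evanno delta-K
  criterion, Rannala–Mountain exclusion tests with gene-drop resampling for
  first-generation migrants (`log10 Lmax − log10 Lhome ≥ 2` at p < 0.01),
  two-generation immigrant-ancestry posteriors, recent migration-rate
  matrices, parentage LOD scores, and a conservative multi-program
  consensus rule designating each individual migrant / admixed / resident.
* **Occupancy surveys**: PCA + varimax covariate reduction, single-season
  occupancy likelihood
  `P(y) = ψ·Π p^y (1−p)^(1−y) + (1−ψ)·1{y = 0}` with three detection
  structures, AIC selection and model averaging, parametric-bootstrap
  goodness of fit with overdispersion `ĉ` and `√ĉ` SE inflation, and
  naive-versus-model occupied-area summaries.
* **Connectivity**: occupancy-derived cost surfaces (`cost = 1 − ψ`,
  settlements impermeable), least-cost paths and 1.5-km buffered corridors
  (Dijkstra, 8-neighbour), circuit-theory effective resistance and current
  maps with corridor bottlenecks (sparse Laplacian solves, 4-neighbour).
* **Validation**: Mantel and Freedman–Lane partial Mantel tests of
  linearized genetic distance (`d/(1−d)`) against five spatial models
  (straight-line GGD, log GGD, least-cost path LCPD, corridor LCCD,
  resistance RD), with cluster-controlled partials.

A seeded synthetic-data generator (landscapes, drifting metapopulations,
planted migrants, noisy scat replicates, detection histories, plus a
ground-truth ledger) stands in for the undeposited field data and powers
all parameter-recovery and calibration tests.

## A worked example

```r
library(tigerscape)

cfg <- sim_config(seed = 108, n_pops = 6, n_patches = 6, n_loci = 11,
                  effective_size = 40, n_generations = 100,
                  grid_shape = c(18, 24), settlement_band = TRUE)
res <- run_pipeline(cfg, n_perm = 999)

res$individuals
#> geno_set: 208 samples, 11 loci, 6 populations
#>   loci typed: 86.8%; populations: pop1, pop2, pop3, pop4, pop5, pop6

round(res$fst$estimate[1:4, 1:4], 3)
#>       pop1  pop2  pop3  pop4
#> pop1 0.000 0.017 0.016 0.056
#> pop2 0.017 0.000 0.041 0.039
#> pop3 0.016 0.041 0.000 0.069
#> pop4 0.056 0.039 0.069 0.000

res$comparison$table
#>   genetic spatial     r     p pct_increase_vs_GGD
#> 1 gen_fst     GGD 0.586 0.036                 0.0
#> 2 gen_fst  logGGD 0.572 0.031                -2.3
#> 3 gen_fst    LCPD 0.742 0.016                26.7
#> 4 gen_fst      RD 0.704 0.011                20.1
```

The pipeline simulates a landscape split by a settlement band with a single
corridor gap, lets demes drift with migration that decays with inter-patch
resistance, degrades the genotypes with scat-style noise, rebuilds
individuals by consensus + identity matching, estimates *F*~ST~, fits
occupancy, builds the cost surface, computes least-cost and resistance
distances, and runs the Mantel comparison. Because gene flow in this
simulation really did follow landscape resistance, the corridor-aware
models (LCPD, RD) explain the pairwise differentiation better than
straight-line distance — gains of 27% and 20% in Mantel *r* here. (Numbers
above are from this exact seed; your run reproduces them bit for bit.)

Individual pieces work standalone — e.g. an occupancy fit is a classed
model object:

```r
h <- gen_detection_histories(rep(0.6, 300), 0.3,
                             sim_config(surveys_per_grid = c(5, 5)), seed = 9)
fit <- fit_occupancy(h, ~ 1, "constant")
fit
#> Single-season occupancy model: psi(1),p(constant)
#>   sites: 300  logLik: -669.14  AIC: 1342.28  converged: TRUE
#>   mean psi-hat: 0.596  mean p-hat: 0.296
summary(fit, c_hat = 1.4)
#> Occupancy model: psi(1),p(constant)
#> logLik -669.14  AIC 1342.28  (SEs inflated by sqrt(c-hat) = 1.183)
#>                 estimate     se exponent
#> psi_(Intercept)   0.3896 0.1929   1.4764
#> p_(Intercept)    -0.8649 0.1157   0.4211
```

with `coef`, `logLik`, `AIC`, `vcov`, `predict`, `fitted` and `simulate`
methods.

## Package layout

| file | contents |
|---|---|
| `R/geno.R`, `R/io.R` | genotype container; GENEPOP / ESRI ASCII / table I/O |
| `R/simdata.R` | seeded synthetic landscapes, metapopulations, noise, surveys |
| `R/genotypes.R` | consensus, identity matching, PI, diversity, HWE/LD |
| `R/popstruct.R` | F_ST, R_ST, AMOVA, PCoA, linearization, bottlenecks |
| `R/assignment.R` | admixture Gibbs, delta-K, exclusion tests, ancestry, LOD, consensus rule |
| `R/occupancy.R` | covariate reduction, occupancy MLE, AIC averaging, GOF |
| `R/connectivity.R` | cost surfaces, least-cost corridors, circuit theory |
| `R/landgen.R` | distance-matrix assembly, Mantel framework, pipeline |

The methods vignette (`vignettes/tigerscape-methods.Rmd`) documents every
model, default and numerical choice.
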