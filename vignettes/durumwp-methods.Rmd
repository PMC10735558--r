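---
title: "Methods: water productivity analysis for durum wheat multi-environment trials"
author: "durumwp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water productivity analysis for durum wheat multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durumwp)
library(dplyr)
```

# The problem

Durum wheat in the Mediterranean basin is mostly rainfed, and in-season
moisture is the dominant driver of grain yield (GY). Breeding for this
region means finding genotypes that convert moisture into grain
efficiently — their *water productivity* (WP, kg of grain per ha per mm of
moisture) — and that do so stably across a wide range of environments.
`durumwp` implements the complete analysis chain such a study needs:

1. plot-level phenotype processing and design-adjusted genotype means
   (BLUEs) for augmented and alpha-lattice trial designs;
2. variance partitioning (G, E, G×E) and broad-sense heritability;
3. climate-driven clustering of trial environments into moisture-stressed
   and non-stressed mega-environments;
4. AMMI decomposition of G×E with the AMMI wide adaptation index (AWAI)
   and a yield-vs-stability selection surface;
5. classification of genotypes into five water-productivity classes from
   their moisture-response slopes;
6. genome-wide association (fixed-effects and kinship mixed models),
   LD-based assembly of marker–trait associations (MTAs) into QTL;
7. haplotype effect testing and KASP-style validation metrics for
   marker-assisted selection.

Every stage is exercised end-to-end on synthetic data from the package's
own generator, which plants known ground truth, so the statistical
machinery is testable without any field data.

# Phenotype processing

## Derived yield components

Two components are derived from plot measurements (weights in grams, plot
area in m²):

$$\mathrm{Gr.m^{-2}} = \frac{\text{harvested weight}}{\text{plot area}\times \mathrm{TKW}/1000},
\qquad
\mathrm{GpS} = \frac{\mathrm{Gr.m^{-2}}}{\mathrm{Spk.m^{-2}}}$$

where TKW is the 1000-kernel weight and Spk.m⁻² the spike density. A
measured grains-per-spike value is never overwritten; rows with missing
inputs keep the component absent and are only counted in a log message —
a missing TKW should not delete a plot.

## Design-adjusted means

Multi-environment trials rarely replicate every entry everywhere.
`compute_blues()` supports the two layouts such programmes use:

* **Augmented design** — unreplicated test entries plus replicated checks.
  The block effect is estimated as that block's check mean minus the
  overall check mean (the classical check-based additive correction) and
  subtracted from every entry. This is deterministic and closed-form; its
  standard errors come from the residual mean square of the check ANOVA,
  scaled by $\sqrt{1 + 1/c}$ for entries seen once and shrinking with
  $\sqrt{r}$ under replication.
* **Alpha-lattice** — two replicates with resolvable incomplete blocks,
  fitted as a fixed-effects model `trait ~ genotype + replicate + block`
  with adjusted means extracted via `emmeans`. In a balanced design with
  no block variance these collapse to arithmetic means, which is asserted
  in the test suite.

Genotypes are treated as fixed effects throughout: the output is a best
linear unbiased *estimate* per genotype and environment, which every
downstream stage consumes.

## Variance partition and heritability

`variance_partition()` reports the share of the total sum of squares
attributable to genotype, environment and their interaction
(share = SS/SS~total~, computed from cell and marginal means; the four
components are asserted to reconstruct the total to 1 part in 10⁸).
Per-environment broad-sense heritability uses the replicate-based formula
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e/r)$ from the within-environment
one-way ANOVA; REML variance components are deliberately out of scope —
the closed-form estimator is deterministic and unit-testable.

## Scaling and correlations

Because environment means span an order of magnitude, the genetic
component of yield is expressed as **ratio-to-max**: each genotype's value
divided by the environment's best entry, averaged over environments. The
top entry of every environment scores 1, so the statistic is invariant to
environment-level shifts and scales.

`trait_gy_correlations()` mirrors the conventional trait-by-environment
correlation table: Pearson r of DTH, TKW, SPK and GpS against GY per
environment and per mega-environment average, with a single significance
code at P < 0.001 ("•"), "ns" otherwise, and "-" where a trait is
unavailable or degenerate.

# Environments and climate

The climate table is long-format over five growth stages (pre-sowing,
vegetative, flowering, grain-fill, maturity) and climatic variables.
`climate_regression()` regresses environment-mean GY on each
(stage, variable) factor separately and flags factors with P < 0.05;
`cluster_environments()` standardizes the significant factors, projects
the environments onto principal components retaining ≥ 80% of the
variance (configurable), and cuts a Ward-linkage tree at *k* = 2. The
cluster with the lower mean total moisture is labelled
`moisture_stressed` — a deterministic rule replacing manual labelling,
asserted as an invariant. With *k* = 1 the single group is labelled
against a configurable 400 mm pivot.

Boundary environments (~430–460 mm) can land on either side in noisy
draws; this ambiguity is a property of real data too, where trials a few
mm apart in seasonal moisture can be grouped differently depending on
which climatic factors are examined.

# Stability: AMMI and AWAI

`fit_ammi()` fits additive genotype and environment effects to the
two-way table of GY BLUEs, then factors the doubly-centered residual by
SVD. Scores are scaled symmetrically ($u\sqrt{\lambda}$, $v\sqrt{\lambda}$)
so the sum of IPC outer products reconstructs the interaction exactly
(asserted to 1e-8 on random tables). The fraction of G×E variance on the
i-th axis is $s_i = \lambda_i^2 / \sum_k \lambda_k^2$.

The number of *significant* interaction principal components is decided
by a sequential F-test with Gollob degrees of freedom
$df_k = (g-1)+(e-1)-(2k-1)$. When plot-level error is available its mean
square can be supplied; by default each axis is tested against the pooled
mean square of the remaining (untested) axes, and testing stops at the
first non-significant axis. The last axis is untestable without an
external error term and is conservatively declared non-significant.

The **AMMI wide adaptation index** for genotype *g* is

$$\mathrm{AWAI}_g = \sum_{i \le i^*} s_i \, |PC_{g,i}|$$

over the $i^*$ significant axes: 0 for a genotype that never interacts
(widest adaptation), growing with interaction load. Two conventions for
its direction circulate; the package reports both the raw index (0 =
best) as primary and a ratio-to-minimum rescaling
(min positive AWAI / AWAI, clipped to [0, 1], zero-AWAI genotypes mapped
to 1) in which 1 = best. `selection_surface()` crosses ratio-to-max yield
with AWAI and flags genotypes beating the panel average on both axes —
the standard yield-potential × stability selection view.

# Water productivity classes

WP is the quotient of grain yield and total in-season moisture. The
moisture response of the *average* genotype is summarized by the OLS
slope of environment-mean GY on moisture, fitted per mega-environment
group (`group_slopes()`); the frozen reference values 5.08 (stressed) and
4.85 (non-stressed) kg/ha/mm can be supplied instead of recomputing.

Each genotype's own slopes $b_i$ (per group) place it in one of four
quadrants relative to the group slopes:

| class | name | stressed | non-stressed |
|---|---|---|---|
| 1 | Stable water response | $b_i \le$ group | $b_i \le$ group |
| 2 | Responsive to low moisture | $b_i >$ group | $b_i \le$ group |
| 3 | Responsive to high moisture | $b_i \le$ group | $b_i >$ group |
| 4 | Highly water responsive | $b_i >$ group | $b_i >$ group |

with a fifth class, *No water response*, for genotypes whose GY-moisture
regression is not significant at α = 0.01.

Two design choices deserve explanation:

* **The significance gate is the overall regression by default.** The
  class table carries a single r² per genotype, and requiring *both*
  within-group regressions to reach P < 0.01 turns out to be so strict
  under realistic variance structure (E ≫ G×E, within-group moisture
  spans of ~200 mm, 7–11 environments per group) that essentially every
  genotype would be declared unresponsive. The single regression across
  all environments has the span to detect genuine moisture response while
  still sending flat genotypes to class 5 at the nominal rate. The
  stricter per-group reading is available via `gate = "per_group"`.
* **Boundary ties go to the "≤" side**, with a 1e-8 relative tolerance so
  that a genotype whose estimated slope equals the group slope to
  floating-point noise is classified deterministically.

Genotypes observed in fewer than 3 environments within a group are
reported unclassified with an explicit reason rather than guessed.

# Association analysis

## Curation, structure, kinship

`curate_markers()` applies the standard array filters — missing rate
< 1%, minor allele frequency ≥ 5%, heterozygosity ≤ 5% (all
configurable) — and reports counts per filter. `structure_and_kinship()`
returns Q (leading principal components of the centered dosage matrix;
count by the eigenvalue-elbow rule unless given) and the VanRaden genomic
relationship matrix $K = WW'/(2\sum p_j(1-p_j))$, asserted symmetric
positive semidefinite.

## LD decay

Within-chromosome pairwise allelic r² is binned by physical distance and
an exponential-plus-floor curve $r^2(d) = (r_0 - f)e^{-d/\tau} + f$ is
fitted to the bin means; the decay distance is where the fitted curve
crosses a critical background r². The pipeline's default critical value
is the frozen 0.05; a value derived from the panel size
(`critical_r2_for_n()`) is available but can sit *inside* the
genome-wide structure-LD floor on structured panels, making the crossing
undefined. When the floor itself reaches the critical value, the method
reports the maximum observed distance — the honest statement that LD does
not decay below background within a chromosome for that panel.

## GWAS

`gwas()` scans each marker against one phenotype context (a single
environment or a combined mega-environment mean) with days-to-heading and
the Q PCs as fixed covariates, so flowering-time loci do not masquerade
as yield loci.

* `GLM_Q` — fixed-effects regression; implemented by residualizing the
  phenotype and all (mean-imputed) dosages on the covariates once, then
  per-marker t-tests. The marker r² is the *incremental* r² after
  covariates, as a fraction of total phenotypic variance.
* `MLM_QK` — adds one random polygenic term with covariance σ²~g~K. The
  variance ratio is estimated once by REML on the null model using the
  eigendecomposition of K, then fixed for every marker test (the
  population-parameters-previously-determined approximation), making the
  scan a single weighted least-squares pass. With K = I the weights are
  constant and the mixed model reproduces the fixed model exactly — a
  limiting identity asserted to 1e-6 in the tests.
* `auto` — runs both and keeps the model whose genomic inflation factor
  λ = median(χ²)/qchisq(0.5, 1) is nearer 1, operationalizing the usual
  visual QQ-plot comparison.

An MTA must clear **both** gates: LOD = −log₁₀(p) at or above the cutoff
(default 2.69, a Bonferroni-by-LD style threshold) and marker r² at or
above the squared critical Pearson correlation (default 0.024).

One caveat the test suite makes explicit: a QTL whose genotypes are
nearly collinear with the structure axes is invisible to a
structure-corrected scan *by design*. The power simulations therefore
plant their test QTL at markers segregating within subpopulations (r² on
Q below 0.2); confounded markers are a blind spot shared by all Q/K
corrected methods, not a defect of this implementation.

## QTL assembly

`assemble_qtl()` chains same-chromosome MTAs whose distance is strictly
below the merge distance (default: twice the estimated LD decay distance;
the conventional frozen value can be supplied). Chaining is single-linkage
and therefore transitive: MTAs at 10, 100 and 190 Mbp merge into one QTL
spanning 180 Mbp even though the ends are farther apart than the merge
distance — a documented consequence of the rule. A QTL is *consistent*
when its members include a combined-analysis context **and** more than
one individual environment; it is a *true positive* when a second panel's
QTL overlaps its span on the same chromosome (closed 1-based bp
intervals). The representative marker is the member with the highest LOD,
ties broken by r², then by lowest position. Identifiers `Q.<prefix>.<NN>`
are numbered along the genome, so the output is invariant to input order.

# Haplotypes and KASP validation

`build_haplotypes()` partitions genotypes by their +/− pattern of
favorable alleles (from the MTA effect signs in the discovery context —
never re-estimated in a validation panel, which would leak information)
at the representative markers; heterozygous or missing calls exclude a
genotype, and groups are numbered by descending favorable-allele count.
`haplotype_effect_test()` fits a one-way fixed-effects model and assigns
compact letters from pairwise least-significant-difference tests,

$$\mathrm{LSD}_{ab} = t_{1-\alpha/2,\,df_e}\sqrt{\mathrm{MSE}\,(1/n_a + 1/n_b)},$$

the unequal-n form; letters are the maximal cliques of the
not-significantly-different graph, so two groups share a letter exactly
when they do not differ at α.

`kasp_validate()` scores a marker the way a breeder validates a KASP
assay: rank the panel by GY, call the top *n* (default 20) positives and
bottom *n* negatives, and count carriers of the favorable allele:
accuracy = (TP+TN)/2n, sensitivity = TP/n, specificity = TN/n. With
balanced extremes accuracy is identically the mean of sensitivity and
specificity, which is asserted. A literal-denominator variant (both
ratios over all 2n extremes) is available behind a flag since the prose
definitions of these ratios are ambiguous in parts of the literature. An
AND-rule over several markers (carrier at all loci) is appended on
request; it can only lose sensitivity and gain specificity relative to
its weakest member, also asserted.

# The synthetic-data generator

`sim_config()` + `simulate_trials()` emulate the statistical structure of
a Mediterranean durum trial series; all ground truth (QTL positions and
effects, per-genotype slopes, true WP classes, subpopulations, variance
components) is returned for testing.

**Study conditions (defaults).** 200 inbred genotypes × 18 environments
(11 moisture-stressed, 7 non-stressed) spanning 210–650 mm; 600 biallelic
markers on 14 chromosomes of 600 Mbp; 6 planted QTL; 4 subpopulations;
augmented design with 4 checks and 6 blocks. Environment-mean GY is
affine in moisture within each group with the planted slopes 5.08 and
4.85 kg/ha/mm, and group intercepts (0 and 2540 kg/ha) chosen so the
mean WP lands near 5.1 (stressed), 9.5 (non-stressed) and ~7 overall —
the regime a rainfed/irrigated Mediterranean series shows.

**Variance structure.** The `var_*` fields are *relative shares*
(defaults G/E/G×E/resid = 0.10/0.73/0.12/0.05). Because the environment
effect is pinned to the planted group slopes and the moisture spread, the
absolute scale is anchored to the realized moisture-driven environment
variance; the other components are scaled to it. Nothing else would let
the planted slopes and the planted variance shares hold simultaneously.
Realized plot-level shares recover the configured ones within ±0.05 at
the default scale (asserted at 200 × 18); in the default study the
residual and the unresponsive genotypes push a few points from E into the
apparent G×E share, as they would in a real unreplicated-entry trial.

**Genomes.** Near-fully homozygous dosages (2% residual heterozygous
calls, 0.2% missing) as expected for inbred lines; subpopulation
structure by allele-frequency drift (SD 0.10); local LD by copying
founder haplotypes (3 per 20 Mbp block per subpopulation, with 2%
mutation). The built-in curation pass makes every retained marker satisfy
the MAF/het/missing filters by construction, and violating markers can be
planted deliberately to exercise the filter.

**Moisture response.** Per-genotype slope deviations are N(0, 1)
kg/ha/mm by default, or planted exactly via `planted_slope_dev`. A
configurable fraction (default 5%) of genotypes is *null*: flat across
all environments, the ground truth for class 5. To keep the environment
means on the configured group trends despite the flat nulls, the
responsive genotypes' environment response is inflated by 1/(1−f). QTL
carry both a main effect (260 kg/ha per allele — each of the six loci
then explains roughly 6% of the combined-context variance, matching the
notion that a handful of loci carries most of the mappable signal) and a
moisture interaction (0.5 kg/ha/mm per allele), so marker effects
genuinely interact with the environment.

**Climate.** Stage moistures are Dirichlet shares of the environment
total, with the agronomic stress signature — stressed environments
deplete flowering and grain-fill moisture relative to the vegetative
stage — so the two regimes are separable in climate space, as the
mega-environment clustering presumes. Pre-sowing moisture and stage
maximum temperatures carry independent noise.

**What the generator does not emulate** — and hence what green tests do
*not* certify about real data: spatial field trend and neighbour effects;
meiotic recombination and pedigree structure (LD is block-wise, not a
recombination map); weather as a process (stage values are draws, not a
water-balance model); genotype-by-management interaction beyond treating
each management as an environment; and measurement artefacts such as
harvest errors or lodging. Passing tests certify the statistical
machinery, on data with the planted correlation structure.

## Reproducibility

Every stochastic function takes its seed from the configuration and runs
under `withr::with_seed()`, so the global RNG state is left untouched and
a fixed seed reproduces results byte-for-byte (asserted). Sub-stream
seeds are derived deterministically and stay below 2³¹.

# Numerical choices and degenerate inputs

* Missing two-way cells for AMMI are imputed by iterated row+column
  expectation to 1e-6, iteration count logged.
* Interaction SS below ~1e-10 (relative to the squared grand mean) is
  treated as numerically zero: no significant IPCs, AWAI all zero.
* Mean imputation of missing dosages is used for association tests only,
  never for curation statistics.
* The REML profile in the mixed model is optimized on a log-λ grid of 33
  points on [e⁻⁸, e⁸] followed by golden-section refinement.
* KASP rank ties at the extremes boundary are broken by genotype id;
  `p = 0` underflow is floored at the smallest double before taking LOD.
* Problem sizes in the test-suite simulations (e.g. 200 × 18 trials for
  share recovery; 20 seeds × 200 genotypes × 500 markers for GWAS
  calibration) are the smallest at which the checked properties are
  stable, which keeps the default test run fast on one CPU.

# Known limitations

* Narrow-sense heritability (pedigree/REML) is out of scope.
* The augmented-design standard errors are approximate (check-ANOVA
  based), not the full mixed-model standard errors.
* The mixed model fits one variance ratio on the null model (P3D); exact
  per-marker REML would be slower and marginally more powerful.
* `variance_partition()` uses mean-based sums of squares — exact for
  balanced and near-balanced layouts, approximate under severe
  unbalancedness.
* Mega-environment clustering can flip boundary environments between
  groups in noisy draws; downstream group statistics inherit that
  uncertainty, as they do in real series.
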