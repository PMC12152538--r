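---
title: "Methods: synthetic morphometric covariance workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic morphometric covariance workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphocov)
```

## Purpose and scope

`morphocov` implements an end-to-end analysis workflow for studying how
regional brain volumes co-vary across individuals stratified by CSF
Alzheimer's-disease biomarker status, together with a synthetic cohort
generator that lets every stage be validated by parameter recovery. The
workflow covers:

1. cohort simulation (biomarker groups, ages, sexes, ICV, per-region
   volumes with block covariance, imaging sessions with QC scores);
2. cohort preparation (inclusion rules, QC gating, session averaging,
   ICV adjustment with optional bilateral merging, A/T group
   assignment);
3. structural covariance networks (SCNs) and graph metrics;
4. a cluster-separability statistic (SGCC) on 2-D embeddings;
5. per-region logistic associations and a regularised volume-based
   classifier;
6. random-effects (REML) meta-analysis with BH false-discovery-rate
   control;
7. a spin-test spatial null for parcel-map overlap.

All data in this package are synthetic. Published effect sizes from any
real cohort are **not** targets: the generator emulates study
*conditions* (group sizes, age structure, cutoffs), and correctness is
established through oracles, invariants and parameter recovery, not by
matching clinical results.

## Cohort generator

### Model

For group $g$ with $n_g$ subjects and $R$ regions, standardized latent
volumes are drawn as $Z \sim N(0, \Sigma_g)$ with

$$\Sigma_g = \rho_g B + (1-\rho_g) I,$$

where $B_{ij} = 1$ when regions $i$ and $j$ belong to the same
anatomical block (subcortical, frontal, temporal, ...). This family is
positive definite for $\rho_g \in [0, 1)$ and gives a single knob per
group for how tightly volumes co-vary — the property the SCN stage is
supposed to detect. Mean structure is added on the standardized scale:

$$\text{latent}_{ij} = Z_{ij} + \delta_{j,g} + s_\text{age}(\text{age}_i - 65)
  + s_\text{sex}\,[\text{male}_i],$$

with region/group shifts $\delta$ from an *effect map*. Raw volumes are
$v_{ij} = b_j (1 + c_v\,\text{latent}_{ij})\,(\text{ICV}_i / \overline{\text{ICV}})$,
where $b_j$ is a fixed per-region base volume (mm^3) and $c_v = 0.1$ the
volume coefficient of variation. Subjects expand into 1–2 imaging
sessions with multiplicative noise (SD 1%) and per-region QC scores;
sessions are drawn to fail the QC gate with probability
`qc_fail_prob`.

CSF biomarkers are drawn uniformly within a margin on the
group-appropriate side of the cutoffs (A+ iff ABR < 0.082; T+ iff
p-Tau181 > 41.8 pg/mL), so boundary behaviour of the classifier rules is
exercised constantly.

### Default parameters (the emulated study conditions)

| parameter | default | unit / meaning |
|---|---|---|
| group sizes | control 60, A+T− 25, A+T+ 121, other dementia 100 | subjects |
| age means | 63.1 / 74.8 / 69.2 / 68.9 | years, per group as above |
| $\rho_g$ | 0.45 / 0.35 / 0.25 / 0.30 | within-block covariance strength |
| effect map | amyloid: −0.6 SD on thalamus, amygdala, ventral DC, cerebellum, brain stem; tau (A+T+): +0.8 SD extracerebral CSF, −0.6 SD lateral ventricle | standardized shifts |
| sex | P(female) = 0.431; males +0.2 SD all regions | — |
| ICV | mean 1.45e6, SD 1.3e5 | mm^3 |
| age slope | −0.02 SD per year from age 65 | — |
| sessions | 70% one, 30% two; QC fail probability 5% | — |

The $\rho_g$ ordering (controls most connected, A+T+ least) and the
effect-map directions were fixed once, a priori, from the qualitative
pattern the workflow is meant to detect, and are **not** tuned to any
test outcome. The default region list has 52 entries: 18 non-cortical
structures plus 34 cortical parcels; the exact composition is
configurable (`region_names`, `block_assignment`) and carries no claim
of matching any particular atlas.

### Scope and limitations of the generator

* Covariance is exchangeable within blocks; real SCNs have richer
  topology (hubs, distance dependence). The generator supports recovery
  tests of *contrasts* in connectedness, not of realistic network shape.
* Biomarkers are independent of volumes given the group label, so the
  group label is the only path from biology to morphometry.
* QC failure is session-wide (one level shared by all regions plus
  small jitter), which makes the mean-subcortical-QC gate nearly
  deterministic per session by design.

## Preparation stage

Sessions are kept when their **mean subcortical QC is strictly greater
than 0.65**; surviving sessions are averaged per subject. Inclusion
requires age ≥ 50 years and an MRI-to-lumbar-puncture interval within
±1 year. Volumes are merged by **summing** the inputs of each output
region (so bilateral merging conserves volume) and divided by ICV.
A/T status uses strict inequalities — a value exactly at a cutoff is
negative — and A−T+ subjects are excluded. Every dropped row is
accounted for in a `drop_log` attribute.

## Structural covariance networks

Edges are partial Pearson correlations between region pairs after OLS
adjustment for age and sex, Fisher z-transformed
($z = \operatorname{atanh} r$ with $|r|$ clipped at $1 - 10^{-15}$).
Proportional thresholding keeps the $k = \operatorname{round}(p\,N(N-1)/2)$
strongest **signed** edges ($p = 0.35$ by default), with row-major
first-occurrence tie-breaking so results are deterministic. If the
thresholded graph is disconnected the package either raises an error or
augments it with maximum-spanning-tree edges of the full weight matrix
(Prim's algorithm), flagging the augmentation.

Shortest paths are computed by a vectorised Floyd–Warshall pass — one
engine for binary (unit lengths) and weighted ($1/w$ lengths) modes.
Metrics: characteristic path length (mean distance over ordered pairs),
global efficiency (mean inverse distance), nodal and global clustering,
and small-worldness defined as global clustering divided by path
length.

### Why binary metrics are the default

Graph metrics support both a binary and a weighted mode
(`graph_metrics(net, mode = )`). **Binary is the default** for two
reasons, both recorded here as this package's own design call:

1. *Scale.* At 35% density a connected binary graph has path length in
   $[1, 2]$ and efficiency/clustering of the same order as commonly
   reported SCN values; weighted $1/z$ path lengths on Fisher-z networks
   land around 6–10, a different scale altogether.
2. *Sensitivity.* In recovery simulations the Onnela weighted clustering
   (with max-normalised weights) is nearly invariant to the generator's
   $\rho$ contrast (recovery rate ≈ 0.78), while binary clustering and
   small-worldness recover it essentially always. A metric that cannot
   see the effect it is supposed to measure is a poor default.

The weighted mode remains available and is oracle-tested (Dijkstra
distances via igraph, Onnela clustering by explicit triple loop).

Group comparisons of nodal metric distributions use two-sided Wilcoxon
rank-sum tests — exact when both sides have ≤ 12 untied values,
normal approximation with continuity correction otherwise — with BH
adjustment across group pairs within each metric.

## Separability (SGCC)

Volumes are standardized and embedded in 2-D (PCA by default; classical
MDS and external coordinates also supported). The standardized global
clustering coefficient is

$$\mathrm{SGCC} = \frac{\bar d_\text{between} - \bar d_\text{within}}
  {\max(\bar d_\text{between}, \bar d_\text{within})} \in [-1, 1],$$

with within-label pair distances pooled across labels and the degenerate
$0/0$ case defined as 0. Strata (e.g. sex) are processed independently;
a stratum failing the preconditions yields an `NA` row plus a warning
rather than aborting the run.

## Association and classification

Per-region association is a logistic regression of group membership on
the standardized ICV-adjusted volume plus age and sex; regions with
uncorrected p < 0.05 are flagged as selected features. The solver is a
single Newton iteration with step-halving covering three estimators:
plain MLE, Firth's bias-reduced likelihood (Jeffreys-prior penalty,
finite under complete separation; score
$U^*_j = \sum_i (y_i - p_i + h_i(\tfrac12 - p_i))x_{ij}$ with $h_i$ the
hat diagonal), and ridge with an unpenalized intercept. The classifier
stage uses a seeded stratified 75/25 split, 3×3-fold cross-validation
over a penalty grid `seq(0.001, 0.1, 0.001)` maximising accuracy (ties
resolved toward the largest penalty), optional minority up-sampling
inside training folds only, AUROC by the rank (Mann–Whitney) statistic
with ties at half credit, and a 2000-sample stratified percentile
bootstrap CI.

## Meta-analysis and FDR

Per-cohort log-odds are pooled under the random-effects model
$y_i \sim N(\mu, v_i + \tau^2)$ with $\tau^2$ maximising the restricted
likelihood by bounded 1-D optimisation (bound $10 k \max v_i$, doubled
with a warning if hit; explicit $\tau^2 = 0$ boundary check). Regions
enter the pooled table when significant in at least one cohort; a region
estimable in only one cohort passes through flagged as $k = 1$. BH
adjustment is applied across pooled regions. `metafor` and a dense
$\tau^2$ grid serve as independent cross-checks in the test suite, never
as the implementation.

## Spatial correspondence

The spin test rotates parcel centroids on the unit sphere with Haar
rotations (QR of a Gaussian matrix, determinant forced to +1), reassigns
each rotated centroid to the nearest original centroid (maximum inner
product, many-to-one allowed), and recomputes Dice overlap with each
network. The one-sided p-value is
$(1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n_\text{perm})$, so it can
never be exactly zero. The synthetic parcellation places centroids on a
deterministic Fibonacci lattice and partitions them into contiguous
networks by nearest-seed assignment.

## Validation strategy

* **Oracles**: igraph distances and local clustering (binary and
  weighted via $1/w$ Dijkstra), brute-force Onnela clustering, exhaustive
  graph enumeration on $N \le 5$ plus seeded random connected graphs at
  $N = 6, 7$; `glm` for MLE logistic; closed-form 2×2 log odds ratios and
  the half-cell-corrected Firth 2×2; penalized-likelihood grids;
  `metafor` (REML and DL) and dense $\tau^2$ grids; hand-computed BH;
  pairwise-concordance AUROC; full-enumeration exact Wilcoxon.
* **Invariants**: edge count $k$, mean degree $2k/N$, Fisher-z
  antisymmetry, SGCC bounds under fuzzing, spin p > 0, Dice bounds.
* **Parameter recovery** (seeded): the $\rho$ contrast is detected in
  ≥ 90% of 100 replicates; a −0.8 SD injected effect recovered with sign
  and p < 0.05 in ≥ 95% of 50 replicates at n = 100/group; a null
  generator yields ≈ 5% per-region selection and meta-stage FDR ≤ 5%;
  REML 95% CI coverage over 200 four-cohort replicates falls in
  [90%, 99%]; spin-test null p-values are approximately uniform
  (KS < 0.1 across 200 runs at 199 permutations — a bound with a small,
  accepted Monte-Carlo flake probability). The calibration reads the
  p-value at the **largest** network: Dice granularity scales with
  network size, and on very small networks frequent ties with the null
  make the (still valid) p-values conservative rather than uniform, so
  uniformity is only a meaningful assertion where the statistic is
  reasonably fine-grained.

Problem sizes in these studies (replicate counts, group sizes,
permutation counts) are the package's own validation choices, sized to
finish in minutes on one CPU.

## Reproducing the analysis

The numbered drivers under `analysis/` run the workflow over a seeded
synthetic cohort and write everything under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prepare.R
Rscript analysis/03_scn.R
Rscript analysis/04_separability.R
Rscript analysis/05_association.R
Rscript analysis/06_meta.R
Rscript analysis/07_correspondence.R
```

`run_pipeline(pipeline_config(seed = ...), out_dir)` performs the same
stages programmatically with per-stage derived seeds, a dependency
check, and a manifest holding the configuration snapshot and MD5 hashes
of every output file. `scripts/acceptance.R --seed <int> --out <path>`
recomputes the headline validation quantities as JSON.

## Limitations

* Synthetic volumes are linear-Gaussian; no site effects, scanner
  effects, or non-linear atrophy trajectories.
* The SGCC is computed on a 2-D embedding; separability visible only in
  higher dimensions is missed by construction.
* The spin test's nearest-centroid reassignment is many-to-one, so a
  rotated map can drop or duplicate parcels; this follows the standard
  centroid-based spin construction and its known limitations.
* Wald inference is used throughout the logistic and meta-analytic
  stages; profile or exact intervals are out of scope.
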