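---
title: "Methods: regional SUVR screening and metabolic covariance network comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional SUVR screening and metabolic covariance network comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suvrnet)
```

## The analysis problem

Regional FDG-PET uptake proxies glucose metabolism. In a multi-group
clinical cohort (controls plus disease groups such as hypertension, type 2
diabetes, obesity and gout), the questions this package addresses are:

1. Which brain regions show altered metabolism in a disease group,
   once age and sex composition differences are removed?
2. Which clinical blood biomarkers track regional metabolism, after
   adjusting for age, sex and BMI?
3. Does the *covariance structure* of regional metabolism — the
   metabolic covariance network — differ between a disease group and
   controls, edge by edge?

The processing chain is: SUVR normalization → age/sex residual
correction → per-region two-group t screening → per-pair partial
correlation screening → group covariance networks with sparsity
thresholding → edge-wise permutation inference.

## SUVR and the cerebellar reference

Regional uptake is normalized per subject as
$\mathrm{SUVR}_r = \mathrm{SUV}_r / \mathrm{SUV}_{\mathrm{ref}}$, where
the reference is the mean over the cerebellar labels of the atlas
(`atlas_aal90()` marks labels 91–116 as reference; 1–90 are the analysis
regions). When ROI tables carry voxel counts, the reference mean is
voxel-count weighted; otherwise unweighted. SUVR is dimensionless and
invariant to any per-subject global intensity scale, which is the point
of the normalization. `extract_roi_means()` ignores non-finite voxels
because spatially normalized PET volumes commonly pad the outside of the
brain with NaN.

The atlas ships with the standard 90 AAL cerebral region labels. The
node coordinates in `atlas_aal90()` are a *synthetic schematic layout*
(left/right at ±40 mm, ordered along y), adequate for writing
BrainNet Viewer node files and building toy label volumes; they are not
MNI centroids, and users with real data should supply their own centers
via `atlas_spec()`.

## Age/sex correction

Disease and control groups often differ in age and sex composition, so a
raw group comparison of SUVRs is confounded. The correction regresses
each region's SUVR on age and sex (OLS with intercept), keeps the
residual, and adds back a recentering constant so values stay on the
SUVR scale:

* `fit_scope = "pooled"` (default): one fit over both groups of the
  contrast; the constant is the *pooled* per-region mean. Group-mean
  differences attributable to age/sex composition are then removed —
  under an age-confounded null the corrected group difference is
  centered at zero. This matches the motivation for correcting in the
  first place (the compositions differ between groups).
* `fit_scope = "per_group"`: separate fits within each group; the
  constant is the per-group mean. Because per-group OLS residuals sum
  to zero, group means are preserved *exactly* — this scope denoises
  but deliberately does not shift group means.

A design note: adding back *per-group* means after a *pooled* fit would
reintroduce exactly the confounded mean difference, defeating the
correction; that combination is therefore not offered. BMI is never a
correction covariate — it enters only the partial-correlation screen.
The correction is fitted per disease-vs-control contrast, not once
globally, since each contrast pools a different pair of groups.

## Screening

**Regions.** Per region, a two-tailed independent t-test compares
corrected SUVRs between the groups. A two-sided F test of variance
equality at α = 0.05 selects the pooled-variance Student test or
Welch's test with Satterthwaite degrees of freedom
(`variance_rule = "always_welch"`/`"always_student"` force either).
Regions are flagged at uncorrected p < α (default 0.05); this is an
exploratory screen, and Benjamini–Hochberg adjustment is available via
`adjust = "BH"`. Degenerate input (zero variance in both groups with
equal means) returns p = 1 by convention.

**Biomarkers.** For each (region, biomarker) pair,
`partial_correlation()` residualizes both variables on the covariates
(age, sex, BMI by default) and correlates the residuals;
$t = r\sqrt{df/(1-r^2)}$ with $df = n - 2 - k$. The residual
formulation agrees with the precision-matrix formulation to numerical
precision (tested to 1e-10). Missing biomarker values are handled by
complete-case omission *per pair*, so n varies across pairs exactly as
it does in practice when different indicators have different coverage;
pairs with n < k + 3 are skipped with a warning. Subjects missing BMI
drop out of the partial-correlation screen but not the t screen.

## Metabolic covariance networks

Within one group, the network weight between regions i and j is the
across-subject Pearson correlation of their SUVRs. This is the standard
metabolic covariance construction: it is a *group-level* network, and a
"subject" is a sample point, not a network.

**Sparsity thresholding.** The weighted network is binarized by keeping
the top $m = \mathrm{round}(S \cdot n(n-1)/2)$ edges of the descending
edge ranking (half-up rounding, so m is reproducible across platforms;
for n = 90 and S = 0.35, m = 1402). Ranking uses signed r by default —
binarized "connectivity" conventionally keeps the strongest positive
couplings — with `rank_by = "absolute"` as the alternative. Ties break
lexicographically in (i, j), which makes edge sets nested in S.

**Percolation threshold.** `min_connected_sparsity()` finds, by
incremental union-find over the same ranking, the smallest edge count
whose graph spans all nodes in one connected component, and reports it
as a sparsity S\*. This "sparsest fully connected network" value is the
natural common threshold for comparing groups: below it, some node is
disconnected and node-level graph measures are undefined. Small cohorts
have larger S\* (the gout-sized 14 vs 14 design typically needs a much
denser threshold than the large contrasts), which is why the package
lets S be set per contrast or as `"auto_min_connected"`.

**Modularity.** `modularity_partition()` runs Louvain community
detection (via igraph) on the binarized graph and reports Newman–Girvan
$Q = \sum_c (e_c/m - (d_c/2m)^2)$. The optimization is degenerate, so
the partition is fixed by a seed (default 0). Modularity should be
computed on a *connected* graph: below the percolation threshold,
isolated nodes become singleton modules that say nothing about
structure. The recommended practice, used throughout the package's own
validation, is to threshold at `max(S, min_connected_sparsity(net)$S)`
before partitioning.

## Edge-wise permutation inference

The observed statistic per edge is the difference in correlation,
$T_{ij} = r_{ij}(A) - r_{ij}(B)$ (group A = disease, so positive T
reads "strengthened in disease"); `statistic_mode = "fisher_z"` uses
the variance-stabilized difference instead. The null is built by
randomly reassigning the pooled subjects to two groups of the original
sizes (label shuffles sampled with replacement, standard at B = 5000)
and recomputing T. The two-tailed empirical p-value uses the add-one
estimator $p = (1 + \#\{|T^{perm}| \ge |T^{obs}|\})/(B+1)$, which is
finite-sample valid and never below $1/(B+1)$.

Implementation details worth knowing:

* The permutation space is canonicalized in the *unordered* pooled
  subject set (rows sorted by subject id, subset size anchored to the
  group containing the smallest id). Only |T| enters the p-value, so
  swapping the two input tables negates every delta and leaves every
  p-value bit-identical.
* If a permuted split leaves a region with zero variance, the affected
  edges contribute T = 0 for that permutation (counted, with a single
  warning); a zero-variance region in an *observed* group is an error.
* `compare_at_sparsity()` restricts the reported edge universe to the
  union of the two groups' binarized adjacencies at a common S,
  mirroring how connectivity differences are reported at a fixed
  sparsity; a warning is raised if S is below either group's
  percolation threshold.
* Edge-wise α = 0.05 without family-wise correction matches the
  exploratory stance of the screening stages.

## The synthetic cohort generator

Because clinical PET cohorts cannot be redistributed, validation runs
on `generate_cohort()`, which plants known truth at every level the
analysis touches:

$$\mathrm{SUVR}_{ir} = \mu_r + \delta_{g(i),r} + \beta^{age}_r\,age_i
  + \beta^{sex}_r\,sex_i + \epsilon_{ir}, \qquad
  \epsilon_i \sim N(0,\; \sigma^2 R_{g(i)})$$

with $R_g = (1-c_g)R_{block} + c_g J$: a block correlation matrix
(within-module $r_w$, between-module $r_b$) blended with a group-level
shared latent factor $c_g$ that raises every inter-regional
correlation. Shifting $c_g$ between groups plants globally
strengthened or weakened covariance connectivity with known direction.
Linked biomarkers load on the linked region's residual with
$\lambda = \rho\,\sigma_\eta/(\sigma_\epsilon\sqrt{1-\rho^2})$, which
makes the partial correlation given age, sex and BMI equal ρ in
expectation (exact construction, no rejection sampling). Missingness is
completely at random — matching the complete-case treatment downstream —
and the mask consumes its RNG draws even at rate 0 so that changing the
rate never perturbs any other generated value.

Defaults that define the emulated study conditions: baseline SUVR
μ = 1.3, residual SD σ = 0.1, β_age = −0.002 per year (≈ mild global
hypometabolism with age), β_sex = 0.02, six covariance modules with
r_w = 0.45 / r_b = 0.15 and a shared latent weight of 0.45 for the
control condition — inter-regional SUVR correlations in metabolic
covariance data are high, and these values put typical null-preset edge
weights in that realistic range. Gaussian residuals are the default
(the downstream statistics are correlation- and t-based, so Gaussianity
enables closed-form checks); `noise = "t"` provides standardized
heavier tails for robustness experiments.

The presets mirror the emulated cohort: 497 controls; 112 hypertension
(49 regions shifted −0.5 σ, the right-amygdala slot +0.5 σ, older and
more male than controls, attenuated shared latent); 56 T2DM (38 regions
down); 11 obesity (4 motor/cingulate regions up, BMI ≈ 33); and a
matched 14 vs 14 gout design (right paracentral slot up, *elevated*
shared latent, age/sex-matched groups). The planted differential-region
sets are index conventions (e.g. regions 1–49 minus the amygdala slot,
plus the right-superior-parietal slot that carries the uric-acid link),
not claims about which anatomical regions change in real disease.

What the generator does *not* emulate: non-Gaussian tails beyond the t
option, missingness that depends on disease severity (not at random),
site/scanner batch effects, spatial autocorrelation at the voxel level,
and any true inter-regional covariance of real disease groups (only the
qualitative direction of connectivity change is planted). Passing tests
therefore demonstrate the *statistical machinery* — calibration, power
at planted effect sizes, direction recovery, exactness of the
combinatorial operations — not clinical reproduction.

## Numerical and design choices

* Half-up rounding for edge counts; R's default round-half-even would
  make m parity-dependent.
* Edge ties break lexicographically in (i, j); thresholding is thereby
  monotone in S.
* p-values are never 0 (add-one estimator); t-test p = 1 for two
  constant equal groups; constant-after-residualization input is an
  error for correlations (undefined), detected with a relative
  variance tolerance of 1e-20.
* All stochastic stages restore the caller's RNG state; the pipeline
  derives one sub-seed per stage from the master seed so reruns are
  byte-identical (the run manifest carries no timestamps for exactly
  this reason).
* The control-subset matcher (greedy nearest-age within a 5-year
  caliper, exact sex) is a pragmatic stand-in: real studies report
  matched subset sizes but rarely the selection rule, so the matcher
  logs its seed and achieved balance to keep any subset auditable.

## Validation scales and known limitations

The shipped validation (test suite and `scripts/acceptance.R`) uses:
exact enumeration at 4 + 4 subjects (70 splits) against B = 10,000
Monte-Carlo permutations; 200 null simulations at B = 500 for type-I
error; 100 seeds for correction calibration; 50 random 20-node matrices
for the percolation oracle; 20 seeds of a 45 + 45-region two-block
design at n = 200 for modularity recovery; 15–25 seeds of the
hypertension-like preset for screening power; and pooled significant
edges over 5 gout-like cohorts for direction of connectivity change.

Two honest caveats from that validation. First, complete recovery of
*all 50* planted regions in a single seed happens in roughly 85% of
seeds at the planted 0.5 σ effect (per-region power ≈ 0.998 compounds
over 50 regions; the per-region flag rate is ≈ 0.99 and planted
directions are always correct) — single-seed complete recovery is a
stricter event than per-region power suggests. Second, at a sparsity
below the percolation threshold the thresholded graph fragments and
modularity partitions acquire singleton modules; the connectivity floor
described above is the remedy and is applied in all recovery analyses.

Out of scope by design: image acquisition and spatial normalization
(inputs are assumed already normalized), partial-volume correction,
weighted-graph modularity, cluster-level (network-based statistic)
inference, and graph metrics beyond those described here.
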