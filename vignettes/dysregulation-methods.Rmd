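---
title: "Methods: dysregulation scoring, reference populations, and the conservation test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dysregulation scoring, reference populations, and the conservation test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysregkit)
```

## The model

Physiological dysregulation is quantified as the Mahalanobis distance

$$D_M = \sqrt{(x - \mu)^\top S^{-1} (x - \mu)}$$

of an individual's simultaneously observed biomarker vector $x$ from the
multivariate mean $\mu$ of a reference population with covariance $S$. The
reference population operationalizes homeostasis: its centroid has distance
0, and $D_M$ grows both with unusual individual marker levels and with
unusual *combinations* of levels. The score is deliberately emergent — a
useful $D_M$ should not be a proxy for any single marker, and
`marker_score_correlations()` reports the score-vs-marker correlations as a
diagnostic (flag threshold 0.3 by default; in well-behaved multi-marker
panels the maximum |r| is typically well below 0.2).

Assumptions worth stating plainly:

* **Approximate multivariate normality** of the reference. Each marker is
  natural-log- or square-root-transformed when that improves normality in
  the reference sample, then centered and scaled by the reference mean and
  standard deviation (n−1 divisor throughout). Both the transform choice and
  the moments are *specific to each reference population*.
* **The reference mean approximates the healthy state.** Self references use
  each individual's first (youngest) observation, approximating a younger,
  presumably healthier sample.
* **Positive definiteness of $S$.** Guaranteed by requiring more reference
  members than markers and, when the condition number still exceeds a
  threshold, by minimal diagonal shrinkage (below).

## Transform selection

The selection criterion is the Shapiro–Wilk W statistic, maximized over the
admissible transforms (log requires strictly positive reference values,
square root nonnegative), with exact ties broken identity > sqrt > log. W is
bounded, comparable across transforms, and standard; for reference samples
larger than 5000 (where W is unreliable and `shapiro.test` refuses) the
criterion falls back to minimizing |skewness|. No Box–Cox or other families
are offered. This is a deliberate formalization: published analyses of this
kind chose transforms partly by hand, and an algorithmic rule is the only
reproducible stand-in.

When one population's spec is applied to another population's values, a cell
can violate the transform's domain (e.g. a nonpositive value under log). The
default policy drops the whole observation — $D_M$ needs a complete vector —
and counts it; `set_missing` is available for diagnostics only.

## Reference population schemes

* **self** — first observations of the species' own individuals.
* **cross** — identical construction, tagged for provenance; its spec, $\mu$
  and $S$ are applied to *other* species' rows. Applied back to its own
  species it reproduces self-scheme scores exactly (a tested invariant).
* **combined** — first observations pooled across species, each species
  subsampled without replacement to the minimum per-species count $m$, so
  the best-sampled species cannot dominate. The sampling unit is the
  individual (first observation), not the visit, to avoid pseudo-replication.
  The seed is mandatory and recorded in provenance. A
  `standardize_within_species` flag z-scores each species' markers within
  species before pooling; it is off by default (variable-panel runs) and
  recommended for direct cross-species comparisons, where among-species mean
  differences would otherwise dominate the pooled covariance. Both modes are
  provided because either pooling convention is defensible; the package does
  not claim one is canonical.

## Numerical choices

* **Covariance conditioning.** When `cond(S) > 1e8` (configurable),
  $S \leftarrow (1-\lambda) S + \lambda\,\mathrm{diag}(S)$ with the minimal
  $\lambda$ found by bisection. Shrinkage keeps $D_M$ a true metric and is
  reproducible, unlike a pseudo-inverse. Zero-variance markers defeat any
  diagonal shrinkage and are an error.
* **Distance computation.** Via the Cholesky factor of $S$ (triangular
  solve), never an explicit inverse; equivalence to the explicit-inverse
  quadratic form within 1e-10 is an acceptance criterion. Useful identities
  tested: scoring a reference against itself gives
  $\overline{D_M^2} = p(n-1)/n$; under the true generating moments
  $D_M^2 \sim \chi^2_p$.
* **Within-species standardization of the score** (`dm_z`) uses all scored
  visits of the species, so model coefficients are comparable across
  species. When model residuals are skewed (|skewness| > 1 by default) the
  dependent variable is recomputed as the within-species z-score of
  $\log D_M$ — transform first, then scale. The original analyses judged
  this "as needed" visually; the skewness rule is this package's documented
  convention, and the flag is carried in every model result.
* **First-observation ties** (two visits at the same minimal age) are broken
  by stable input order.
* **Boundary conventions.** Adult filtering is inclusive
  (age ≥ maturation age); plausibility bounds are an open interval with the
  bounds themselves retained; plausibility screening blanks cells rather
  than dropping rows, leaving row retention to the complete-case rule of
  panel selection. The default pipeline order is adults-then-plausibility
  (configurable; the original order is unstated).

## Association models

Per species (never pooled): `dm_z ~ age_z * sex` with random intercepts for
individual and for population, fitted by REML via lme4. Selection rules, all
tested: the individual intercept is omitted when repeated observations are
absent for ≥ 99% of individuals; the population intercept requires > 1
population; sex terms are dropped for single-sex species; rows of unknown
sex are excluded whenever a sex term is present. A preliminary pooled
all-species model with random slopes is deliberately *not* a headline
output. Inference uses the Wald normal approximation (estimate ± 1.96·SE);
lmerTest-style denominator-degree-of-freedom corrections are not available
in this environment and would change little at the tested sizes.
P-values are reported unadjusted, mirroring the source analyses' explicit
choice; adjust downstream if you test many species × sets.

Body-mass models: `mass ~ age_z + age_z² + sex + age_z:sex (+ dm_z)` with a
random age slope within individual; the mass-change model regresses the
subsequent change rate (kg/year to the next visit, attached to the earlier
visit) on sex, age, `dm_z` and their two-way interactions.

## Survival coding

Each observation opens a risk interval at its age. The interval ends at the
age of the next observation (if any), else at confirmed death (if any), else
0.25 years after the observation — the minimum inter-visit gap in the
motivating database, so unknown-status individuals are censored shortly
after last being seen even though this shortens exposure; that is a
faithfulness choice, not an efficiency one. The event is 1 only on the last
observation of an individual with confirmed death. A death age earlier than
a later observation is impossible data and a validation error, not a
censoring rule. Duplicate visit ages (and a death exactly at the last
observation age) are shifted by 1e-6 years with a warning. Cox models use
age as the timescale, Efron tie handling (ages are continuous; the
convention is stated because the source is silent), and a prespecified
screen that drops the `dm_z × sex` interaction when non-significant at 0.05.
The random center effect is a gamma frailty on population via
`survival::frailty()`; the coxme package the original analyses used is not
in this environment, and a shared-frailty term is the standard equivalent
for a single random intercept.

## The conservation test

For every ordered species pair (A, B), A's observations are scored against
A's self reference and against B's reference; the Pearson correlation of the
two score vectors is cell (A, B) of the cross-reference matrix (diagonal
exactly 1; not symmetric). Phylogenetic proximity is the negative patristic
distance — Spearman correlation makes any strictly monotone choice
equivalent, which is tested. The headline p-value is a Mantel-style
permutation test (species labels permuted jointly over rows and columns,
9,999 permutations by default, seeded): matrix cells sharing a species are
dependent, so the naive cell-independence p-value — also reported, since the
source presented plain p-values — is anti-conservative. Upper- and
lower-triangle restrictions are provided as a robustness check; note the
full-matrix rho need not lie between the two half-matrix rhos. Any
combined-reference row/column is excluded from the test (it is display
furniture). Missing cells (pairs depleted by domain violations) are deleted
pairwise, erroring beyond 20% missingness.

## The synthetic world

`simulate_cohort()` emulates the *structure* of multispecies research-center
biomarker panels, not any real species' units or reference ranges:

* **Phylogeny:** coalescent-style ultrametric tree (depth 60 million years
  by default, echoing the span of the primate radiation), or a user tree.
* **Species divergence:** marker means evolve by Brownian motion
  (σ_phylo per √My, default 0.1); correlation structure evolves down the
  tree by blending the parent correlation toward an edge-specific random
  target with weight 1 − exp(−κ·edge length/depth), so sister species share
  correlation history. Convexity of the blend guarantees positive
  definiteness; base marker variances are preserved (this is the package's
  reading of "correlation-preserving" divergence). At σ_phylo = κ = 0 all
  species are identical — a tested limit — and the median off-diagonal
  cross-reference correlation decreases in κ (tested on paired seeds).
* **Aging signal:** dysregulation is generated as residual dispersion
  *inflation* around the species centroid (factor 1 + γ·standardized age,
  default γ = 0.15), not mean drift — matching the definition of $D_M$ as
  deviation from the homeostatic centroid. γ is the recoverable quantity.
* **Mortality:** Gompertz hazard h₀·exp(b·(age − maturation)) multiplied by
  exp(β·dm_z) with the *latent* standardized score, piecewise-constant
  between visits, sampled exactly by inversion of the piecewise cumulative
  hazard. Defaults h₀ = 0.02/y, b = 0.08/y, β = log 1.5 (the hazard ratio
  magnitude reported for the species where dysregulation predicted
  mortality). Because mortality depends on the latent score, hazard ratios
  fitted on the *estimated* score are attenuated by scoring noise; the Cox
  recovery acceptance band [1.35, 1.65] around HR 1.5 absorbs that
  attenuation (observed mean ≈ 1.45 at n = 300 individuals, 12 markers).
* **Design defaults** (100 individuals/species, mean 4 visits at mean 1-year
  gaps with a 0.25-year floor, adult window 5–30 years, even sexes with a
  +0.25 raw-unit male offset) sit inside the ranges of the motivating
  cohorts (25–2,463 individuals, 1–15 visits/individual). Species can be
  flagged single-sex or single-visit to exercise those model paths, and
  per-species marker-availability masks reproduce the variable-panel
  ("Set 1") versus fixed-panel ("Set 2") distinction; panels are complete
  before masking, so masks are the *only* source of missingness.
* **Mass:** species intercept + linear/negative-quadratic age trend +
  individual level; `dm_z` moves the subsequent change *rate*
  (default slope 0: the null world, matching the empirical finding of no
  association between the score and mass).

What a green test does **not** establish: the generator is multivariate
normal by construction, visits are missing-at-random, hazards are
proportional, and availability masks are the only missingness mechanism.
Real cohorts violate all four (lab drift, informative visit schedules,
non-normal markers), so green acceptance demonstrates *method correctness
under the stated world*, not robustness to real-data pathologies.

## Acceptance configurations

The acceptance suite fixes its simulation designs a priori: mixed-model
recovery at a standardized age slope of 0.30 (200 individuals × 4 visits,
100 replicates); Cox recovery at HR 1.5 (300 individuals, 50 replicates);
conservation detection at the largest κ of the grid {0, 0.3, 0.6, 1.0} with
σ_phylo = 0.3 over 12 species of 80 individuals (100 replicates, 999
permutations per test — the module default stays 9,999; 999 is ample to call
p < 0.05 and keeps the suite inside its time budget; the null uses 50
replicates for the same reason). Twelve species are used because Mantel
permutation power is driven as much by the number of labels as by the effect
size; at 8 species the same effect is detected in only ~90% of replicates.

## Known limitations

* Linear age effects only; no nonlinear age models.
* No alternative dysregulation indices (allostatic-load sums, PCA
  distances), no age- or sex-stratified references, no multiple-testing
  adjustment by default, no phylogenetic comparative models beyond the rank
  matrix correlation (no PGLS, no Pagel's λ).
* Mixed-model inference is Wald-normal; at very small n_ids the intervals
  will be slightly anti-conservative.
* The synthetic generator's covariance divergence is exchangeable across
  markers; it does not emulate structured physiology (organ-system blocks).
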