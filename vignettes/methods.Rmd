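---
title: "Models and methods behind staygreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind staygreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
design was genuinely open.

## 1. Senescence model and canopy traits

After heading, a healthy wheat canopy holds close to 100% green leaf
area and then yellows in a sigmoidal decline. We model the scored green
fraction $y$ (percent) on the thermal-time scale as the logistic power
function

$$y(TT) = \frac{100}{1 + (TT/\mathrm{GLA}_{50})^{s}},$$

with $TT$ the cumulative sum of daily mean temperatures above a 0 °C
base from the day of sowing (°Cd). The parameterisation has two useful
exact properties: $y(\mathrm{GLA}_{50}) = 50$ whatever $s$, and the curve
is strictly decreasing for $s > 0$. Derived traits:

* green canopy duration $\mathrm{GCD} = \mathrm{GLA}_{50} - TT_\mathrm{heading}$
  (°Cd), the post-heading life of at least half the canopy;
* leaf area duration
  $\mathrm{LAD} = \mathrm{LAI}_{max}\int_{TT_\mathrm{heading}}^{TT_\mathrm{harvest}} y(TT)/100\, dTT$
  (°Cd), integrated green area weighted by maximal canopy size;
* grain-filling duration $TT_{\mathrm{BBCH87}} - TT_{\mathrm{BBCH59}}$ (°Cd).

**Assumptions.** The canopy is fully green at heading (disease-free,
fungicide-protected trials); the decline is monotone; visual scores are
unbiased up to symmetric observation noise.

**Numerical choices.**

* *Base-temperature truncation.* Days with a negative mean contribute 0
  °Cd. A base of 0 °C is standard for winter wheat; whether sub-zero
  days subtract heat is rarely stated — truncation is the standard
  agronomic convention and is what we implement and document.
* *Fit initialisation.* The model is linear in disguise:
  $\log(1/\hat y - 1) = s\,\log TT - s\,\log \mathrm{GLA}_{50}$, so the
  steepness starts from the slope of that regression on interior points
  and $\mathrm{GLA}_{50}$ from linear interpolation of the 50% crossing.
  Scores of exactly 0 or 100% are nudged by $10^{-4}$ *only* for this
  initialisation, never for the least-squares objective.
* *Bounds and restarts.* L-BFGS-B with $s \in (0, 200]$,
  $\mathrm{GLA}_{50} \in (0, 2\max TT]$; up to 10 jittered restarts on a
  data-derived local RNG stream (the caller's RNG state is untouched),
  after which the fit is flagged unconverged and downstream traits are
  reported missing.
* *Scale invariance.* Input may be percent or fraction; everything is
  rescaled internally, so published fits on either scale are reproduced
  identically.
* *Quadrature.* LAD uses adaptive quadrature with absolute tolerance
  $10^{-8}$ on the unit-scaled integrand; the tests pin it against a
  dense trapezoid oracle at $10^{-5}$ relative and against the analytic
  step-function limit for large $s$.
* *Degenerate inputs.* Fitting requires at least 3 points and at least
  one score below 50% ("insufficient senescence signal" otherwise): the
  decline must constrain the curve. The harvest bound of the LAD
  integral is configurable because its exact definition (physiological
  maturity vs combine date) is a trial-protocol choice.

## 2. Trial mixed model, BLUEs, heritability

Plot values are modelled as
$P_{ijkl} = \mu + c_i + y_j + cy_{ij} + YR_{jk} + YRG_{jkl} + e_{ijkl}$:
cultivar, season and their interaction fixed; the replicate-within-season
and sub-group-within-replicate blocks random. We fit by REML with lme4 —
the de-facto standard engine for exactly this model class — rather than
hand-rolled iterations; the test suite keeps an independent route, a
closed-form expected-mean-squares (Henderson) oracle on balanced data,
against which the REML estimates must agree to ~$10^{-6}$ (the
three-level season variance is checked one digit looser because its
profile likelihood is extremely flat).

* *BLUEs* are estimated marginal means: cultivar × season cells are
  predicted from the fixed part and averaged over seasons with **equal
  weight** (the estimated-marginal-means convention), not by cell
  counts. On balanced noise-free data the BLUE is the arithmetic mean.
* *Noise-free data* make REML degenerate (zero residual variance), so
  the fitter falls back to ordinary least squares and reports zero
  block variances — this keeps the degenerate test cases exact instead
  of numerically fragile.
* *Heritability* uses the fully random version of the same model
  ($H^2 = \sigma^2_C / (\sigma^2_C + \sigma^2_{CY}/n + \sigma^2_e/(nr))$).
  The design-block variances are estimated but deliberately do not enter
  the denominator, matching the entry-mean definition. Negative variance
  estimates are handled by boundary projection to zero (lme4's
  behaviour); how the original tooling handled them is not documented
  anywhere we could verify, and projection is the common default.
* *Term significance* is reported from sequential model comparison:
  F-tests when the model is pure fixed effects, likelihood-ratio tests
  on ML fits when random blocks are present. The exact denominator-df
  recipe behind published F-tests is generally unstated; sequential
  model comparison is self-consistent, and the simulation suite checks
  its operating characteristics (power ≈ 1 under planted effects,
  type-I error ≈ 5% under the null) rather than its labels.
* *Missing plots* are handled by fitting on the available cells; no
  imputation.

## 3. Breeding progress

Cultivars with a known year of release are ordered by that year (ties
broken by name, so results are deterministic) and grouped into
overlapping windows of 10 cultivars, stride 1 — $n - w + 1$ windows. The
regression of *window means* on *window mean years* is the reproduction
convention: published progress figures plot exactly these dots and their
regression line. A non-overlapping mode exists behind a flag for
sensitivity analysis.

Relative four-decades progress is defined as percent superiority,
$100\,(\hat y(2010)/\hat y(1970) - 1)$. We chose this over the raw ratio
because it is the definition consistent with the worked numbers the
definition must reproduce (a 7.55 t/ha baseline with slope 0.059
t/ha·yr gives 31.3%, not 131%). It errors when $\hat y(1970) \le 0$,
where a ratio on the trait scale is meaningless.

The segmented regression is the continuous two-phase fit
$y = \beta_0 + \beta_1 x + \beta_2 (x - bp)_+$ with $bp$ chosen by
exhaustive search over the observed window-mean years (at least two
points per phase). Continuity at the breakpoint is enforced — whether
published segmented fits did so is unstated, but a discontinuous fit
would confound a trend change with a level shift. Exact ties resolve to
the earliest candidate with a warning, and a fit that improves the RSS
of the single line by less than 1% is flagged as "no breakpoint
support".

## 4. Association scan

* *QC*: markers are kept when polymorphic, ≤ 10% missing, MAF ≥ 5% —
  the same three rules used for the 45,370-marker panels this module
  emulates; the QC report carries per-rule drop counts, and the output
  provably satisfies its own thresholds.
* *Kinship*: VanRaden realized relationship,
  $K = Z'Z / (2\sum p(1-p))$ from marker-centred dosages, mean-imputed
  for this computation only. Symmetric PSD by construction.
* *Structure*: PCA on the centred dosage matrix, k-means (25 restarts,
  seeded) on the components explaining 80% of the variance (a
  configurable default — the number of components retained before
  clustering is typically unreported), groups entering the model as
  indicator covariates. This approximates discriminant analysis of
  principal components: only the group memberships are consumed
  downstream, so the discriminant step itself is omitted.
* *Scan*: the exact one-random-effect mixed model
  $y = Xb + g_m m + u + e$, $u \sim N(0, \sigma^2_g K)$. The variance
  ratio $\delta = \sigma^2_e/\sigma^2_g$ is REML-profiled **once** on
  the null model after a spectral decomposition of $K$; each marker is
  then tested by generalised least squares at that ratio. This is the
  standard population-scale approximation (EMMAX-style): exact,
  deterministic, no per-marker REML. Markers with missing calls are
  tested on the reduced cultivar set with a direct Cholesky solve of
  the subset covariance (the inverse of a submatrix is not the
  submatrix of the inverse).
* *Explained variance* per marker is defined as the squared correlation
  between dosage and the structure-adjusted phenotype, in percent — the
  quantity is rarely given a formula in publications, so we state ours.
* *Thresholds*: Bonferroni $-\log_{10}(\alpha/m)$ and Benjamini–Hochberg
  step-up at the stated FDR (whether published FDRs used q-values or BH
  is typically unstated; BH is implemented and labelled as such).
* *LD* $r^2$ is the squared Pearson correlation of dosages,
  pairwise-complete, with era-subset means available for
  release-era comparisons. *Allele burden* counts minor alleles over a
  region and tests additivity by an F lack-of-fit comparison of the
  linear burden regression against saturated per-count means — the
  diagnostic that flags, e.g., an effect saturating after one allele.

## 5. The synthetic-data generator: its stated world

The generator emulates the structure of a German winter-wheat
breeding-history trial: **174 cultivars released 1966–2013** (release
years sampled with 66% weight on the last two decades, reflecting how
such collections are composed), **3 seasons × 2 replicates**, cultivars
randomised within **4 sub-groups**, plus the random structure of the
trial model with per-trait variance components. Default trait trends
mirror the magnitudes reported for such panels: grain yield
0.04 t/ha·yr, grains per spike 0.16 yr⁻¹, GCD ≈ 2 °Cd·yr⁻¹. Genotypes
are biallelic dosages on the 21 bread-wheat chromosomes from **5
subpopulations** (Balding–Nichols differentiation, $F_{ST}$ 0.15 —
a realistic degree of structure for European cultivar panels), mostly
homozygous with a small hybrid fraction (mirroring the 5 hybrids such
panels contain), with MCAR missingness and an optional causal region
whose minor alleles shift one trait.

Decisions worth recording:

* *One root seed, one derived stream per random term* (genetic, G×E,
  blocks, residual, each genotype stage). Adding a trait or term never
  perturbs the draws of another — the tests assert this bit-exactly.
* *Release years with replacement.* A span of 48 years cannot host 174
  distinct years; several releases per year is also what real
  collections look like.
* *Season main effects* are fixed offsets (default zero) rather than a
  variance component: with only 3 seasons a "season variance" is
  ill-estimated, and the trial model treats season as fixed anyway. The
  mixed-model oracle tests set non-zero offsets explicitly.
* *Scoring noise* is truncated Gaussian, clipped to [0, 100]%: the true
  noise model of visual scores is unknown (nobody publishes it), and
  clipping — rather than resampling — is simple and testable. This is a
  stand-in and is flagged as such.
* *What a green test does not establish*: the generator has no spatial
  field trend, no disease pressure, no scoring-date irregularity, no
  genotype-by-management interaction, and LD only through population
  structure (markers are conditionally independent given the group).
  Recovery of planted truth here validates the estimators' arithmetic
  and their behaviour under the stated stochastic structure — not
  robustness to field artefacts.

## 6. Known limitations

* The association module fits one trait, one marker at a time; no
  haplotype-block models, no multi-locus shrinkage.
* Sequential LRTs for fixed terms are asymptotic; at very small panel
  sizes they run slightly liberal (visible, and bounded, in the type-I
  simulation).
* The segmented fit searches one breakpoint only.
* The VCF writer is minimal (GT field, placeholder alleles) — adequate
  for round-tripping simulated dosages, not a general-purpose exporter.
* BLUE standard errors ignore the uncertainty of the estimated variance
  components, as is conventional.
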