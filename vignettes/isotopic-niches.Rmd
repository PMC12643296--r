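---
title: "Isotopic niche estimation and stressor linkage in small water bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopic niche estimation and stressor linkage in small water bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swbniche)
```

`swbniche` quantifies the isotopic niches of benthic invertebrate
communities in agricultural ponds and ditches and relates them to
measured stressors. This vignette documents the models, the parameters
that matter, the numerical choices, and the limits of what the synthetic
test bed can demonstrate.

## The data model

An analyzed sample is one tin capsule — a single ground specimen or a
pooled set of conspecifics — with a site, a water-body type (`pond` or
`ditch`), one of six functional feeding groups (collector/filterer,
collector/gatherer, grazer/scraper, omnivore, predator, shredder), and a
(δ¹³C, δ¹⁵N) pair in ‰ relative to VPDB and atmospheric air. Counting is
in analyzed-sample units throughout; individual-organism counts are out
of scope. Validation enforces unique sample ids, one water-body type per
site, canonical FFG levels (free text is mapped through a fixed synonym
dictionary; unknown labels are rejected, never guessed) and finite δ
values. Groups with fewer than `min_n = 3` samples are dropped before
niche estimation — strictly below three, so n = 3 groups are retained,
matching the survey convention the package emulates.

## δ corrections

Both corrections are pure translations of one stratum:

* **Fertilizer (δ¹⁵N).** Organic fertilization raises the nitrogen
  baseline of ditches, which would masquerade as a trophic shift. The
  pooled consumer mean δ¹⁵N is computed per water-body type and
  (mean_ditch − mean_pond) is subtracted from ditch samples only. All
  sampled invertebrates count as consumers; the mean is unweighted over
  samples (not over sites or FFGs), because no weighting convention is
  implied by a baseline shift.
* **Maize (δ¹³C).** A C4 crop in one pond's catchment raises consumer
  δ¹³C there. The mean over the unaffected ponds is the reference; the
  difference is subtracted from the affected pond(s) only.

Translations preserve within-stratum variances and all pairwise
distances, so every geometric niche metric of a corrected stratum is
unchanged except for its position — which is exactly the point. Two
correction states are carried through the pipeline: δ¹⁵N-only for
community-level comparisons and the ordination (carbon sources are real
ecology and should not be equalized away when comparing communities),
and δ¹⁵N + δ¹³C for FFG-level ellipse comparisons, where the maize
signal would otherwise dominate one pond's guilds. Re-applying a
correction is mechanically allowed but warned about, since it is only a
no-op when the means already coincide.

## Layman metrics and their estimators

The six community metrics are computed on the raw point cloud: δ¹³C and
δ¹⁵N ranges, convex-hull area (TA, ‰², via `grDevices::chull` and the
shoelace formula; fewer than three distinct non-collinear points give
0), mean distance to the centroid (CD), mean nearest-neighbour distance
(MNND) and the standard deviation of nearest-neighbour distances
(SDNND). SDNND uses the sample (n − 1) standard deviation, the
convention of the standard Layman-metric implementations, to stay
comparable with the literature. Duplicate coordinates are legal and may
produce zero nearest-neighbour distances; ties are irrelevant because
only the distance value enters the metric.

## The Bayesian niche model

Each group's cloud is modelled as bivariate normal. The prior is a
weakly informative conjugate Normal–Inverse-Wishart:
μ₀ = sample centroid, κ₀ = 10⁻³, ν₀ = 3, Ψ₀ = I (‰²). ν₀ = 3 is the
smallest degrees of freedom with a finite prior covariance mean in two
dimensions; κ₀ = 10⁻³ makes the prior mean carry ~0.001 observations of
weight. Because the model is conjugate, the posterior is sampled
*exactly* and i.i.d. (`stats::rWishart` for Σ, then μ | Σ): no MCMC, no
burn-in, no convergence diagnostics, and the results are equivalent to a
vague-prior Gibbs sampler in the regime where such samplers are normally
run. Default `n_draws = 10000` (pipeline default 2000, which is ample
for modes and 95% intervals of smooth unimodal posteriors); each group
gets its own stream derived stably from the master seed, so ensembles
are bitwise reproducible and independent of which other groups are
fitted. Groups at the minimum n = 3 are fitted but flagged: their
posteriors are visibly prior-influenced.

The standard ellipse area is SEA(Σ) = π√det Σ, with theoretical coverage
1 − e^(−1/2) ≈ 39.35% — the conventional "40% of the data". SEAc
multiplies the sample-covariance SEA by (n − 1)/(n − 2). SEA.B is the
posterior distribution of SEA over covariance draws.

Posterior summaries use a Gaussian KDE (Silverman bandwidth, 1024 grid
points): the mode is the density argmax, and credible intervals are
highest-density regions obtained by thresholding the same density, which
makes the 50/75/95% intervals nested by construction — a sample-window
HDI search does not guarantee nesting, a KDE threshold does. Constant
draw vectors short-circuit to zero-width intervals.

Community-level "Layman.B" posteriors recompute the six metrics, at each
draw, on the point set formed by the member groups' mean-vector draws:
group centroids, not individuals. This is the convention of the
Bayesian ellipse frameworks this package follows; the alternative
reading ("spacing of individuals") would require pooling posterior
predictive draws and is deliberately not implemented. Welch comparisons
(`stats::t.test`, Welch–Satterthwaite dof, 95% CI) are exposed for both
posterior draw vectors and group-level point estimates; which of the two
a study should report is a design choice the package leaves to the
analyst.

## Ellipse overlap

Maximum-likelihood ellipses use the ML covariance (denominator n —
distinct from the n − 1 covariance inside SEAc; both are documented
because mixing them silently is a classic error) and a boundary at the
χ²₂ quantile q(p) = −2 ln(1 − p), with p = 0.95 by default. The overlap
area is computed by transforming the plane so the first ellipse becomes
the unit disk — this bounds the integrand's conditioning for eccentric
ellipses — and integrating the chord overlap with the mapped second
ellipse by adaptive quadrature (`stats::integrate`, requested relative
tolerance 10⁻⁶; failure to converge is an error, not a silent result).
The headline percentage is Jaccard-style (overlap/union); because the
phrase "proportion of both overlaps" is genuinely ambiguous, the
fractions of each single ellipse are always exported alongside so a
reader can reconstruct either normalization.

## Toxic units and water summaries

TU_sum = log₁₀ Σ Cᵢ/Eᵢ over detected substances, Eᵢ the *minimum*
(most sensitive) endpoint available for the substance and organism
class. Detections quantified below the LOQ enter at LOQ/2. A sample with
no detections returns `NA` flagged `no_detection` — "no toxic pressure"
is not 0, which would mean a toxic-unit sum of exactly one. Nutrient
sums are NH₄⁺ + NO₃⁻ only; phosphate and nitrite are carried in the data
model but not summed. Per-type summaries use the sample SD and report
`NA` for single-site types.

## Stressor linkage

Environmental variables are z-scored (constant columns are an error).
The response dissimilarity over sites is Mahalanobis: Euclidean distance
after whitening the metric columns by the inverse square root of their
covariance. With six metrics and seven sites this covariance is
near-singular by construction; the default whitens over the
eigendirections above 10⁻⁸ of the largest eigenvalue (a pseudo-inverse)
and warns, while `strict = TRUE` turns the situation into an error
rather than hiding it. BIOENV search is exhaustive over all non-empty
variable subsets (capped at 20 variables), scoring each by the Spearman
correlation (average ranks on ties) between the subset's Euclidean
distances and the response. Excluding variables before the dbRDA (the
package default drops `ec` and `o2`, which fluctuate over the day and
are weakly identified from single in-situ readings) is configuration,
not hard-coded behaviour.

dbRDA follows the standard construction: G = C(−½D²)C (Gower
double-centering), projection onto the centered constraint space by the
QR-based hat matrix, eigenanalysis of HGH and (I−H)G(I−H). Negative
eigenvalues — impossible for metric input up to rounding — are clipped
to zero with a warning. On Euclidean dissimilarities the constrained
eigenvalues equal classical RDA's, which the tests verify against an
independent regression-then-eigenanalysis oracle and against `vegan`
(whose inertia is scaled by 1/(n−1); the cross-check rescales).
Permutation tests permute site rows of D freely (no blocks, as no
restricted design applies), with pseudo-F = (constrained/q)/(residual/
(n−q−1)) and p = (1 + #{F* ≥ F})/(1 + n_perm); terms are tested
sequentially in column order and axes marginally against the full-model
residual.

## The synthetic test bed

`scenario_survey_like()` emulates a three-pond, four-ditch survey:
per-(site × FFG) sample counts follow the survey's published count
template (row sums 228 pond / 453 ditch samples), group means follow a
trophic ladder in δ¹⁵N (primary consumers ≈ 5–6.5 ‰, omnivores 8 ‰,
predators 10 ‰) with FFG-specific δ¹³C baselines near −30…−27 ‰, group
covariance diag(2, 1) ‰² with 0.3 covariance, and Gaussian site-level
mean shifts (SD 0.5 ‰). Ditches carry a +3.5 ‰ δ¹⁵N fertilizer offset
and "Pond 3" a +8 ‰ δ¹³C maize offset — magnitudes chosen once as
ecologically plausible signals clearly above the group SDs. Setting
`site_sd = 0` makes the type offsets the only systematic signal, which
closed-loop recovery tests require. Water chemistry draws Bernoulli
detections per substance (panel of 12; probabilities tuned to expected
counts of 2.7 per pond and 6 per ditch), lognormal concentrations with
15% of detections placed below the LOQ, and nutrient sums around 0.25
(ponds) and 1.15 mg/L (ditches).

What the generator does *not* emulate — and what passing tests therefore
cannot show about field data: non-normal or multimodal isotope clouds
(e.g. omnivores splitting into herbivorous and predatory clusters),
within-group taxonomic structure, correlated detection of co-applied
pesticides, seasonal dynamics, and measurement error in δ values beyond
the group covariance. Tests demonstrate estimator correctness under the
model's assumptions, not robustness to their violation.

## Problem sizes and tolerances

The test suite runs on synthetic data at the scale of the emulated
survey (≈ 680 samples, 7 sites) and uses: 20–25 replicates for
Monte-Carlo recovery checks, 2·10⁵ points for the ellipse-coverage
simulation (binomial SE ≈ 0.11 percentage points), 99–999 permutations
for ordination tests, and 200 null replicates for the type-I-error check
(acceptance bound: within 3 binomial SEs of 0.05). Quadrature overlap is
validated against closed-form circle lenses to 10⁻⁵ and against
Monte-Carlo rejection sampling to 3 MC standard errors.

## Known limitations

* The bivariate-normal niche model is unimodal by construction; groups
  with mixed feeding strategies violate it and their SEA/SEA.B should be
  read as an envelope, not a density.
* With seven sites, the Mahalanobis response and the dbRDA are heavily
  rank-limited; permutation p-values are honest but power is minimal,
  and the pseudo-inverse whitening means the "Mahalanobis" distance is
  taken in a reduced subspace.
* Overlap is reported for ML ellipses only; no posterior distribution of
  overlap is computed.
* Endpoint tables are user-supplied; the package performs no lookups in
  pesticide-properties databases, and the bundled endpoint values in the
  generator are synthetic.
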