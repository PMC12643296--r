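# swbniche

Isotopic niche metrics for benthic invertebrate communities in small
agricultural water bodies (ponds and ditches).

Ponds and kettle holes embedded in farmland, and the drainage ditches
around them, host rich benthic invertebrate communities while being
exposed to fertilizer runoff and pesticide residues. Classical taxonomic
diversity indices are often too blunt to register these pressures.
`swbniche` implements a functional alternative: it treats each community's
cloud of paired carbon and nitrogen stable isotope measurements
(δ¹³C, δ¹⁵N, in ‰) as its *isotopic niche* and provides the full
quantitative pipeline to estimate, compare, and relate those niches to
measured stressors. It is aimed at freshwater ecologists and
ecotoxicologists working with site × functional-feeding-group (FFG)
isotope tables and site-level water chemistry.

## What it computes

**δ corrections.** δX = (R_sample/R_standard − 1)·10³ converts isotope
ratios to per-mil notation. Two mean-offset corrections remove signals
that would otherwise dominate between-type comparisons: the ditch-wide
δ¹⁵N enrichment from organic fertilization (ditch consumer mean minus
pond consumer mean, subtracted from ditch samples only) and the δ¹³C
enrichment of consumers in a maize-influenced pond (C4 photosynthesis;
offset relative to the unaffected ponds, subtracted from that pond only).

**Layman community metrics.** For a point set in (δ¹³C, δ¹⁵N) space: the
δ¹³C and δ¹⁵N ranges, total convex-hull area TA (‰²), mean distance to
centroid CD, mean nearest-neighbour distance MNND, and its standard
deviation SDNND.

**Bayesian niche ellipses.** Each group's cloud is modelled as bivariate
normal; the posterior of (μ, Σ) under a conjugate Normal–Inverse-Wishart
prior is sampled exactly (no MCMC). The standard ellipse area
SEA = π√det(Σ) covers 1 − e^(−1/2) ≈ 39.4% of the data ("the 40%
ellipse"); SEAc = SEA·(n−1)/(n−2) is the small-sample point estimate and
SEA.B the posterior distribution of SEA, summarized by kernel-density
modes and nested 50/75/95% highest-density intervals. Community-level
"Layman.B" posteriors are obtained by recomputing the six metrics on each
posterior draw of the member groups' centroids. Welch's t
(unequal-variance) comparisons are provided for group summaries.

**Niche overlap.** Maximum-likelihood ellipses at a chosen coverage p
(boundary at the χ²₂ quantile −2·ln(1−p)) are intersected by adaptive
quadrature; the overlap is reported as area, as a Jaccard proportion
(overlap/union), and relative to each ellipse.

**Toxic units.** TU_sum = log₁₀ Σᵢ Cᵢ/EC50ᵢ scores the toxic pressure of
a water sample over its detected pesticides, with the most sensitive
EC50/LC50 endpoint per substance and organism class (invertebrates,
algae) and half-LOQ substitution for sub-LOQ detections. Nutrient sums
(NH₄⁺ + NO₃⁻) and detection counts are summarized per water-body type.

**Stressor linkage.** Per-site Layman metric matrices are related to
environmental variables via exhaustive BIOENV subset selection (Spearman
rank correlation between subset Euclidean distances and the Mahalanobis
response dissimilarity), distance-based redundancy analysis (dbRDA via
Gower double-centering), and permutation pseudo-F tests on the model,
terms, and axes.

A synthetic-data generator (`scenario_survey_like()`,
`simulate_isotope_dataset()`, `simulate_water_chemistry()`) emulates the
whole study design — per-group bivariate-normal clouds with known
fertilizer/maize offsets and per-site chemistry with known detection
probabilities — so every estimator can be tested closed-loop against
ground truth.

## Worked example

```r
library(swbniche)

sc  <- scenario_survey_like(seed = 1)      # 3 ponds, 4 ditches, 6 FFGs
tab <- simulate_isotope_dataset(sc)

summarize_counts(tab)
#> <counts_summary>
#>  totals: ditch = 453, pond = 228
#>  mean samples per site: ditch = 113.25, pond = 76.00

res <- correct_d15N_fertilizer(filter_min_group_size(tab, 3))
res$report
#> <correction_report> d15N: target mean 11.209, reference mean 7.000,
#>   offset 4.209 permil subtracted from Ditch 1, Ditch 2, Ditch 3, Ditch 4

ens <- fit_group_ensembles(res$table, "ffg_by_type", n_draws = 2000, seed = 1)
pp  <- res$table[res$table$wb_type == "pond" & res$table$ffg == "predator", ]
sea_metrics(pp$d13C, pp$d15N, ensemble = ens$ensembles[["pond.predator"]])
#> <ellipse_summary> n = 52: SEAc = 13.428, SEA.B mode = 12.920
#>   [95% HDI 9.522, 16.462] permil^2

ffg_overlap_table(res$table, p = 0.95)[, c("ffg", "overlap_pct")]
#>                  ffg overlap_pct
#> 1 collector_gatherer        30.2
#> 2     grazer_scraper        40.5
#> 3           omnivore        31.6
#> 4           predator        38.2
#> 5           shredder        79.6
```

The counts reproduce the emulated survey design (228 pond and 453 ditch
samples; 76 and 113.25 per site). The correction report shows the
recovered fertilizer offset (the generator planted 3.5 ‰ plus random
site-level shifts). The ellipse summary gives the pond predators' core
niche width with its Bayesian uncertainty, and the overlap column is the
Jaccard percentage of the 95% ML ellipses of each guild's pond vs ditch
niche. `run_pipeline(pipeline_config(scenario = sc, out_dir = "out"))`
chains all stages and writes each artifact with an MD5 manifest.

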