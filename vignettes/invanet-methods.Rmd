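---
title: "Methods: models, parameters and design choices in invanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in invanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`invanet` analyses paired invaded/native rhizosphere surveys that combine a
16S OTU table with a CNPS-cycling qPCR chip. This vignette documents the
statistical models the package implements, the tunable parameters and their
defaults, the synthetic generative model used for validation, and the design
choices made where more than one convention exists in the field.

## 1. qPCR quantification

The chip reports a cycle threshold (CT) per sample and assay. The
quantification chain is:

* **Efficiency QC.** Each assay has an amplification efficiency `E` (fold
  amplification per cycle, ideally 2). Assays with `E < 1.8` or `E > 2.2`
  are eliminated for all samples; the bounds themselves are retained
  (`qc_filter()`).
* **Detection threshold.** CT = 31 is the detection limit: wells with
  CT > 31, or blank wells (`NA`), quantify to zero. Non-detects are true
  zeros downstream; nothing is imputed.
* **Relative copies.** Detected wells map to `N0 = E^(31 − CT)`
  (`ct_to_relative()`), so a well exactly at the threshold has one relative
  copy and each cycle earlier multiplies copies by `E`.
* **Absolute copies.** The externally measured absolute 16S copy number of
  each sample anchors the scale:
  `abs_gene = N0_gene × abs_16S / N0_16S` (`quantify()`). A sample whose
  16S reference is itself a non-detect is flagged and its absolute
  abundances are undefined (`NA`), never silently zero.

The chip's own protocol does not print the CT-to-copies formula; the
`E^(31 − CT)` convention with per-assay `E` (equivalently
`10^((31 − CT)/(10/3))` at `E ≈ 2`) reproduces the behaviour of the
WaferGen-style analysis pipelines this chip ships with.

The bundled panel (`qmec_panel()`) has 71 functional assays — 35 C-cycling
(21 degradation, 10 fixation, 4 methane metabolism), 22 N, 9 P, 5 S — plus
one 16S reference. The degradation/fixation/methane split within carbon is
a package convention (the chip literature prints per-category totals only
for detected genes); the 35/22/9/5 totals are the chip's layout.

## 2. Community analysis

* **Rarefaction** (`rarefy()`): subsampling without replacement to a common
  depth, by default the minimum sample total. The seed is a mandatory
  argument; samples below depth are dropped with a warning. Alpha indices
  are computed on rarefied counts.
* **Alpha diversity** (`alpha_diversity()`): observed richness; the
  bias-corrected Chao1 `S + F1(F1 − 1)/(2(F2 + 1))`; ACE with rare-species
  cutoff 10; Shannon entropy with natural logarithm; Simpson diversity as
  Gini–Simpson `1 − Σ p²` (the more common reading of "Simpson diversity";
  `simpson = "inverse"` switches to `1/Σ p²`). All-zero samples are
  reported `NA` with a warning. When a sample has no species at abundance
  ≤ 10 the ACE machinery has nothing to extrapolate from and ACE is
  reported as observed richness.
* **Beta diversity**: Bray–Curtis `Σ|x − y| / Σ(x + y)` (semi-metric, so
  the triangle inequality is not assumed downstream); PCoA by Gower
  double-centering of `−d²/2` with axes scaled by `√λ`. Negative
  eigenvalues are retained in the eigenvalue report but excluded from
  coordinates and from the explained-variance proportions. On Euclidean
  inputs the embedding reproduces the distances exactly, which the tests
  assert to 1e-9.
* **ANOSIM** (`anosim()`): all `M = n(n−1)/2` distances are ranked with
  mid-ranks for ties; `R = (r̄_between − r̄_within)/(M/2)`. The p-value
  uses the add-one convention `(1 + #{R* ≥ R})/(1 + n_perm)`, so it is
  never zero and never below `1/(n_perm + 1)`.

  **Blocked permutation.** For paired designs the package supports
  `strata`: labels are permuted only within each block (site). This is not
  cosmetic. When paired samples are positively correlated (shared site
  effects), the observed labeling — every site discordant — is an extreme
  configuration among free relabelings, and the unrestricted test is
  drastically conservative (essentially zero rejections on truth-free
  data). With site strata the test holds its nominal level: on 400
  truth-free synthetic datasets (20 samples, 199 permutations) the
  rejection rate at α = 0.05 was 0.055, inside the exact binomial 99%
  band. The pipeline always uses site strata; unblocked permutation
  remains the default for data without structure.
* **Kruskal–Wallis screens** (`kruskal_wallis_screen()`): the table is
  collapsed to a taxonomy rank, the `top_n` most abundant taxa kept
  (survey convention: top 10 phyla, top 20 families), and each tested with
  the tie-corrected H (chi-square p). Raw p-values are compared to 0.05 —
  the screen is descriptive, as is conventional for these phylum/family
  panels — with `p_adjust = "BH"` available. Fully tied taxa are reported
  `H = 0, p = 1` rather than the 0/0 the ties correction would produce.

## 3. Co-occurrence networks and keystones

`build_network()` implements the field's standard filter chain:

1. OTU counts become relative abundances over the *full* community, then
   features present in strictly more than `prevalence_min` (default 0.8)
   of samples are kept. Normalising before filtering keeps the
   denominators interpretable; gene tables enter on their absolute-copy
   scale (ranks, hence Spearman correlations, are unaffected by the
   choice of scale within a feature).
2. Spearman correlations with mid-ranks; two-sided p from the
   t approximation `t = ρ√((n−2)/(1−ρ²))`. Zero-variance features are
   excluded with a warning.
3. One Benjamini–Hochberg family per network build (all tested pairs —
   no finer family is defensible without more structure), and an edge iff
   `q < alpha` (strict) **and** `|ρ| > r_min` (strict). The magnitude
   `|ρ|` is compared, so negative edges are retained and carry
   `sign = "negative"`.

Presets: `fmen` (OTU + gene nodes, `r_min = 0.6`) and `genenet`
(gene–gene, `r_min = 0.8`). All pair types (otu–otu, otu–gene, gene–gene)
are tested by default; `pair_types` can restrict this. Only nodes with at
least one edge are kept — the convention used when reporting node counts
of rendered networks.

`topology()` reports node/edge counts, signed edge counts, average degree
`2E/N`, average local clustering (degree < 2 contributes 0), transitivity
(3 × triangles / connected triples), modularity from greedy agglomeration
(deterministic for a given graph), and mean distance and diameter on the
largest connected component, with the component count alongside — the
conventions are stated because disconnected graphs leave them undefined
otherwise. Edgeless networks report `NA` distances.

**Keystone taxa** (`keystone_taxa()`): the top-`k` (default 5) OTU nodes by
degree. Ties break by higher mean relative abundance, then lexicographic
id; both tie-breaks are deterministic so reports are reproducible. Fewer
than `k` OTU nodes returns all of them with a warning.

## 4. Driver analysis

* **Importance** (`importance()`): two methods behind one interface.
  `rf_permutation` (default) reports the percentage increase in
  out-of-bag MSE when a predictor is permuted (%IncMSE, 500 trees);
  `lmg` reports the LMG decomposition of the linear model's R² —
  the average, over all predictor orderings, of the R² gain when the
  predictor enters — computed from the correlation matrix over all 2^p
  subsets (capped at p = 20) so the shares sum exactly to the full-model
  R². Significance for both comes from a response-permutation null with
  the add-one convention (`n_perm = 99` by default). Zero-variance
  predictors contribute exactly 0.
* **Keystone–gene regression** (`keystone_gene_regression()`): the
  "average standardized abundance" is defined as: ln-transform each
  keystone OTU's abundance, z-score it across samples, average the
  z-scores per sample; the response is ln gene abundance; ordinary least
  squares. Because ln(0) is undefined, the default policy on zeros is an
  error naming the offending samples; `zero_policy = "pseudo"` adds half
  the smallest positive value, with a message. The pipeline uses the
  pseudo-count policy since rare keystones do drop out of single samples.
* **RDA** (`rda_genes()`): response columns standardised, regressed on the
  (centered) predictors, constrained axes from the fitted values (vegan),
  overall permutation F-test. Collinear predictors fail with the
  dependent columns named, since silent dropping would change the
  variance partition.

## 5. Spatial interpolation

`idw()` uses planar Euclidean distance on degree coordinates: the study
region spans ~1.3°, where planar distortion is far below the sampling
density; `haversine = TRUE` is available. The default grid is 100 × 100
over the points' bounding box padded 5%, power 2. IDW is an exact convex
interpolator — the tests assert exactness at sample points to 1e-12 and
boundedness by the input range. `north_south_contrast()` splits at the
median latitude by default (no principled boundary exists otherwise) and
reports per-category median differences with Kruskal–Wallis p-values. The
pipeline reports per-group contrasts and a pooled all-sample contrast;
the pooled one has twice the stratum size and is the better-calibrated
gradient readout.

## 6. The synthetic generative model

`generate_dataset()` draws, per sample `s`: a latent factor
`f_s ~ N(0,1)`; per-site, per-OTU random effects `u ~ N(0, 0.3²)` shared
by the two paired samples; and log relative OTU abundances

```
L_sj = α_j + λ f_s · 1[j ∈ keystones(group_s)] + δ dir(phylum_j) · 1[group_s = AP] + u_{site(s),j} + ε_sj
```

with `ε ~ N(0, 0.5²)`, softmax to proportions, multinomial counts at a
lognormal depth (mean 20 000, CV 0.1). Gene log absolute abundances share
the same `λ f_s` plus a latitude gradient `γ` (log units per degree,
default 1) on configured categories and `N(0, 0.5²)` noise; CT values are
produced by inverting the quantification chain exactly, so `quantify()`
recovers the planted gene abundances to floating-point precision.
Responder phyla mimic the invasion signature (Bacteroidetes and
Nitrospirae up, Actinobacteria down in `AP`); edaphic ammonium is shifted
by `δ` between groups and negatively coupled to the gene-driving factor in
invaded samples. Baseline OTU log-abundances are `N(0, 1.2²)`; planted
keystones get baseline 0.5 — moderately abundant, so they survive the 80%
prevalence filter that any network-based keystone definition presupposes
(field surveys report keystones that can be rarer than this; a planted
keystone below the prevalence filter would be undiscoverable by
construction, which is a limitation of degree-based keystone definitions,
not of the generator).

Defaults: 22 sites (44 samples), 300 OTUs, 5 keystones per group,
`λ = 0.9`, `δ = 0.5`, `γ = 1`, gradient on the three carbon categories
and P. Effect sizes are free parameters of the generator — realistic for
field surveys of this kind, but not estimates of any particular study.
What the generator does **not** emulate: phylogenetic signal, overdispersed
(beyond multinomial) counts, assay cross-reactivity, spatially structured
site effects, and compositional coupling between the OTU community and the
chip measurements. Passing recovery tests therefore demonstrates that the
pipeline detects the planted structure at realistic noise, not that real
surveys carry such structure.

## 7. Determinism and numerics

Every stochastic operation takes an explicit seed; the pipeline derives
per-stage seeds from one global seed (`seed × 1000 + stage index`,
mod 2³¹ − 1) so stages can be re-run in isolation and identical
configurations yield byte-identical reports. RNG state of the caller is
always restored. Perfect correlations get `p = 0`; `|ρ|` is clipped to 1
before the t transform; Chao1/ACE require integer counts and refuse
otherwise. Problem sizes in the validation suite (400 null datasets of 20
samples for ANOSIM level; 50 seeds at the full 44-sample design for
keystone recovery; 100 seeds of 30 × 4 for importance calibration; 100
random graphs ≤ 10 nodes against the brute-force oracle) were chosen so
the whole suite completes in about a minute while the binomial bands
remain tight enough to detect miscalibration.

## 8. Known limitations

* Spearman networks ignore compositionality; SparCC-style corrections are
  out of scope, so negative-edge counts on relative-abundance data should
  be read with that bias in mind.
* The t approximation for Spearman p-values is slightly anti-conservative
  deep in the tail at small n; with BH and the `|ρ|` threshold the
  realised false-edge rate on null data stays far below the nominal
  α fraction (asserted in the tests), but exact permutation p-values
  would be preferable for n < 15.
* Degree-based keystone identification inherits all caveats of
  correlation networks: hubs are statistical, not demonstrated ecological,
  keystones.
* The LMG decomposition is exact but exponential in predictors (capped at
  20); random-forest importance is the default for wider predictor sets.
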