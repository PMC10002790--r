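---
title: "cargoHCS: models and methods for arrayed dynein-cargo screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cargoHCS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cargoHCS)
```

# The assay being modelled

An arrayed CRISPR screen for dynein-based trafficking dispenses one crRNA
pool per gene per well of a 384-well plate, images fixed cells in several
fluorescence channels, and quantifies — per cell — where cargo puncta sit
relative to the nucleus. Dynein pulls its cargoes to the centrosome, so
loss of motor function *disperses* them: the perinuclear-to-peripheral
localisation ratio drops. Every plate carries scattered controls: a
non-targeting pool (NTC, the neutral reference, 38 wells), a
positive-control pool with a strong dispersion phenotype (crLIS1-like, 13
wells) and an editing control that kills cells when cutting works
(crPLK1-like).

This package implements both the analysis of such screens and a generative
model of them, so that each analysis stage can be validated against known
ground truth.

# The synthetic screen generator

**Plate layout.** `generatePlateLayout()` scatters the configured control
wells uniformly at random over each 16 × 24 plate and fills remaining wells
with library genes, each placed exactly once. All placement is a
deterministic function of one seed.

**Seed policy.** A single master seed is expanded into per-well (and
per-stage) child seeds with `childSeed()`, a counter-based linear
congruential mix modulo 2³¹ − 1. Any well can therefore be re-simulated in
isolation, and all derived seeds stay below 2³¹.

**Cell populations.** Seeded cells per well are Poisson with mean 260
(within the 100–400 cells/well range typical of these screens). Survival
through the viability gate is Binomial with probability
`base_viability × viability_factor`; the baseline of 0.93 reflects that an
apoptotic/mitotic morphology gate removes a few percent of even healthy
populations (and keeps the viable-fraction endpoint non-degenerate under
NTC). Nuclear area is lognormal (median 170 µm², sdlog 0.25), roundness a
Beta(14, 2.5), integrated DNA intensity lognormal. These are desk-scale
stand-ins chosen to support the area/roundness/intensity endpoints, not
claims about U-2 OS morphology. A planted gene effect shifts the mean area
and roundness additively and sets a per-cell micronucleus probability.

**Radial spot model.** Punctum distances to the nuclear envelope follow a
two-component exponential mixture: a clustered component (scale 2 µm) and a
dispersed one (scale 12 µm), with NTC clustered fraction 0.6. A planted
dispersion effect δ moves mass between components,
`p = clamp01(0.6 + 0.1·δ + well noise)`, with well-to-well technical noise
of s.d. 0.02 on the fraction. Negative δ disperses cargo, positive δ
hyper-clusters it; the clustered fraction responds strictly monotonically
until clamped. The unit of δ is the slope on the mixture fraction; its
realised size in NTC well-level standard deviations depends on the cell
count and well noise and is therefore *measured* downstream rather than
assumed (δ = −1 realises as several NTC S.D. under the defaults).
Per-cell spot counts are Poisson (mean 12 per channel); spot amplitudes are
lognormal (sdlog 0.3).

`simulateWell()` materialises individual spot distances.
`simulateScreen()` instead draws each cell's perinuclear count as
Binomial(n_spots, P(d ≤ 7 µm)) using the mixture's closed-form CDF — which
is distributionally identical to sampling distances and thresholding — so
that thousand-well screens simulate in seconds.

**Spot density and the renderer.** No per-cell spot-count or radial
statistics are published for NTC wells in this assay family, so these
defaults are calibration choices. The mean of 12 puncta per channel was
chosen once as a density at which puncta remain *countable* at the
simulated optical scale — an implicit premise of any spot-count readout.
`renderField()` rasterises nuclei as filled ellipses (axes recovered from
area and roundness via the Ramanujan perimeter approximation), places cells
by rejection sampling so nuclei never overlap (cytoplasm may), converts
each spot's envelope distance to a position along a random direction from
the ellipse boundary, stamps Gaussian puncta (PSF σ 0.8 µm, appropriate for
a 20× acquisition binned to 0.6 µm/pixel on 1080 × 1080 fields), and
applies Poisson shot noise plus Gaussian read noise (s.d. 5 on a background
of 100). We define a punctum's SNR as
`peak amplitude / sqrt(background + read_noise²)`. Ground-truth masks,
spot coordinates, micronuclei and MTOC foci are returned with every image.

**Fingerprint tables.** `simulateFingerprintTable()` emulates a
post-normalisation pool × feature rZ matrix: features fall into blocks that
share a latent factor (pairwise correlation `block_correlation`, a model of
technically related feature families), pools in the same latent group share
a mean profile of strength `effect_scale`, and scattered positive-control
wells are emitted alongside with a configurable subset of features made
highly variable (S.D. ≥ 3) across them. Group signatures are drawn **per
feature**, not per block: a perturbation's mean effect on each feature is
its own, while block correlation models the noise covariance. (A
block-aligned alternative was considered and rejected: strong group signal
then makes same-block features empirically collinear, so the redundancy
filter would collapse exactly the features carrying signal; the filter's
intended true positives are near-collinear feature families, which the
fixtures plant explicitly at correlation ≥ 0.99.)

# Imaging

**Segmentation.** Nuclei: Gaussian smoothing (σ 1 µm), Otsu threshold,
hole filling, connected components, minimum area 30 µm²; border-touching
nuclei are flagged and excluded downstream. Roundness is 4πA/P² (clamped
at 1 against discretisation). Cytoplasm: above-background pixels are
assigned to the nearest nucleus using exact Euclidean distance transforms,
giving a partition of the foreground; when no diffuse foreground exists the
fallback is the nucleus dilated by a 2 µm rim, and such cells are flagged
`zero_cyto`.

**Spot detection.** Difference-of-Gaussians band-pass (σ and 2σ at the
punctum scale), local 3 × 3 maxima above a robust background threshold
(median + 5 × 1.4826·MAD of the response, per cell when masks are given,
global otherwise), sub-pixel centroids by intensity-weighted refinement of
the 3 × 3 response patch, and de-duplication of plateau maxima within
1.2 px. Puncta closer than about twice the filter σ merge into one
response peak; a greedy deflation pass subtracts a Gaussian of the detected
amplitude at each accepted peak and re-runs detection on the residual,
recovering the fainter partner of close pairs. Residual-pass candidates
must be at least 1.5 px from any accepted spot and reach 30 % of the
weakest accepted response, which suppresses subtraction artefacts. When
detection quality is benchmarked against ground truth, matching is
proximity-based at 2 px on each side (a detection covering an unresolvable
pair counts for both truth spots); this is stated wherever it is used.

**Ring compartments.** Envelope distances come from exact Euclidean
distance transforms: positive outside the nucleus, 0 on
background-adjacent nucleus pixels, negative further inside. Pixels are
1-based with centres on integer coordinates (micron conversion
`(i−1)·pixel_size`); discretisation makes distances exact only up to half a
pixel diagonal, which is the documented tolerance at ring boundaries. The
inner boundary is inclusive: d ≤ 7 µm is perinuclear (the convention is a
choice; the assay definition only fixes the 7 µm and 14 µm cutoffs).
Two-ring mode merges intermediate and outer into "peripheral".

**Localisation ratio.** `n_perinuclear / (n_peripheral + 1)` per cell,
averaged per well. The pseudocount sits in the denominator only, so a cell
with no spots scores 0 (maximally "dispersed" is not asserted; it simply
cannot divide by zero) — the zero-denominator rule is otherwise
unspecified in the assay description.

**Viability gate.** Percentile bounds (default 1st–99th) on nuclear area,
roundness and integrated DNA intensity, estimated from pooled NTC cells.
Three joint two-sided gates retain ~94 % of a clean population. Gating
with fixed bounds is idempotent. The exact bounds used in real screens are
not published; percentiles on the named criteria are our documented
choice.

**MTOC and micronuclei.** MTOC foci are detected with the same spot
detector at σ 1.2 µm on the γ-tubulin channel; wells report the fractions
of cells with 0, exactly 1 and >1 foci. Micronuclei are DNA-positive
objects of 1–30 µm² inside a cell's cytoplasm that do not touch the primary
nucleus.

**Per-cell features.** A reduced, deterministic morphological-profiling
schema (`cellFeatureNames()`): nuclear morphology; per-channel intensity
summaries, coefficient of variation and a three-ring radial intensity
profile; per-channel spot statistics including compartment counts and the
localisation ratio. Missing channels yield `NA` features, never zeros.

# Normalisation

The robust Z uses the Gaussian-consistent MAD constant 1.4826
(configurable); a zero MAD falls back to the NTC sample S.D., and a zero
S.D. flags the endpoint degenerate. Two-point normalisation anchors
median(NTC) → 0 and median(positive) → −100. The robust Z′ plugs scaled
MADs into the classical Z′ formula; it has *no* MAD fallback, so
zero-spread controls give exactly 1 (the closed-form limit), and equal
control medians flag an undefined window. Normalisation is per plate by
default — controls are scattered on every plate precisely because plate
effects exist — with cross-plate pooling behind a flag.

The LDA composite combines features that individually show at least a
minimal control window. "Window ≥ 0.1" is read as a robust-Z′ requirement
between the control groups (the alternative reading, mean |rZ| of the
positive controls, is implemented behind `filter = "mean_rz"`). The
two-class Fisher discriminant is fitted on standardised control wells with
the within-class covariance shrunk toward its diagonal
(Schäfer–Strimmer-style intensity estimated from the variance of the
empirical covariances), keeping the fit defined with few control wells;
the sign is oriented so the NTC median exceeds the positive-control
median, and the composite is then treated as an ordinary metric.

# Hit calling

Genes are first prefiltered on endpoints that flag indirect effects:
|area| ≤ 4 NTC S.D., roundness ≥ −3.5 S.D., micronuclei ≤ +4 S.D., and
viability no worse than the positive-control range (all configurable; the
viability bound is qualitative in the assay description, so the
positive-control minimum per screen is our default). Thresholds are then
mean(NTC) ± k·S.D.(NTC) per metric on the endpoint scale (the equivalent
z value is reported alongside), k = 2.0 in primary-screen mode and 2.5 in
validation mode; the stricter hit set provably nests inside the looser
one. A gene's effect is the mean of its qc-passing wells (wells below 100
analysed cells are withheld); genes whose wells all fail are dropped with
a reason. The overall hit flag is the union over the configured metric
set, which inflates the null rate accordingly (three two-sided metrics at
k = 2 give an expected ~13 % union tail in a one-shot screen — the reason
validation uses replicates and k = 2.5). Multi-cargo categories encode
the per-cargo hit/sign pattern mechanically (e.g. `"EEA1- only"`,
`"PEX-/EEA1-/TGN-"`), replacing manual annotation with a deterministic
rule. K-means grouping of cargo-effect profiles uses k-means++ seeding
with Lloyd iterations and restarts; the conventional k for cargo grouping
is 14, but k is always an explicit, logged parameter.

# Fingerprinting

Pool profiles are per-pool medians of well rZ vectors. Feature reduction
happens in two documented passes. (1) Variability: a feature is dropped
when its S.D. across the plate-scattered positive-control wells is ≥ 3 —
computed on the rZ scale, since the controls are described
post-transformation. (2) Redundancy: pairwise simple-regression R²
(= squared Pearson correlation) with a greedy, deterministic visiting
order — descending dynamic range, ties by name — dropping a feature when
R² ≥ 0.8 against any kept feature, so exactly one representative survives
per collinear block. Both filters are idempotent and order-stable, and
every input feature gets a ledger entry (kept / variable / redundant).

Profiles are then min-max scaled to [0, 1] per feature (constant features
map to 0.5 and are flagged); scaling after filtering and before clustering
follows the stated processing order. Hierarchical clustering uses
complete linkage on 1 − Pearson correlation between pool profiles
(Pearson, because "correlation" is otherwise unqualified); zero-variance
pools are excluded with a reason, since their correlation is undefined.
The dendrogram cut (k or height) is a user parameter — cluster inspection
is interpretive. UMAP embeddings are for visualisation only and are never
used for hit calling; determinism is ensured by seeding and single-threaded
SGD.

Recovery diagnostics compare flat labels to simulator truth with the
pair-counting adjusted Rand index plus per-group purity. Null pools carry
`NA` truth and are excluded from the ARI: they have no true group, and
which cluster absorbs them is immaterial to whether the planted
co-functional groups were recovered.

# Numerical choices and degenerate inputs

* Identical seeds give byte-identical tables and images end to end.
* Blank images segment to zero nuclei (not an error); empty NTC sets,
  missing schema columns, capacity overflows and invalid parameters raise
  typed errors naming the offending entity.
* MAD = 0 fallbacks, constant-feature handling, zero-spot cells, and
  zero-variance pools are each resolved by an explicit documented rule
  rather than NaN propagation.
* Hit thresholds, filter cutoffs and every other numeric that affects
  results appear in the run config and the pipeline log; `runPipeline()`
  writes a manifest with config hash and per-output checksums, and
  re-running a deleted intermediate reproduces identical tables.

# What the synthetic data do and do not show

The generator reproduces the *structure* of the real assay — plate
layouts with scattered controls, per-cell morphology and radial spot
statistics, viability and micronucleus effects, correlated feature blocks
with latent co-functional groups — under known ground truth. It does not
attempt photorealistic microscopy (no uneven illumination, no focus drift,
no cell-cycle structure, no segmentation-adversarial morphology), does not
model guide-level editing efficiency, and its nuclear/spot distribution
parameters are calibration choices rather than published measurements.
Tests passing on these data therefore validate the computational contracts
(formulas, filters, orderings, calibration under the stated model), not
performance on any particular real screen.

# Problem sizes used by the tests and acceptance script

Chosen as desk-scale versions of the real screen: robust-Z calibration on
10,000 simulated NTC-like wells of 260 cells; spot-detection benchmarks on
twenty 540 × 540 fields of 22 cells at SNR 5; ring-assignment oracles on 50
random cells; hit-calling calibration on 1,000 null genes against a pooled
NTC reference of 5,000 wells (large enough that the binomial sampling the
confidence interval assumes dominates threshold-estimation noise) plus 100
planted 5-S.D. effects; fingerprint recovery on 60 pools × 300 features
over ten seeds; and an end-to-end screen of four plates / 1,200 genes with
20 pan-cargo and 5 selective planted hits. On one CPU the full test suite
runs in well under a minute per criterion.
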