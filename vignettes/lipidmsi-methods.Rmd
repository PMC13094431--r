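---
title: "Methods: spatial lipidomics segmentation, enrichment and identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial lipidomics segmentation, enrichment and identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmsi)
```

This vignette records how the pipeline's pieces are defined, which knobs
matter, and where genuinely open design choices were settled — the level of
detail a reviewer or a maintainer needs and a help page cannot carry.

## The data model

A DESI-MSI acquisition is represented as an `msi_dataset`: a `width` ×
`height` pixel grid in row-major order (0-based x = column, y = row), one
strictly increasing m/z axis shared by all pixels, and a pixels × m/z
matrix of non-negative intensities. This mirrors imzML *continuous* mode,
which the reader and writer implement directly (m/z as 64-bit floats stored
once, intensities as 32-bit floats per pixel, coordinates converted from
imzML's 1-based convention). Processed-mode imzML — per-pixel axes — is
rejected with an explicit error rather than resampled: every downstream
step assumes one axis, and silently interpolating someone's centroids is
worse than refusing.

Tissue annotation travels as a `tissue_mask` over a fixed label vocabulary
(background, muscle, liver, brain, eye, gill, adipose, other), read from
plain CSV label grids or indexed PNGs with a legend sidecar.

## Preprocessing

**TIC normalization** rescales each pixel to unit summed intensity. The
normalization target is arbitrary up to a constant; summing to 1 makes
pixel spectra directly comparable as compositions. Zero-TIC pixels are left
untouched and flagged in metadata rather than dropped, so grid geometry
survives. The operation is idempotent.

**Baseline correction** subtracts a rolling-minimum baseline over a
sliding m/z window (default 5 Da) and clips at zero; a window wider than
the axis degenerates to global-minimum subtraction. This is meaningful for
profile-like, densely sampled axes. On sparse centroided axes a one-point
window would subtract each peak from itself, so the pipeline default is to
*skip* the step (`baseline_window = NULL`); the synthetic phantoms emit
centroided axes and carry their additive baseline as planted noise instead.

**Peak picking** takes local maxima of the mean spectrum, where "local"
means neighbors within an adjacency window (0.02 Da): isolated centroids
are peaks by themselves, contiguous profile bins compete. Peaks are ranked
by mean intensity and truncated to `top_n` (default 200, the working depth
of a negative-mode analysis of this kind).

**Alignment** groups centroids across replicates greedily, seeded from the
most intense unassigned feature downward, taking at most one member per
replicate within 0.02 Da. Seeding by intensity (ties toward lower m/z)
makes the grouping independent of the order replicate tables are supplied
in. The per-consensus-feature mass deviation is reported as the maximum
pairwise |Δm/z| in ppm. The tolerance is a configuration choice: 0.02 Da is
well inside the ±0.05 Da annotation scale while wide enough for the
between-replicate deviations the reference table reports (≤ 4.8 ppm, i.e.
≤ 0.004 Da at m/z 900).

**Deisotoping** removes feature B when some feature A lies 1.00336 ±
0.01 Da below it with larger mean intensity — the M+1 carbon isotopologue
pattern. Decisions use mean-spectrum intensities (one global feature list),
not per-pixel votes; the most intense feature of a table can therefore
never be removed. Removed satellites are logged with their parent.

**Interday rescaling** multiplies a target replicate by the ratio of mean
ROI TICs against a reference replicate, the standard correction for
source-realignment drift between acquisition days; the phantom generator
plants exactly this kind of global scale factor (0.8–1.25×) so the
correction is testable.

## Segmentation

Pixels are clustered by **bisecting k-means under the correlation
distance** d(u, v) = 1 − Pearson r(u, v), which is invariant to per-pixel
intensity scale — the property that matters when TIC differences between
tissues would otherwise dominate Euclidean distances. Implementation: pixel
spectra are z-scored, so assigning a pixel to the nearer of two z-scored
centroids by correlation equals Euclidean 2-means on standardized vectors;
centroids are re-standardized each iteration. Each bisection splits the
leaf with the largest *total dispersion* (sum of correlation distances to
the leaf centroid), not the largest pixel count — the worst-explained
cluster first. Each split runs 10 random restarts (2 distinct member
pixels as initial centroids) and keeps the lowest-dispersion result;
convergence is assignment stability or 100 iterations. Splitting stops
early when no leaf has positive dispersion (all members perfectly
correlated), reporting the achieved leaf count.

Conventions for degenerate input: a zero-variance spectrum has correlation
0 (distance 1) with everything, except distance 0 to an identical
zero-variance spectrum. Background pixels — TIC below 5% of the median
nonzero pixel TIC — are excluded before clustering and carry `NA` cluster
ids.

Two open points were settled as follows. The segmentation software used in
the source workflow names its metric "distance correlation"; Székely's
distance correlation is a dependence measure between random vectors, not a
pixel-to-pixel metric, and cannot drive k-means assignments, so the
conventional correlation distance reading is implemented. And since no
cluster count is stated, `n_leaves` defaults to 8 — enough leaves for the
six tissue classes of the phantom plus heterogeneity within muscle — and is
an exposed parameter, not a constant.

Cluster quality is scored against a mask by per-leaf Dice and Jaccard
(best-matching label) and a global adjusted Rand index over tissue pixels
(`mclust::adjustedRandIndex`). The adipose cluster is the leaf with maximal
Dice against the adipose label, ties to the lower leaf id; all other leaves
merge into the non-adipose contrast set.

## Enrichment statistics

The selection is two-tiered, per replicate first:

* **Tier 1.** For every consensus feature and replicate, a Welch t-test of
  adipose pixels against the merged non-adipose pixels, with
  Benjamini–Hochberg adjustment *within that replicate's feature family*.
  A feature is a candidate if q < 0.05 **and** the adipose mean exceeds the
  non-adipose mean in at least one replicate. The direction constraint is
  deliberate: "enriched" is one-sided, and without it a feature depleted in
  adipose would count. "Unpaired t-test" is implemented as Welch rather
  than pooled-variance Student (a pooled flag exists): the two pixel
  populations differ grossly in size and variance by construction. The BH
  family scope (per replicate × polarity) is itself a choice — the source
  procedure does not state it — and it is the scope under which the
  "candidate in ≥ 1 replicate" tier-1 wording is coherent.
* **Tier 2.** The rank-based ROC AUC with adipose as positive class
  (Mann–Whitney form, ties half-credited) must exceed 0.7 in at least
  ⌈0.5 × n_replicates⌉ replicates — 2 of 3 in the default design.

Per-pixel values, not ROI means, feed both tiers: the contrast is defined
over pixels within regions. ROI means (3×3 blocks, the 150 µm × 150 µm
aggregation unit at 50 µm pixels) are used only for the technical
reproducibility statistics, where block averaging is the point: CV over
ROI means is approximately the pixel CV divided by 3, which is why the
low-reproducibility regime in the tests uses pixel CV 0.7, not 0.4.
"150 µm²" in the source description is read as a 150 µm × 150 µm block;
taken literally it would be smaller than a single 50 µm pixel.

Reported summaries follow the reference table's conventions: intensities as
means of per-replicate means, fold change as the ratio of those averages,
AUC and fold rounded to two decimals; `from_printed = TRUE` rounds
intensities to 3 significant digits *before* the ratio, which is the only
way the printed columns of the reference table reproduce each other.

## Lipid chemistry and identification

Molecular formulas follow per-class rules parameterized by total acyl
carbons c, double bonds d and extra oxygens x (e.g. FA: C_c H_{2c−2d}
O_{2+x}; TG: C_{c+3} H_{2c−2d+2} O_6; PC: C_{c+8} H_{2c−2d+16} N O_8 P),
validated against reference monoisotopic masses in the tests. Adduct
shifts are electron-mass corrected ([M−H]⁻ = M − 1.0072765; [M+Na]⁺ = M +
22.9892207): at m/z 200–900 the electron mass is 0.6–2.7 ppm, comparable to
the deviations being reported, so ignoring it would bias every Δppm column.
The ether-PE class (PEe) is implemented as plasmanyl; the shorthand in the
source material does not distinguish plasmanyl from plasmenyl, and the
choice only shifts the class formula by one double-bond equivalent.

The annotation database is a deterministic combinatorial enumeration over
per-class carbon/double-bond/oxidation grids (packaged defaults cover FA
12–24, DG 28–40, TG 40–60, PC/PE/PEe/PI 30–44, LPE 14–22), replacing a live
database query so results are reproducible offline. Accurate-mass search
returns all (lipid, adduct) hits within ±0.05 Da, sorted by |Δppm| with
deterministic tie-breaks (class name, then carbons).

MS² matching counts class-diagnostic rule fragments found within ±5 ppm,
inside a ±0.5 Da precursor window (the 1 Da isolation width). The source
text's "±0.05 ppm" match tolerance is physically implausible at the
fragment-scan resolution involved (15,000 ≈ 60 ppm peak width) and is
almost certainly a typo for ±5 ppm or ±0.05 Da; ±5 ppm is implemented and
exposed as a parameter rather than presented as the authors' setting.
Candidates with zero matched fragments are rejected; ties break by
precursor |Δppm|. A **Level-2 identification** requires the imaging side
and the MS² side to agree on both the lipid annotation and the adduct —
the integration rule replayed verbatim over the packaged reference table
in the acceptance checks.

## The synthetic phantom

The generator is the package's ground-truth instrument, emulating the study
conditions rather than instrument physics. A seed-jittered schematic layout
places muscle, liver, brain, eye, a gill band and two adipose depots
(visceral blob + subepidermal ribbon, together 5–20% of tissue) on a 40 ×
50 grid (~2000 pixels; full-scale sections run 40,000–60,000 pixels, and
nothing asserted here depends on full scale). The default panel plants 40
negative-mode species: 12 adipose-enriched fatty-acid-class features at
folds 1.5–2.8 (the reported fold-change range), 12 uniform nulls, and 16
phospholipid tissue markers (3.5× in a home tissue, 0.65× elsewhere, 0.3×
in adipose) that carry the between-tissue signature driving segmentation
while counting as nulls for enrichment. Pixel noise is multiplicative
lognormal at CV 15% (the platform's reported 10–20% band) plus a small
additive baseline; each replicate gets one global scale factor drawn from
0.8–1.25, mimicking interday drift. Base intensities were chosen once so
that expected adipose TIC modestly exceeds the other tissues, as in
lipid-rich fat — this matters because TIC normalization converts any TIC
imbalance into apparent (anti-)enrichment of null features, and the
direction constraint is what keeps specificity intact under it. Optional
M+1 satellites appear at +1.00336 Da with relative abundance 0.0107 ×
C/0.9893 from the species' carbon count.

What the phantom does *not* emulate — and what passing tests therefore do
not show about real data: profile peak shapes, mass-calibration drift,
Poisson counting noise (no count scale is reported for the source data),
spatial intensity gradients within a tissue, matrix effects, and real
histology geometry. Parameter recovery on the phantom demonstrates that the
statistical machinery is wired correctly at realistic effect sizes, not
that the thresholds are optimal for any particular instrument.

One consequence worth recording: with lognormal CV 15% and folds ≤ 2.8
after TIC normalization, a 20%-of-maximum display floor does not isolate
adipose in rendered ion images (the non-adipose background sits at 25–40%
of the maximum); the co-localization tests therefore use a 4×-enriched
feature — the fold reported for the showcase ion image in the source
study — at a 40% floor.

## Problem sizes and runtime

Default test and acceptance workloads: phantoms of ~2000 pixels × 40
features × 3 replicates for recovery (seeds 1–5), 1000-feature null
phantoms × 5 seeds for FDR calibration, 1000 random instances for the
ROC-versus-enumeration oracle. The full suite runs in well under a minute
on one core; the acceptance script in under half a minute.

## Known limitations

* Continuous-mode imzML only; no vendor formats, no processed-mode
  resampling.
* Fragment rules cover the classes appearing in the adipose signature and
  the spiked-standard panel (FA, TG, DG, PC, PE/PEe/PI/PG/PS carboxylates,
  LPE); SM/Cer precursor chemistry is parsed but has no MS² rule, so such
  candidates cannot be confirmed, only mass-annotated.
* Identification stops at Level 2: double-bond positions and sn-isomers
  are out of reach of the class rules by design.
* The bisection tree records members and dispersions but no dendrogram
  heights; it is a segmentation, not a hierarchy for cutting elsewhere.
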