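# lipidmsi

Spatial lipidomics for DESI mass spectrometry imaging: tissue segmentation,
two-tier adipose-enrichment statistics and cross-modal Level-2 lipid
identification, in one tested R pipeline.

## The problem

Desorption electrospray ionization MSI (DESI-MSI) rasters a tissue section
into a grid of full mass spectra (here m/z 100–1200 at 50 µm pixels), but
accurate mass alone cannot separate lipid isobars, and spatial enrichment
claims need statistics that respect replicate structure. This package
implements the integrated workflow used to map adipose depots in full-body
sections of diet-induced obese zebrafish: unsupervised segmentation finds
the adipose metabolic cluster, a two-tier statistical filter selects
adipose-enriched features, and liquid-extraction surface analysis tandem MS
(LESA-MS²) spectra from consecutive sections confirm the annotations at
Lipidomics Standards Initiative Level 2. It is aimed at analysts who want
the full chain — imzML in, identified enriched lipids out — with every step
testable against synthetic ground truth.

## The method

* **Preprocessing.** Per-pixel TIC normalization (each spectrum scaled to
  unit total ion current), optional rolling-minimum baseline correction,
  mean-spectrum peak picking, greedy cross-replicate alignment (tolerance
  0.02 Da) and M+1 deisotoping (Δm/z = 1.00336 ± 0.01 Da, satellite must be
  the smaller peak).
* **Segmentation.** Bisecting k-means on pixel spectra under the
  correlation distance d(u, v) = 1 − r(u, v): the leaf with the largest
  within-cluster dispersion is repeatedly split by 2-means (best of 10
  restarts) until 8 leaves. The adipose cluster is the leaf maximizing the
  Dice coefficient against the histology mask.
* **Enrichment (two tiers).** Tier 1: per replicate, Welch t-tests of
  adipose versus merged non-adipose pixels per feature,
  Benjamini–Hochberg-adjusted within the replicate; a candidate needs
  q < 0.05 *and* the adipose direction in ≥ 1 replicate. Tier 2: the
  rank-based ROC AUC (adipose positive; AUC = P(adipose pixel outranks
  non-adipose pixel), ties half-credited) must exceed 0.7 in ≥ ⌈0.5 n⌉
  replicates.
* **Annotation and identification.** Lipid shorthand is parsed to
  molecular formulas and monoisotopic masses; accurate-mass search
  (± 0.05 Da) against a packaged combinatorial lipid database over the
  common adducts ([M−H]⁻, [M+Cl]⁻, [M+HCOO]⁻, [M+OAc]⁻; [M+H]⁺,
  [M+H−H₂O]⁺, [M+Na]⁺, [M+NH₄]⁺, [M+K]⁺, electron-mass corrected);
  class-diagnostic MS² fragment rules (e.g. H₂O/CO₂ loss for fatty acids,
  acyl neutral losses for TG/DG, the m/z 184.0733 phosphocholine head for
  PC) score LESA-MS² spectra; a feature detected by both techniques as the
  *same lipid and same adduct* is a Level-2 identification.
* **Synthetic phantoms.** A generator plants a multi-tissue zebrafish-like
  section (muscle, liver, brain, eye, gill, two adipose depots) with
  tissue-marker phospholipids, adipose-enriched neutral lipids at fold
  changes 1.5–2.8, lognormal pixel noise (CV 15%), per-replicate intensity
  drift (0.8–1.25×) and optional isotopologue satellites — the ground truth
  every pipeline claim is tested against.

## Worked example

```r
library(lipidmsi)

# chemistry: the oxidized linoleic acid reported at m/z 295.23
rec <- parse_shorthand("FA (18:2;O)")
rec
#> FA(18:2;O) [C18 H32 O3]  M = 296.2351 Da
adduct_mz(rec, "[M-H]-")
#> [1] 295.2279

# accurate-mass annotation of the imaging feature
db <- build_lipid_database()
head(accurate_mass_search(295.23, "negative", db)[,
     c("shorthand", "adduct", "delta_ppm")], 3)
#>    shorthand   adduct   delta_ppm
#> 1 FA(18:2;O)   [M-H]-    7.220067
#> 2   FA(19:1)   [M-H]- -116.011133
#> 3   FA(15:3) [M+OAc]-  130.481645

# full pipeline on a simulated 3-replicate experiment
res <- run_pipeline(pipeline_config(seed = 1))
res$manifest$stage_counts[c("n_consensus_features",
                            "n_tier1_candidates", "n_enriched")]
#> $n_consensus_features  [1] 40
#> $n_tier1_candidates    [1] 12
#> $n_enriched            [1] 12
head(summarize_enrichment(res$enrichment), 4)
#>     avg_mz avg_intensity_adipose avg_intensity_nonadipose avg_fold_change avg_auc
#> 1 199.1704            0.03590402               0.02540802            1.41    0.95
#> 2 227.2017            0.03244186               0.02126391            1.53    0.98
#> 3 253.2173            0.02792046               0.01696941            1.65    0.99
#> 4 255.2330            0.05968604               0.03368858            1.77    1.00
res$partitions[[1]]$dice      # adipose cluster vs ground-truth mask
#> [1] 1
```

The phantom plants 40 features; all 12 planted adipose-enriched lipids (and
only those) pass both tiers, and the segmentation isolates the adipose
depots exactly. Reported fold changes are depressed relative to the planted
1.5–2.8 because TIC normalization divides adipose pixels by their larger
total signal — the same compositional effect a real analysis sees.

The packaged reference table of 52 adipose-enriched lipids identified in
HFD-fed zebrafish ships as `inst/extdata/table1_adipose_lipids.tsv`
(`load_table1()`), and replaying the same-lipid/same-adduct rule over it
yields exactly 52 Level-2 records.

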