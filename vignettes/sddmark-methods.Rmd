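---
title: "Methods: automated SDD lipid marker discovery from imaging mass spectrometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated SDD lipid marker discovery from imaging mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sddmark)
```

## The problem

Subretinal drusenoid deposits (SDD) are extracellular lesions between the
photoreceptors and the retinal pigment epithelium (RPE) that confer high risk
of progression in age-related macular degeneration. MALDI imaging mass
spectrometry (IMS) acquires one centroided mass spectrum per ~10 µm tissue
pixel, so each pixel carries the intensities of hundreds of lipid ions.
`sddmark` implements an automated workflow that (i) harmonizes the mass axis
across pixels, (ii) derives balanced SDD/background training labels from the
data themselves, (iii) trains a per-pixel gradient-boosted classifier, and
(iv) interrogates that classifier with exact TreeSHAP values to rank every
measured ion by its relevance to SDD recognition — positively (ion intensity
up in deposits) or negatively (ion avoids deposits). The top of the ranking
is a shortlist of marker candidates, annotated against theoretical lipid
masses.

Because no donor-eye raw data are publicly deposited, the package ships a
synthetic retina-phantom generator with full ground truth. The phantom is a
first-class, tested component: every downstream stage is validated against
known truth rather than against a fixed snapshot of outputs.

## The phantom and what it does (and does not) emulate

The phantom is a 2D section: four horizontal strata (inner retina, bacillary
layer — photoreceptor inner/outer segments —, RPE, choroid) with dome-shaped
deposit lesions seated on the top edge of the RPE band. Each compartment
carries a lipid panel:

* three deposit-exclusive lysolipids — LysoPC(18:3) [M+H]⁺, LysoPE(18:0)
  [M−H]⁻, LysoPA(16:0) [M−H]⁻ — each emitted as a monoisotopic +
  first-¹³C-isotopologue pair (six true marker features);
* precursor lipids (PC, PE, PA, SM) shared between deposits and the
  photoreceptor stratum;
* a deposit-excluded sphingomyelin, SM(42:1), present in the surrounding
  strata but absent from lesions — the planted negative marker;
* ubiquitous ions spanning the m/z range (including the recalibration
  references), as real lipid runs always contain;
* per-stratum filler species to widen the feature space toward realistic
  peak counts.

Signal corruption follows the acquisition physics: a smooth per-pixel mass
drift field (sum of three long-wavelength cosine modes, bounded by ±15 ppm by
default), an optional global systematic ppm error linear in m/z, per-pixel
multiplicative sensitivity (log-uniform in [0.5, 2]), per-peak lognormal
intensity variation (σ = 0.3), a truncated Gaussian noise floor, per-peak
detection dropout (15%), and occasional single-pixel outlier spikes (rate
0.01/pixel, 50–200 × the base peak) that exercise the robust normalization.

Two generator features matter scientifically:

* **Partial-volume mixing.** A lesion's local thickness follows a
  hemispherical dome profile; pixel signal is `h ×` deposit panel `+ (1−h) ×`
  displaced stratum panel. Lesion edges therefore carry mixed signal, as in
  real sections. This is what makes the deposit-excluded species genuinely
  informative to the classifier — with binary lesions the exclusive markers
  are jointly sufficient and negative evidence earns no credit, contrary to
  how real tissue behaves.
* **Detection dropout** prevents any single marker from being a perfect
  predictor, so the model spreads importance across the marker ensemble, as
  observed in practice.

What the phantom does **not** emulate: chemical noise and matrix clusters,
profile-mode peak shapes, ion suppression gradients, isotope-pattern
interferences between distinct species (panel species are kept ≥ 25 ppm
apart except for one deliberate 11 ppm near-pair), or inter-donor biological
variability. Passing tests therefore demonstrate that the pipeline's logic
is correct under controlled, physically plausible corruption — not that the
classifier numbers transfer to any particular instrument or tissue.

Default sizes: 200 × 120 px grid, 12 lesions of radius 9–14 px. This makes
the labeled SDD class ≈ 3,300–4,100 pixels, the scale typical of curated
training classes in donor-eye lipid IMS work (a few thousand pixels per
class); it also keeps a full end-to-end run well under a minute on one CPU.

## Preprocessing chain

1. **Common mass axis.** Geometric bin edges with constant relative spacing
   (default 1.5 ppm): `edges[i+1] = edges[i]·(1 + 1.5e−6)`. Over m/z
   300–2000 this gives ≈ 1.26 million bins.
2. **Alignment-reference selection.** Candidates are apexes of the
   *un-aligned* mean spectrum; occupancy is the fraction of pixels with a
   centroid within 25 ppm. The six most-occupied peaks (≥ 50% occupancy) are
   chosen under a 50 Th minimum mutual spacing (a left-to-right greedy pass
   maximizes the achievable count before trimming by occupancy). Because an
   apex of a drift-smeared spectrum can sit several ppm from the species'
   drift-median position — with a different offset per species when the
   drift-value distribution is multimodal — each reference is then re-centred
   on the median of its uniquely matched per-pixel positions.
3. **Per-pixel alignment.** One scalar ppm shift per pixel: the median ppm
   deviation of the uniquely matched references, applied as
   `mz ← mz/(1 + shift·1e−6)`. A reference with zero or several centroids in
   its ±25 ppm window is ignored for that pixel (ambiguous matches — e.g. a
   ¹³C isotopologue of one species ~11 ppm from another species' monoisotopic
   peak — would otherwise corrupt the estimate). Pixels with < 2 matched
   references are left unshifted with a warning.
4. **Calibration.** The ppm error model is linear in m/z (two coefficients),
   fitted by least squares over ≥ 4 reference ions matched in the aligned
   mean spectrum. Matching takes the *most intense* picked peak within the
   ±20 ppm search window; nearest-by-ppm matching can latch onto spurious
   low-intensity apexes left by the few unalignable pixels. The inverse
   correction is applied to every spectrum; the fitted model records median
   |residual| and warns above 5 ppm.
5. **Peak picking** on the calibrated mean spectrum: local maxima above
   `3 × MAD` of the binned spectrum (for centroid data without baseline the
   MAD over all bins estimates the additive noise floor) and above a relative
   prominence floor of 10⁻³ of the base peak; the apex m/z is the
   intensity-weighted centroid over the apex ± 1 bins. Isotopic peaks are
   deliberately retained.
6. **Feature extraction.** Summed centroid intensity within ±7 ppm of each
   picked feature, windows clipped at midpoints between adjacent features so
   no centroid is double-counted.
7. **Robust TIC normalization.** Per pixel, the robust TIC sums the observed
   intensities lying between that pixel's own 5th and 95th intensity
   percentiles; the pixel factor is `median(robust TIC)/robust TIC`. Two
   readings of "values outside the window are exempted from the
   normalization correction" are possible: exempt from the *sum* or exempt
   from the *rescaling*. We exempt them from the sum only — every intensity
   of the pixel is rescaled by the factor — because leaving the extremes
   unscaled would break within-pixel peak ratios and column comparability.
   The percentiles are taken over observed (nonzero) intensities: empty
   feature cells are absences, not measurements. The procedure is exactly
   idempotent and, at realistic per-pixel peak counts, a single 100× spike
   changes a pixel's factor by well under 5% because the spike sits above
   the 95th percentile.

## Label creation

Latent spatial patterns are extracted by non-negative matrix factorization
(rank 8 by default, Frobenius objective, multiplicative updates in the
Gram-matrix form). Initialization is deterministic NNDSVD — random
initialization reached different local minima across datasets, occasionally
failing to isolate the lesion pattern. Columns are winsorized at their
99.9th percentile first, so a single-pixel spike (intensity ~10³ × typical)
cannot dominate the objective.

One component is turned into the positive mask. By default the component is
auto-selected by a lesion-shape score: spatial compactness (mean fraction of
4-neighbours that are also positive) × coefficient of variation of
per-column mask heights × √(in-mask/out-mask mean-score contrast). The three
factors encode what distinguishes dome lesions: a tissue band is compact but
has constant column height; the *complement* of lesions within a band varies
in height but has diffuse scores; a noise tail is scattered. Users can
override with an explicit component index, and a correction mask (CSV or
PNG) can add/remove positives, mirroring histology-guided manual correction.

The score-to-mask threshold is Otsu's method on the component scores rather
than a fixed quantile: the lesion area fraction is not known a priori, and a
fixed high quantile (e.g. 95th) caps the positive class at 5% of pixels
regardless of the true lesion burden. A `threshold_quantile` option
reproduces fixed-quantile behaviour when wanted.

Negatives are drawn uniformly without replacement from non-positive pixels,
one per positive when possible, so SDD pixels can never enter the background
class and the classes are balanced.

## Classifier

`sdd_classifier()` is the package's central fitting function: a stratified
67/33 train/test split of the balanced labels, then an XGBoost ensemble
(logistic objective; defaults: 200 rounds, depth 4, η = 0.1,
`colsample_bytree = 0.5`, single thread). Column subsampling is on by
default because the marker features come in strongly correlated
monoisotopic/isotopologue pairs; forcing trees to see different feature
subsets spreads credit across the pair and stabilizes the SHAP ranking.
Held-out metrics are balanced accuracy (mean of per-class recalls),
precision, recall and F1 of the SDD class at a 0.5 threshold. Everything is
seeded and single-threaded, so a fixed seed reproduces the model, metrics
and ranking exactly.

## Interpretation

Local importance values are exact tree-path (TreeSHAP) Shapley values in
log-odds units, computed for *all* pixels (whole-tissue SHAP maps, not just
test pixels). The additivity identity — base value + row sum = model margin —
is asserted in the test suite at every pixel, and the values are
cross-checked against a brute-force Shapley enumeration (all 2^k feature
coalitions, cover-weighted conditional expectations) on small single-tree
models.

The global score of a feature is the mean absolute local value over pixels;
the direction is the sign of the Pearson correlation between the feature's
intensity and its local values (positive = "red", intensity increases SDD
probability; negative = "blue"). Features are ranked by descending global
score with ties broken toward lower m/z. The shortlist takes the top 20,
joins lipid annotations (±10 ppm nearest-match against theoretical masses),
and cross-references features lying k × 1.0033548 above an annotated
monoisotopic feature as its isotopes.

## Mass chemistry

Monoisotopic masses are summed from atomic constants (¹²C = 12 exactly,
H = 1.0078250319, …); adduct ions include the electron mass
([M+Na]⁺ = M + 22.98922). Composition rules per lipid class map the
"class(C:DB)" shorthand to elemental formulas, e.g. LPC(18:3) → C26H48NO7P
and PI(38:4) → C47H83O13P; SM uses the combined base+acyl carbon convention.
Only ¹³C isotopologues are modeled — at the ±7–10 ppm windows used, ²H/¹⁵N/¹⁸O
isotopes are irrelevant. These rules reproduce the reference marker and
calibrant m/z values used throughout the package — 480.310, 481.313,
518.324, 519.327 (three decimals) and 885.5499, 756.5514, 760.5851,
782.5670 (four decimals).

## Numerical choices and degenerate inputs

* Axis bin indices are computed in log space (O(1) per peak on megascale
  axes), with an explicit edge-consistency guard against log round-off.
* All-zero pixels normalize with factor 1 and a warning; empty spectra
  resample to zero vectors; an all-zero mean spectrum picks no peaks
  (not an error).
* Exact annotation ties (isobaric species) resolve to the first entry in
  ascending-m/z order, stably.
* NMF convergence: relative change in reconstruction error < 10⁻⁵ checked
  every 10 iterations, capped at 200.
* imzML is written in processed (centroided) mode, m/z as 64-bit and
  intensities as 32-bit floats; continuous-mode files are rejected on read.
  Pixel coordinates are 0-based internally (x = column, y = row) and
  converted to the format's 1-based convention at the boundary.

## Problem sizes used in validation

The test suite validates units on 60×48-pixel phantoms and the end-to-end
properties on the default 200×120 phantom: ten seeded runs for the
classifier-performance and marker-recovery properties, with the
classifier-performance labels taken from the ground-truth mask (the
phantom's analog of the study's manually curated annotations) and the
marker-recovery runs using the full NMF-derived labeling path. The
calibration-precision check uses a 100×60 phantom with ±15 ppm smooth drift
plus a (3 + 0.002·m/z) ppm global error.

## Known limitations

* One polarity per run; the phantom emits both adduct polarities in a single
  dataset for convenience and records a nominal polarity tag.
* The scalar per-pixel shift cannot correct non-linear intra-spectrum warp;
  the calibration model is linear in m/z. Both are the minimal models the
  corruption they correct calls for, and both are exposed as functions that
  can be replaced.
* The NMF component auto-selection is tuned to lesion-versus-band geometry;
  for tissues with different lesion morphology use the explicit
  `component` override.
* Spike features (genuine single-pixel outliers) survive peak picking by
  design; they are harmless to the classifier and ranking but inflate the
  feature count relative to the planted panel.
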