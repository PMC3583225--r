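---
title: "Quantified in situ patterns: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantified in situ patterns: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qispr)
```

## The method

qispr turns qualitative in situ hybridization (ISH) images of the
embryonic cerebral wall into 20-bin radial optical-density profiles
(QISPs) and groups them into laminar expression classes. The pipeline
has four stages, each usable on its own.

### Expression screen

Input is a gene-by-sample table of log2-scale RMA values. Because RMA is
log2, a difference of group means is a log2 fold-change and
`fold_change(t, r) = 2^(t − r)`. The "not expressed" threshold is derived
from negative-control genes (genes known to be silent in the tissue,
e.g. eye-specific genes in embryonic cortex) as

> threshold = mean(controls) + 2 · SD(controls), rounded **up** to the
> nearest 0.5 log2 unit.

The multiplier 2 and grain 0.5 are a reconstruction: with the canonical
internal standard (mean 5.5, SD 0.7 log2 units) the rule gives
5.5 + 1.4 = 6.9 → 7.0, the threshold used in practice, and every
analyzed gene is then expressed at least 2^1.5 ≈ 2.8-fold over baseline.
The threshold is always user-overridable.

A gene is **eligible** when the *larger* of its two group means reaches
the threshold. Restricting eligibility to the target group alone would
silently discard strongly down-regulated genes that have fallen below
threshold in the target while remaining well expressed in the reference;
taking the max preserves the rule's intent (exclude never-expressed
genes) symmetrically for both directions. Eligible genes with linear
fold ≥ cutoff (default 3) are up-regulated, ≤ 1/cutoff down-regulated,
with ties at exactly the cutoff included ("≥ k-fold" is inclusive).

### QISP extraction

The region of interest is an explicit input (as it is when placed by
hand on an atlas image): an axis from the ventricular to the pial
surface, a band width, and a pure-background rectangle. The band is
partitioned into 20 equal segments along the axis — sROI 1 ventricular,
sROI 20 pial, each 5% of the wall. Segment boundaries are
`round(k·L/20)` pixels along an axis of length L, half-open intervals
with the last closed, so the partition is deterministic for any axis
length and segment sizes differ by at most one pixel row. The grid is
computed by projection, so rotated (jittered) axes work identically.

Optical density defaults to the linear absorbance proxy
`(white − I)/white` in [0, 1]. Atlas images are stained-section
photographs, not calibrated transmittance measurements, so a linear
proxy is the honest default; a `−log10(I/white)` mode is available (with
intensities floored at 1 count to avoid divergence at full black).
Background is a scalar — the mean density of the background rectangle —
subtracted from every bin and floored at 0. Smoothing averages each bin
with its neighbours: window of 3 in the interior, window of 2 at the two
ends. No padding is invented beyond the wall; consequences are that
constant profiles are fixed points, monotone profiles stay monotone, and
smoothed values never leave the raw range.

The ventricular anchoring of sROI 1 is a fixed convention throughout the
package (profile vectors, deep ratio, zone map all index from the
ventricular surface).

### Deep-ratio validation

`deep_ratio = mean(sROI 1–2) / mean(sROI 3–20)`. Profiles with ratio
**strictly** greater than 1 are invalid: their expression is strongest at
the deep ventricular surface, the signature of precursor populations
rather than the differentiating lineage. Exactly 1.0 (e.g. a uniform
profile) is valid — the criterion is "exceeds 1", and the boundary
matters for flat patterns. A zero superficial mean makes the ratio
undefined; such VZ-only patterns are flagged invalid with reason
`"no superficial signal"` rather than raising an error, since they are
precisely what the criterion is meant to exclude. The ratio is computed
on the smoothed profile by default (the same variant that is clustered);
the variant is selectable because raw and smoothed ratios can differ for
profiles with signal concentrated at the ventricular edge.

### Clustering and zone assignment

Profiles are standardized per gene (mean 0, SD 1). Under the Pearson
distance `d = 1 − r` this changes no distance — Pearson correlation is
invariant to positive affine transforms, which is exactly why it suits
expression *patterns*: two genes with identical shapes but different
staining intensities are at distance 0. Standardization only equalizes
gene weights in the cluster centroids. Zero-variance profiles have no
defined correlation; they are tagged degenerate, excluded from the tree,
and reported with cluster `NA` / zone `"unassigned"` instead of
poisoning the distance matrix.

Agglomeration uses average linkage by default (the conventional choice
for correlation-based gene clustering; complete and single are
available). Genes are sorted lexicographically by id before clustering
so distance ties break deterministically and reruns give identical
trees. The flat cut at user-chosen k removes the k−1 highest merges;
cluster ids are renumbered by first appearance so they are stable across
sessions. There is no automatic choice of k: the method's published use
cut at k = 15 without a stated criterion, and we prefer an explicit
parameter over an invented selection rule.

Each cluster's centroid (mean of normalized members) is assigned to the
zone containing its argmax: deep = sROIs 1–10 (the VZ compartment),
middle = 11–15 (IZ), upper = 16–20 (CP/MZ) by default. Only the deep
boundary is well anchored in the literature; the 15/16 split is our
choice and the whole map is configurable. Exact argmax ties break toward
the more superficial bin, matching the developmental reading that more
superficial expression reflects a more mature state. Zone percentages
are reported both as integers (rounded half-up, never banker's rounding,
so 44/317 → 14 and 224/317 → 71) and at one decimal (49/317 → 15.5).

## The synthetic generator

The generator exists so the pipeline can be tested against known ground
truth without any atlas download. It emulates, with deliberately simple
models:

* **Radial archetypes** as sums of Gaussian bumps on the 1–20 sROI axis:
  `vz_peak` (centre 6), `iz_peak` (12), `cp_peak` (18), a Dab1-like
  `dual_peak` (5 and 17), `deep_invalid` (centre 1, the only archetype
  whose noise-free deep ratio exceeds 1), and `flat`. Amplitudes default
  to 0.6 optical-density units with 10% log-normal per-gene jitter.
  Archetype counts follow largest-remainder rounding, so membership
  totals are exact and deterministic.
* **Image rendering**: a vertical tissue band (wall span 200 px, band
  width 30 px in a 220 × 64 image by default) whose optical density is
  piecewise constant per sROI — which makes the extraction round trip
  analytically checkable — plus a background level (0.05), an additive
  illumination ramp (0.01 top-to-bottom), per-pixel Gaussian noise
  (SD 0.02 on the density scale) and 8- or 16-bit quantization with
  clamping.
* **Replicate jitter**: rigid ROI shift along the axis (SD 3 px),
  rotation about the band centre (SD 1.5°) and a log-normal staining
  scale (SD 0.05). These defaults were calibrated once so that five
  repeated measurements of a dual-peak profile show pairwise Pearson r
  of roughly 0.87–0.99 with means above 0.9 — the variation reported for
  repeated manual densitometry — and were not tuned further.
* **Expression matrices**: reference-group gene means ~ N(9, 0.8) log2
  units (comfortably expressed), target = reference + planted log2
  fold-change (drawn uniformly from [log2(3)+0.2, 6] so planted genes
  are unambiguous screen hits), replicate noise SD 0.25, three samples
  per group, and negative controls drawn i.i.d. from N(5.5, 0.7) in
  every sample.

No published noise model exists for colorimetric ISH staining, so the
noise magnitudes are calibration choices, not claims about real atlas
data. What the generator does **not** emulate: histological texture and
cell-scale granularity, section artifacts (folds, bubbles, missing
tissue), nonlinear stain saturation, spatially correlated background,
and the curvature of the real cerebral wall. Passing tests therefore
demonstrate that the *arithmetic and geometry* of the pipeline are
correct and robust to placement jitter and pixel noise — not that the
deep-ratio criterion or the clustering would behave identically on real
stained sections, where ROI placement and background choice remain the
dominant, operator-controlled sources of variation.

## Numerical and degenerate-input choices

* All randomness flows through explicit integer seeds
  (`withr::with_seed`), and the pipeline derives per-stage seeds from
  one top-level seed: identical config + seed gives byte-identical
  outputs.
* Proportions must sum to 1 within 1e-9; archetype counts are then exact
  by construction.
* Rendered intensities clamp to the bit-depth range; densities above
  ~0.9 optical-density units saturate, so archetype amplitudes stay
  below that.
* Empty masks, empty groups, unknown archetypes/groups, k out of range
  and absent input paths are hard errors; undefined deep ratios and
  degenerate profiles are *flags*, not errors, because they are
  meaningful analysis outcomes.
* Missing images are a policy (`skip`, recorded in the manifest, or
  `fail`), mirroring the reality that public atlases do not cover every
  screened gene.

## Test problem sizes

The suite runs planted-truth checks at sizes chosen to finish in seconds
while leaving no statistical ambiguity: 60-gene cohorts for archetype
separability and cluster recovery (20 seeds × 60 genes for the 95%
recovery property), a 328-gene cohort (11 deep-invalid) for the
validation bookkeeping, 5-replicate concordance, and ≤ 200-gene random
matrices against a brute-force screen oracle. The acceptance script
re-runs the same computations from scratch under a user-supplied seed.

## Known limitations

* ROI placement is manual by design; there is no automatic wall
  detection or registration.
* Background is a single scalar per image; per-sROI background
  correction is out of scope.
* The screen is a pure fold/threshold rule — no variance moderation or
  multiple-testing machinery — faithful to the original design and
  appropriate for its small-replicate setting, but not a substitute for
  a differential-expression model.
* Zone assignment is per cluster centroid (a per-gene reading can be
  obtained by clustering with large k); heterogeneous clusters straddling
  a zone boundary inherit their centroid's zone.
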