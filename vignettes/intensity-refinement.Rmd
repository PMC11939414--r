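---
title: "Intensity-based refinement of hippocampal segmentations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-based refinement of hippocampal segmentations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hipporefine` treats segmentation quality as a correction problem. The
hippocampus is a gray-matter structure that legitimately contains interposed
white matter (alveus, fimbria), tiny enhancing vessels and occasional
CSF-intensity cysts. The common segmentation errors are the converse:
missing marginal gray matter, included marginal CSF, and included enhancing
tissue (above all choroid plexus along the superior margin). Given paired,
coregistered precontrast and postcontrast T1 volumes, each of these errors is
detectable from voxel intensities alone, so each candidate segmentation can
be *refined* and the refinement effort measured. The total correction
volume — gray matter added plus CSF removed plus enhancement removed, in
mL — is the quality score; segmentations needing less correction are better.

Three study-level references drive the classification:

* **Gray-matter range.** Mean ± k·SD of T1 intensities over the *aggregate
  smallest* segmentation, the voxelwise intersection of every candidate
  (including every threshold of probability-map candidates). Because this
  consensus core contains the interior white matter, vessels and cysts, its
  SD is wider than that of pure gray matter — deliberately so: the range
  must capture the hippocampal tissue mixture, and the interval edges stay
  well clear of pure white matter and CSF.
* **CSF range.** Mean ± k·SD of T1 intensities over a ventricular CSF
  reference (conventionally the right lateral ventricle of a whole-brain
  parcellation; `extract_label_mask()` pulls label 43 by default), after
  excluding enhancing voxels so intraventricular choroid plexus does not
  contaminate the statistics.
* **Enhancement rule.** The subtraction image is
  `(post_norm − pre_norm) × 1000` with each volume min–max normalized over
  its whole field of view (background included); a voxel is enhancing iff
  its subtraction value strictly exceeds mean + k·SD of the whole
  subtraction volume.

All three use the population SD (divide by n) and `k = 1` by default; the
multipliers are exposed (`k_gm`, `k_csf`, `k_enh`) because only the
gray-matter convention is firmly established and the CSF/enhancement
multipliers are modelling choices. Gray-matter and CSF membership is a
closed interval; enhancement is a strict inequality, so an all-zero
subtraction volume classifies nothing as enhancing and a probability
threshold of 1.0 yields an empty mask.

## The refinement procedure

For one candidate segmentation, in order:

1. **Gray-matter addition.** Candidates are the one-iteration dilation shell
   (6-connectivity by default). A voxel is retained iff it is in the
   gray-matter range, inside the *aggregate largest* segmentation (the union
   of all candidates — this prevents leaking into adjacent gray matter such
   as the parahippocampal gyrus), and not enhancing (this keeps isointense
   choroid plexus out). Retained voxels are joined to the label; joined
   components not connected to the original label are discarded.
2. **CSF removal.** The margin is the overlap of the *aggregate shell*
   (union minus intersection — the zone where candidates disagree) with the
   current label. Margin voxels in the CSF range are removed; the label is
   then reduced to its largest connected component.
3. **Enhancement removal.** Same margin logic against the current label;
   membership is the subtraction-image rule. Interior enhancing voxels sit
   inside the consensus core, hence outside the shell, and are never
   removed.

The enhancement classification is computed *before* step 1 because step 1
already needs it. The shell and union are computed once from the original
candidates; margins are recomputed against the running label at each
subtraction step (the alternative — freezing the margin at the original
label — differs only for voxels added in step 1, and the running-state
choice lets erroneously added voxels be corrected again rather than locked
in). Voxels disconnected by a subtraction step are attributed to that step's
removed volume, which makes the bookkeeping identity exact for every run:

```
|refined| = |original| + |added GM| − |removed CSF| − |removed enhancement|
```

Island analysis uses 26-connectivity (diagonal touching counts, conservative
against over-removal) while dilation uses 6-connectivity (face neighbours,
the common default of binary-dilation routines); both are configurable
because neither choice is canonical. Component ties are broken by the
smaller first linear (column-major) voxel index, so results are
deterministic. Grid compatibility (shape, spacing, orientation token) is
checked on every combination of volumes; the package never resamples.

Probability-map candidates are binarized at `p > t` for a default grid of
0.0–1.0 in steps of 0.1 and refined per threshold; empty thresholds are
skipped with a warning rather than an error (a threshold of 1.0 can never
retain anything under strict `>`). The reported optimum is the threshold
minimizing total correction, ties to the lowest threshold.
`fragmentation_flag()` provides an automated stand-in for visual quality
review: more than 5 components, or a largest component under 90% of the
mask, flags a segmentation as too fragmented to assess.

## Statistics

Observations are per-hippocampus totals (left and right are separate rows).
`compare_algorithms()` always runs and reports all four stages —
Shapiro–Wilk per group, Levene's test centred on the mean, Welch's ANOVA,
Tukey HSD — rather than branching on intermediate p-values: the cascade's
role is to document why the heteroscedasticity-robust omnibus test is
appropriate, and the pairwise Tukey table (mean difference, adjusted p, CI,
significance flag at α = 0.05) is the primary output. Left and right sides
share the study references (gray matter from the right-side consensus, CSF
from the right lateral ventricle), matching the convention of building all
references on the right side once per study.

## The phantom generator

`phantom_spec()` / `phantom_generate()` build a synthetic subject on a
64×64×44 voxel grid at 1 mm isotropic: per side, a gray-matter ellipsoid
hippocampus (semi-axes 8×14×7 voxels, ≈3.3 mL) containing a white-matter
sheet, 12 enhancing vessel voxels and 10 cyst voxels; a CSF cap over its
superior surface; an enhancing plexus-like blob abutting the superior
margin; and a box ventricle with a one-voxel partial-volume rim along its
superior wall and an intraventricular enhancing blob. Intensity bands
default to GM 100±5, WM 140±5, CSF 10±3, plexus 80, partial volume 75
(arbitrary units), +300 postcontrast boost on enhancing voxels, and additive
Gaussian acquisition noise of SD 5 — 5% of the GM mean — on pre and post
independently. Bands must be separated by more than twice the summed SDs, or
the spec is rejected.

Two generator properties matter for interpreting test results:

* The ventricle's partial-volume rim is what makes the CSF range *work*. A
  reference of pure CSF would give a range of exactly ±1 SD of the CSF
  population, which by construction captures only ~68% of CSF voxels; the
  rim widens the interval (as real ventricle labels, which always include
  boundary voxels, do) so that marginal CSF is captured almost completely
  while gray matter stays excluded. Real studies inherit this behaviour from
  imperfect ventricle parcellations; the phantom makes it explicit.
* Candidate errors are realized as whole voxels in disjoint per-candidate
  regions (y-stripes of the CSF cap and plexus, sized in proportion to the
  requested volumes), grown by face-adjacency from the hippocampus surface.
  Every injected voxel therefore lies in the disagreement shell and stays
  connected to its label, and the ledger records requested and realized
  volumes exactly — requests beyond a region's capacity are clipped and
  recorded honestly.

Probability-map candidates assign 0.95 to the truth core, 0.65 to the truth
boundary layer, 0.35/0.15 to the CSF rim (adjacent/deeper) and 0.25/0.12 to
the enhancing blob, so the optimal threshold is known to lie in (0.4, 0.6)
and correction curves are monotone in threshold by construction.

What the phantom does *not* emulate: bias fields, partial-volume ramps at
every tissue interface, anatomy beyond coarse topology, registration error,
or the intensity overlap of real tissue classes. Passing phantom tests
demonstrates that the machinery is correct — exact recovery in the
noise-free limit, graceful degradation under noise — not that the method's
tissue model is adequate for any particular scanner or population.

## Numerical choices and degenerate inputs

* Population SD throughout; masked statistics require ≥ 2 voxels, otherwise
  an insufficient-sample error names the cause (including the
  enhancing-voxel exclusion, when that is what emptied the sample).
* Min–max normalization errors on constant-intensity volumes.
* An empty mask dilates to an empty mask with a warning; a subtraction step
  that would empty the segmentation warns and reports the whole label as
  removed.
* Thresholds outside [0, 1], unsorted sweep grids, mismatched grids and
  sub-minimal statistics groups all fail loudly.

## Validation suite sizes

The test suite runs entirely on generated data: morphology primitives are
checked against brute-force oracles on 100 random 8×8×8 masks per property;
refinement bookkeeping and delta-mask disjointness on 40 randomized
small-grid (40×40×32) phantoms plus every other refinement in the suite;
injected-error recovery noise-free (voxel-exact) and at 5% noise (±10%); and
ranking recovery with Tukey separation on a 30-subject cohort with mock
algorithms injected at ~0.3/0.6/1.0 mL mean total error. These sizes were
chosen to keep the full suite around two minutes on one CPU while leaving
each property with substantial random coverage; `scripts/acceptance.R`
recomputes the headline quantities at the same sizes.

## Known limitations

* The method assumes roughly accurate inputs: the union constraint and the
  shell margin come from the candidates themselves, so a cohort of uniformly
  wrong segmentations yields references and margins that are wrong in the
  same way. It ranks candidates; it does not certify any of them.
* Correction volumes are comparative estimates, not calibration factors:
  refined masks are a by-product, not ground-truth-grade segmentations.
* Postcontrast acquisitions are required, which rules out most public
  datasets.
* Preprocessing (bias correction, rigid registration, resampling to a
  common ~1 mm grid) is out of scope and must be done upstream.
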