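# hipporefine

Intensity-based refinement and assessment of automated hippocampal
segmentations on paired precontrast and postcontrast T1-weighted MRI —
without manual or consensus ground-truth labels.

## The problem

Hippocampal volumetry drives the assessment of Alzheimer's disease and
mesial temporal sclerosis, and small errors matter: a ~1 mL shift can move a
patient across most of an age-normalized percentile range. Automated
segmentations commonly include tissue that is not hippocampus — enhancing
choroid plexus and vessels along the superior margin, and surrounding CSF —
and commonly miss marginal gray matter. Dice-style comparison against manual
or consensus ("virtual ground truth") labels cannot quantify these
inclusions, because the reference labels suffer from the same errors.

`hipporefine` instead asks, voxel by voxel: *how much correction does each
segmentation need?* Each candidate segmentation is refined at its margins
by three operations, and the total correction volume (mL) ranks competing
algorithms — lower is better:

1. **Gray matter added.** Candidate voxels are the one-iteration dilation
   shell of the segmentation. A voxel is added iff its precontrast T1
   intensity lies within the gray-matter range
   `[μ_GM − k·σ_GM, μ_GM + k·σ_GM]` (computed over the *aggregate smallest*
   segmentation — the voxelwise intersection of all candidates), it lies
   inside the *aggregate largest* segmentation (the union), and it is not
   enhancing. Added voxels disconnected from the original label are dropped.
2. **CSF removed.** The correction margin is the overlap of the candidate
   with the *aggregate shell* (union minus intersection — the disagreement
   zone). Margin voxels whose T1 intensity falls in the CSF range
   `[μ_CSF ± k·σ_CSF]` (computed over a ventricular CSF reference mask,
   enhancing voxels excluded) are removed, then islands are removed.
3. **Enhancement removed.** Same margin, but membership is a strict
   threshold `s > μ_s + k·σ_s` on the subtraction image
   `s = (post_norm − pre_norm) × 1000`, where each volume is min–max
   normalized to [0, 1]. Because corrections are restricted to the
   disagreement shell, interior enhancing vessels and CSF-intensity cysts —
   which genuinely belong to the hippocampus — are never touched.

All statistics use the population SD (divide by *n*) and default to `k = 1`.
Candidates may be binary masks or probability maps; probability maps are
swept across thresholds (strict `>`; 0.0–1.0 in steps of 0.1 by default) and
the threshold minimizing total correction is reported. Cohorts are compared
with Shapiro–Wilk, Levene, Welch's ANOVA and Tukey HSD on per-hippocampus
total corrections.

A fully synthetic phantom generator (paired pre/post volumes, ventricle
reference, candidate segmentations with voxel-exact injected errors) makes
every stage testable without clinical data.

## Worked example

```r
library(hipporefine)

# a noise-free phantom subject with two mock algorithms; mockA carries known
# errors: 0.1 mL gray matter eroded, 0.2 mL CSF rim, 0.3 mL enhancing blob
b   <- phantom_generate(phantom_spec(noise_free = TRUE))
sub <- compute_subtraction(b$t1_pre, b$t1_post)

cands <- lapply(b$candidates, function(a) a$right$mask)
ctx   <- refine_context(cands, b$t1_pre, sub, b$csf_reference)
refine(cands$mockA, ctx)
```

```
<refinement>
<correction_record> total 0.6000 mL = GM added 0.1000 + CSF removed 0.2000 + enh removed 0.3000
  original 3.6670 mL -> refined 3.2670 mL
```

The three injected errors are recovered exactly — 0.1 mL of eroded gray
matter is added back, and the 0.2 mL CSF rim and 0.3 mL enhancing blob are
removed — so the candidate needs 0.6 mL of total correction and the refined
mask equals the 3.267 mL ground-truth hippocampus.

For real data, `run_refine_config(read_run_config("run.yaml"))` executes the
same pipeline from NIfTI files (coregistered pre/post volumes, a ventricle
mask or whole-brain parcellation, and the candidate segmentations), writing
the subtraction image, intensity ranges, delta masks and a corrections CSV.
A thin command-line wrapper lives at `inst/cli/hipporefine.R`
(`refine`, `phantom` and `cohort` commands). Inputs are assumed already
N4-corrected, rigidly registered to a common space, and resampled to a
shared grid (e.g. with ANTs); the package never resamples silently.

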