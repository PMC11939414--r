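#' Subtraction image and per-study tissue intensity references
#'
#' Tissue classification is intentionally simple and per-study: a closed
#' interval mean +/- k*SD over a reference mask for gray matter and CSF, and a
#' strict threshold mean + k*SD over the pre/post-contrast subtraction image
#' for enhancement. All statistics use the population SD (divide by n); this
#' flavour is fixed and documented rather than configurable per call.
#'
#' @name intensity_reference
NULL

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

new_intensity_range <- function(mean, sd, k, source_mask_label, n_voxels) {
  structure(list(lo = mean - k * sd, hi = mean + k * sd,
                 mean = mean, sd = sd, k = k,
                 source_mask_label = source_mask_label,
                 n_voxels = n_voxels),
            class = "intensity_range")
}

#' @export
print.intensity_range <- function(x, ...) {
  cat(sprintf("<intensity_range:%s> [%.4g, %.4g] (mean %.4g, sd %.4g, k=%g, n=%d)\n",
              x$source_mask_label, x$lo, x$hi, x$mean, x$sd, x$k, x$n_voxels))
  invisible(x)
}

#' Build the pre/post-contrast subtraction image
#'
#' Both volumes are min-max normalized to \[0, 1\] independently over the whole
#' volume (background air included), subtracted (post minus pre) and scaled by
#' 1000, giving values in \[-1000, 1000\]. Enhancing tissue, which brightens
#' after gadolinium, stands out as strongly positive.
#'
#' @param pre,post coregistered `intensity_volume`s on one grid.
#' @return an `intensity_volume` of subtraction intensities.
#' @export
compute_subtraction <- function(pre, post) {
  stopifnot(inherits(pre, "intensity_volume"), inherits(post, "intensity_volume"))
  stopifnot_same_grid(pre, post)
  norm01 <- function(v, what) {
    rng <- range(v$data)
    if (rng[1] == rng[2])
      stop(sprintf("degenerate %s volume: constant intensity %g", what, rng[1]),
           call. = FALSE)
    (v$data - rng[1]) / (rng[2] - rng[1])
  }
  sub <- (norm01(post, "postcontrast") - norm01(pre, "precontrast")) * 1000
  intensity_volume(sub, spacing = pre$spacing, grid_id = pre$grid_id)
}

masked_range <- function(vol, keep, k, label, insufficient_msg) {
  vals <- vol$data[keep]
  if (length(vals) < 2L) stop(insufficient_msg, call. = FALSE)
  new_intensity_range(mean(vals), pop_sd(vals), k, label, length(vals))
}

#' Gray-matter intensity range from the consensus segmentation
#'
#' Mean +/- k*SD of precontrast T1 intensities inside the aggregate smallest
#' (consensus) segmentation. Because the consensus core also contains the
#' interposed white-matter structures, vessels and occasional cysts that
#' legitimately belong to the hippocampus, its SD is wider than that of pure
#' gray matter, which is what lets the range capture marginal gray matter
#' reliably.
#'
#' @param t1 precontrast `intensity_volume`.
#' @param smallest_seg consensus `binary_mask` (>= 2 voxels).
#' @param k SD multiplier, default 1.
#' @return an `intensity_range`.
#' @export
gm_range <- function(t1, smallest_seg, k = 1) {
  stopifnot(inherits(t1, "intensity_volume"), inherits(smallest_seg, "binary_mask"))
  stopifnot_same_grid(t1, smallest_seg)
  masked_range(t1, smallest_seg$data, k, "gm_consensus",
               "consensus segmentation has fewer than 2 voxels")
}

#' CSF intensity range from a ventricular reference
#'
#' Mean +/- k*SD of precontrast T1 intensities inside the CSF reference mask
#' (typically the right lateral ventricle from a whole-brain segmentation)
#' after excluding enhancing voxels, so intraventricular choroid plexus does
#' not contaminate the CSF statistics.
#'
#' @param t1 precontrast `intensity_volume`.
#' @param csf_reference `binary_mask` of the CSF reference region.
#' @param enhancing `binary_mask` of enhancing voxels to exclude (may be empty).
#' @param k SD multiplier, default 1.
#' @return an `intensity_range`.
#' @export
csf_range <- function(t1, csf_reference, enhancing, k = 1) {
  stopifnot(inherits(t1, "intensity_volume"),
            inherits(csf_reference, "binary_mask"),
            inherits(enhancing, "binary_mask"))
  stopifnot_same_grid(t1, csf_reference)
  stopifnot_same_grid(t1, enhancing)
  keep <- csf_reference$data & !enhancing$data
  masked_range(t1, keep, k, "csf_reference",
               paste("CSF reference has fewer than 2 voxels after excluding",
                     "enhancing (choroid plexus) voxels"))
}

#' Enhancement classification rule from the subtraction image
#'
#' The threshold is mean + k*SD over all voxels of the subtraction volume; a
#' voxel is enhancing iff its subtraction value is strictly greater than the
#' threshold.
#'
#' @param sub subtraction `intensity_volume`.
#' @param k SD multiplier, default 1.
#' @return an object of class `enhancement_rule` with fields `threshold`,
#'   `mean`, `sd`, `k`.
#' @export
enhancement_rule <- function(sub, k = 1) {
  stopifnot(inherits(sub, "intensity_volume"))
  m <- mean(sub$data)
  s <- pop_sd(sub$data)
  structure(list(threshold = m + k * s, mean = m, sd = s, k = k),
            class = "enhancement_rule")
}

#' @export
print.enhancement_rule <- function(x, ...) {
  cat(sprintf("<enhancement_rule> enhancing iff subtraction > %.4g (mean %.4g, sd %.4g, k=%g)\n",
              x$threshold, x$mean, x$sd, x$k))
  invisible(x)
}

#' Classify enhancing voxels
#'
#' @param sub subtraction `intensity_volume`.
#' @param rule an `enhancement_rule`.
#' @param within optional `binary_mask`; result is intersected with it.
#' @return `binary_mask` of enhancing voxels.
#' @export
classify_enhancing <- function(sub, rule, within = NULL) {
  stopifnot(inherits(sub, "intensity_volume"), inherits(rule, "enhancement_rule"))
  enh <- sub$data > rule$threshold
  if (!is.null(within)) {
    stopifnot(inherits(within, "binary_mask"))
    stopifnot_same_grid(sub, within)
    enh <- enh & within$data
  }
  mask_like(sub, enh, label = "enhancing")
}

# closed-interval membership for GM/CSF ranges
in_range <- function(values, range) values >= range$lo & values <= range$hi

#' Extract one integer label from a multi-label volume as a binary mask
#'
#' Convenience for pulling a CSF reference out of a whole-brain segmentation;
#' label 43 is the common right-lateral-ventricle code of whole-brain
#' segmentation outputs.
#'
#' @param labels `intensity_volume` holding integer labels.
#' @param label_id integer label to extract, default 43.
#' @export
extract_label_mask <- function(labels, label_id = 43) {
  stopifnot(inherits(labels, "intensity_volume"))
  mask_like(labels, labels$data == label_id,
            label = sprintf("label-%d", as.integer(label_id)))
}
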