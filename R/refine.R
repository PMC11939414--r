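#' Marginal refinement of a hippocampal segmentation
#'
#' The correction engine. Each candidate segmentation is refined in three
#' marginal steps — gray-matter addition, CSF removal, enhancement removal —
#' against study-level references held in a [refine_context()]:
#' the aggregate largest/smallest segmentations and disagreement shell built
#' once from all candidates, the gray-matter and CSF intensity ranges, and the
#' subtraction-image enhancement rule. The sum of the three correction
#' volumes (mL) is the segmentation's quality score: lower is better.
#'
#' @name refinement
NULL

#' Build the per-study refinement context
#'
#' Aggregates are computed once from the original candidate segmentations
#' (all algorithms and, for probability maps, all thresholds); intensity
#' references are derived from them and from the CSF reference mask. The
#' enhancement rule is computed before any refinement because gray-matter
#' addition must already exclude enhancing voxels.
#'
#' @param candidates list of >= 2 `binary_mask` candidate segmentations used
#'   to form the aggregates (conventionally the right-side segmentations; the
#'   resulting references are applied to both sides).
#' @param t1 precontrast `intensity_volume`.
#' @param sub subtraction `intensity_volume` (see [compute_subtraction()]).
#' @param csf_reference `binary_mask` CSF reference region (e.g. right lateral
#'   ventricle).
#' @param k_gm,k_csf,k_enh SD multipliers for the three references, default 1.
#' @param dilation_connectivity structuring element for gray-matter dilation
#'   (6, 18 or 26; default 6).
#' @param island_connectivity connectivity for island removal (default 26).
#' @param gm,csf optional precomputed `intensity_range`s. Used to apply the
#'   right-side references to the left side: per study the gray-matter range
#'   comes from the right consensus and the CSF range from the right lateral
#'   ventricle, and both are shared across sides.
#' @return an object of class `refine_context`.
#' @export
refine_context <- function(candidates, t1, sub, csf_reference,
                           k_gm = 1, k_csf = 1, k_enh = 1,
                           dilation_connectivity = 6,
                           island_connectivity = 26,
                           gm = NULL, csf = NULL) {
  stopifnot(inherits(t1, "intensity_volume"), inherits(sub, "intensity_volume"))
  stopifnot_same_grid(t1, sub)
  check_mask_list(candidates)
  stopifnot_same_grid(t1, candidates[[1]])
  stopifnot_same_grid(t1, csf_reference)
  largest <- mask_union(candidates)
  smallest <- mask_intersection(candidates)
  shell <- mask_like(largest, largest$data & !smallest$data, label = "shell")
  rule <- enhancement_rule(sub, k = k_enh)
  enhancing <- classify_enhancing(sub, rule)
  structure(list(
    largest = largest, smallest = smallest, shell = shell,
    gm = gm %||% gm_range(t1, smallest, k = k_gm),
    csf = csf %||% csf_range(t1, csf_reference, enhancing, k = k_csf),
    rule = rule, enhancing = enhancing,
    t1 = t1, sub = sub,
    dilation_connectivity = dilation_connectivity,
    island_connectivity = island_connectivity),
    class = "refine_context")
}

#' @export
print.refine_context <- function(x, ...) {
  cat("<refine_context>\n")
  cat(sprintf("  aggregates: largest %d vox, smallest %d vox, shell %d vox\n",
              voxel_count(x$largest), voxel_count(x$smallest), voxel_count(x$shell)))
  print(x$gm); print(x$csf); print(x$rule)
  invisible(x)
}

#' Add marginal gray matter to a segmentation
#'
#' Candidate voxels are the one-iteration dilation shell of the segmentation;
#' a voxel is retained iff its T1 intensity lies in the gray-matter range, it
#' falls inside the aggregate largest segmentation, and it is not enhancing
#' (so isointense enhancing structures such as choroid plexus are never added).
#' Retained voxels are joined to the segmentation and any resulting islands
#' not connected to the original segmentation are dropped.
#'
#' @param seg non-empty `binary_mask`.
#' @param largest aggregate largest segmentation.
#' @param gm gray-matter `intensity_range`.
#' @param enhancing `binary_mask` of enhancing voxels.
#' @param t1 precontrast `intensity_volume`.
#' @param dilation_connectivity,island_connectivity see [refine_context()].
#' @return list with `augmented` and `added` masks.
#' @export
add_marginal_gm <- function(seg, largest, gm, enhancing, t1,
                            dilation_connectivity = 6,
                            island_connectivity = 26) {
  stopifnot(inherits(seg, "binary_mask"), inherits(gm, "intensity_range"))
  stopifnot_same_grid(t1, seg)
  stopifnot_same_grid(t1, largest)
  stopifnot_same_grid(t1, enhancing)
  if (!any(seg$data)) stop("cannot add gray matter to an empty segmentation",
                           call. = FALSE)
  rim <- dilate_once(seg, dilation_connectivity)$data & !seg$data
  keep <- rim & in_range(t1$data, gm) & largest$data & !enhancing$data
  aug <- mask_like(seg, seg$data | keep, label = seg$label)
  aug <- remove_islands(aug, anchor = seg, connectivity = island_connectivity)
  list(augmented = aug,
       added = mask_like(seg, aug$data & !seg$data, label = "added_gm"))
}

#' Margin for CSF and enhancement subtraction
#'
#' The overlap between the aggregate disagreement shell and the individual
#' segmentation. Using the shell rather than a one-voxel erosion lets large
#' over-segmentations be corrected in full.
#'
#' @param seg `binary_mask` (current state of the segmentation).
#' @param shell aggregate shell `binary_mask`.
#' @export
csf_margin <- function(seg, shell) {
  stopifnot(inherits(seg, "binary_mask"), inherits(shell, "binary_mask"))
  stopifnot_same_grid(seg, shell)
  mask_like(seg, seg$data & shell$data, label = "margin")
}

# shared core of the two marginal-subtraction steps: remove `hit` voxels of
# the margin, then keep the largest connected component; voxels disconnected
# by the removal are attributed to this step so bookkeeping stays exact
subtract_and_deisland <- function(seg, hit, island_connectivity, what) {
  reduced0 <- seg$data & !hit
  if (!any(reduced0)) {
    warning(sprintf("%s subtraction removed the entire segmentation", what),
            call. = FALSE)
    return(list(reduced = mask_like(seg, reduced0, label = seg$label),
                removed = mask_like(seg, seg$data, label = paste0("removed_", what))))
  }
  reduced <- remove_islands(mask_like(seg, reduced0, label = seg$label),
                            anchor = NULL, connectivity = island_connectivity)
  list(reduced = reduced,
       removed = mask_like(seg, seg$data & !reduced$data,
                           label = paste0("removed_", what)))
}

#' Remove marginal CSF from a segmentation
#'
#' Margin voxels whose T1 intensity falls in the CSF range are removed; the
#' segmentation is then reduced to its largest connected component, and any
#' voxels disconnected by the removal are counted as removed by this step.
#'
#' @param seg `binary_mask`.
#' @param margin `binary_mask`, subset of `seg` (see [csf_margin()]).
#' @param csf CSF `intensity_range`.
#' @param t1 precontrast `intensity_volume`.
#' @param island_connectivity default 26.
#' @return list with `reduced` and `removed` masks.
#' @export
remove_marginal_csf <- function(seg, margin, csf, t1, island_connectivity = 26) {
  stopifnot(inherits(seg, "binary_mask"), inherits(csf, "intensity_range"))
  stopifnot_same_grid(seg, margin)
  stopifnot_same_grid(seg, t1)
  if (any(margin$data & !seg$data))
    stop("margin must be a subset of the segmentation", call. = FALSE)
  hit <- margin$data & in_range(t1$data, csf)
  subtract_and_deisland(seg, hit, island_connectivity, "csf")
}

#' Remove marginal enhancement from a segmentation
#'
#' Same contract as [remove_marginal_csf()] but membership is a strict
#' threshold on the subtraction image. Interior enhancing voxels (vessels)
#' lie outside the disagreement shell and are therefore never touched.
#'
#' @param seg `binary_mask`.
#' @param margin `binary_mask`, subset of `seg`.
#' @param rule an `enhancement_rule`.
#' @param sub subtraction `intensity_volume`.
#' @param island_connectivity default 26.
#' @return list with `reduced` and `removed` masks.
#' @export
remove_marginal_enh <- function(seg, margin, rule, sub, island_connectivity = 26) {
  stopifnot(inherits(seg, "binary_mask"), inherits(rule, "enhancement_rule"))
  stopifnot_same_grid(seg, margin)
  stopifnot_same_grid(seg, sub)
  if (any(margin$data & !seg$data))
    stop("margin must be a subset of the segmentation", call. = FALSE)
  hit <- margin$data & sub$data > rule$threshold
  subtract_and_deisland(seg, hit, island_connectivity, "enh")
}

new_correction_record <- function(seg, added, removed_csf, removed_enh, refined) {
  vox_ml <- prod(seg$spacing) / 1000
  gm_vox <- voxel_count(added)
  csf_vox <- voxel_count(removed_csf)
  enh_vox <- voxel_count(removed_enh)
  rec <- list(
    gm_added_ml = gm_vox * vox_ml,
    csf_removed_ml = csf_vox * vox_ml,
    enh_removed_ml = enh_vox * vox_ml,
    gm_added_vox = gm_vox,
    csf_removed_vox = csf_vox,
    enh_removed_vox = enh_vox,
    original_volume_ml = mask_volume_ml(seg),
    refined_volume_ml = mask_volume_ml(refined))
  rec$total_ml <- rec$gm_added_ml + rec$csf_removed_ml + rec$enh_removed_ml
  structure(rec, class = "correction_record")
}

#' @export
print.correction_record <- function(x, ...) {
  cat(sprintf(
    "<correction_record> total %.4f mL = GM added %.4f + CSF removed %.4f + enh removed %.4f\n",
    x$total_ml, x$gm_added_ml, x$csf_removed_ml, x$enh_removed_ml))
  cat(sprintf("  original %.4f mL -> refined %.4f mL\n",
              x$original_volume_ml, x$refined_volume_ml))
  invisible(x)
}

#' Refine one segmentation against a study context
#'
#' Runs gray-matter addition, then CSF removal, then enhancement removal on
#' the running segmentation; margins are recomputed from the fixed aggregate
#' shell against the current state at each subtraction step. Returns the
#' refined mask, the three delta masks and the correction bookkeeping. The
#' voxel-count conservation identity
#' `|refined| = |original| + |added| - |removed_csf| - |removed_enh|`
#' holds for every run.
#'
#' @param seg non-empty `binary_mask` candidate segmentation.
#' @param ctx a [refine_context()].
#' @return object of class `refinement` with fields `refined`, `added_gm`,
#'   `removed_csf`, `removed_enh`, `record`, `deltas_disjoint`.
#' @export
refine <- function(seg, ctx) {
  stopifnot(inherits(seg, "binary_mask"), inherits(ctx, "refine_context"))
  stopifnot_same_grid(seg, ctx$t1)
  g <- add_marginal_gm(seg, ctx$largest, ctx$gm, ctx$enhancing, ctx$t1,
                       dilation_connectivity = ctx$dilation_connectivity,
                       island_connectivity = ctx$island_connectivity)
  cur <- g$augmented
  cs <- remove_marginal_csf(cur, csf_margin(cur, ctx$shell), ctx$csf, ctx$t1,
                            island_connectivity = ctx$island_connectivity)
  cur <- cs$reduced
  en <- remove_marginal_enh(cur, csf_margin(cur, ctx$shell), ctx$rule, ctx$sub,
                            island_connectivity = ctx$island_connectivity)
  refined <- en$reduced
  refined$label <- paste0(seg$label, "-refined")
  disjoint <- !any(g$added$data & cs$removed$data) &&
    !any(g$added$data & en$removed$data) &&
    !any(cs$removed$data & en$removed$data)
  if (!disjoint)
    warning("correction delta masks are not pairwise disjoint", call. = FALSE)
  structure(list(
    refined = refined,
    added_gm = g$added,
    removed_csf = cs$removed,
    removed_enh = en$removed,
    record = new_correction_record(seg, g$added, cs$removed, en$removed, refined),
    deltas_disjoint = disjoint),
    class = "refinement")
}

#' @export
print.refinement <- function(x, ...) {
  cat("<refinement>\n")
  print(x$record)
  invisible(x)
}

#' @export
summary.refinement <- function(object, ...) {
  r <- object$record
  data.frame(original_ml = r$original_volume_ml,
             gm_added_ml = r$gm_added_ml,
             csf_removed_ml = r$csf_removed_ml,
             enh_removed_ml = r$enh_removed_ml,
             total_ml = r$total_ml,
             refined_ml = r$refined_volume_ml)
}
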