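#' NIfTI, CSV and JSON interfaces and the subject/cohort pipelines
#'
#' Volumes and masks are exchanged as NIfTI-1 (.nii/.nii.gz); masks are
#' written as uint8 with the source affine. Correction records are appended
#' to CSV with explicit column headers; intensity ranges and enhancement
#' rules are serialized to JSON sidecars.
#'
#' @name io
NULL

nifti_grid_id <- function(img) {
  paste0("nifti:", paste(dim(img), collapse = "x"),
         "@", paste(signif(RNifti::pixdim(img), 6), collapse = ","),
         ":", tryCatch(RNifti::orientation(img), error = function(e) "?"))
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume in ", path, " (got ",
         length(dim(img)), "D)", call. = FALSE)
  img
}

plain_array <- function(img) {
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  a
}

#' Read a NIfTI volume as an `intensity_volume`
#' @param path path to a .nii or .nii.gz file.
#' @export
read_intensity_volume <- function(path) {
  img <- read_nifti_array(path)
  intensity_volume(plain_array(img), spacing = RNifti::pixdim(img)[1:3],
                   grid_id = nifti_grid_id(img))
}

#' Read a NIfTI volume as a `binary_mask` (any nonzero voxel is foreground)
#' @param path path to a .nii or .nii.gz file.
#' @param label role tag for the mask.
#' @export
read_binary_mask <- function(path, label = "segmentation") {
  img <- read_nifti_array(path)
  binary_mask(plain_array(img) != 0, spacing = RNifti::pixdim(img)[1:3],
              grid_id = nifti_grid_id(img), label = label)
}

#' Read a NIfTI volume as a `probability_map`
#' @param path path to a .nii or .nii.gz file with values in \[0, 1\].
#' @export
read_probability_map <- function(path) {
  img <- read_nifti_array(path)
  probability_map(plain_array(img), spacing = RNifti::pixdim(img)[1:3],
                  grid_id = nifti_grid_id(img))
}

#' Write an `intensity_volume` or `probability_map` to NIfTI
#' @param vol the volume to write.
#' @param path destination path (.nii or .nii.gz).
#' @param datatype NIfTI storage type, default "float".
#' @export
write_volume <- function(vol, path, datatype = "float") {
  a <- vol$data
  attr(a, "pixdim") <- vol$spacing
  RNifti::writeNifti(RNifti::asNifti(a, datatype = datatype), path)
  invisible(path)
}

#' Write a `binary_mask` to NIfTI as uint8
#' @param mask the mask to write.
#' @param path destination path.
#' @export
write_mask <- function(mask, path) {
  a <- array(as.integer(mask$data), dim(mask$data))
  attr(a, "pixdim") <- mask$spacing
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "uint8"), path)
  invisible(path)
}

#' Serialize intensity references to a JSON sidecar
#' @param gm,csf `intensity_range` objects.
#' @param rule an `enhancement_rule`.
#' @param path destination .json path.
#' @export
write_ranges_json <- function(gm, csf, rule, path) {
  jsonlite::write_json(list(
    gm = unclass(gm), csf = unclass(csf), enhancement = unclass(rule)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

correction_row <- function(subject, side, algorithm, threshold, res) {
  r <- res$record
  data.frame(subject = subject, side = side, algorithm = algorithm,
             threshold = threshold,
             original_ml = r$original_volume_ml,
             gm_added_ml = r$gm_added_ml,
             csf_removed_ml = r$csf_removed_ml,
             enh_removed_ml = r$enh_removed_ml,
             total_ml = r$total_ml,
             refined_ml = r$refined_volume_ml,
             stringsAsFactors = FALSE)
}

#' Write a phantom subject to a directory of NIfTI files plus a JSON ledger
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_subject <- function(bundle, dir) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(bundle$t1_pre, file.path(dir, "t1_pre.nii.gz"))
  write_volume(bundle$t1_post, file.path(dir, "t1_post.nii.gz"))
  write_mask(bundle$csf_reference, file.path(dir, "csf_reference.nii.gz"))
  for (side in names(bundle$truth))
    write_mask(bundle$truth[[side]],
               file.path(dir, sprintf("truth_%s.nii.gz", side)))
  for (algo in names(bundle$candidates)) {
    for (side in names(bundle$candidates[[algo]])) {
      cand <- bundle$candidates[[algo]][[side]]
      write_mask(cand$mask, file.path(dir, sprintf("%s_%s.nii.gz", algo, side)))
      if (!is.null(cand$prob))
        write_volume(cand$prob,
                     file.path(dir, sprintf("%s_%s_prob.nii.gz", algo, side)))
    }
  }
  jsonlite::write_json(bundle$ledger, file.path(dir, "ledger.json"),
                       dataframe = "rows", digits = NA)
  utils::write.csv(bundle$ledger, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Refine every candidate segmentation of one subject
#'
#' The single-subject pipeline behind the command-line `refine` command:
#' builds the subtraction image, derives per-study references (gray matter
#' from the right-side consensus, CSF from the ventricular reference), builds
#' per-side aggregates, refines every binary candidate and sweeps every
#' probability-map candidate, and (optionally) writes all outputs.
#'
#' @param t1_pre,t1_post precontrast/postcontrast `intensity_volume`s.
#' @param candidates nested list: `candidates[[algorithm]][[side]]` is a list
#'   with a `mask` (`binary_mask`) and optionally `prob`
#'   (`probability_map`); sides are "right" and/or "left". A
#'   `phantom_bundle$candidates` slots in directly.
#' @param csf_reference `binary_mask` CSF reference (e.g. right lateral
#'   ventricle).
#' @param subject subject identifier for the output table.
#' @param thresholds threshold grid for probability-map candidates.
#' @param out_dir if non-NULL, write subtraction image, ranges JSON, delta and
#'   refined masks, and the corrections CSV here.
#' @param k_gm,k_csf,k_enh SD multipliers passed to [refine_context()].
#' @return list: `table` (one row per candidate x side x threshold),
#'   `contexts` (per side), `results` (refinements), `sweeps`.
#' @export
run_refine_subject <- function(t1_pre, t1_post, candidates, csf_reference,
                               subject = "subject", thresholds = seq(0, 1, 0.1),
                               out_dir = NULL, k_gm = 1, k_csf = 1, k_enh = 1) {
  sub <- compute_subtraction(t1_pre, t1_post)
  sides <- unique(unlist(lapply(candidates, names)))
  sides <- intersect(c("right", "left"), sides)
  side_masks <- function(side) {
    out <- list()
    for (algo in names(candidates)) {
      cand <- candidates[[algo]][[side]]
      if (is.null(cand)) next
      if (!is.null(cand$prob)) {
        for (t in thresholds) {
          m <- threshold_map(cand$prob, t)
          if (any(m$data)) out[[length(out) + 1L]] <- m
        }
      } else out[[length(out) + 1L]] <- cand$mask
    }
    out
  }
  # references come from the right side when present, and are shared
  ref_side <- if ("right" %in% sides) "right" else sides[[1]]
  contexts <- list()
  contexts[[ref_side]] <- refine_context(side_masks(ref_side), t1_pre, sub,
                                         csf_reference, k_gm = k_gm,
                                         k_csf = k_csf, k_enh = k_enh)
  for (side in setdiff(sides, ref_side))
    contexts[[side]] <- refine_context(side_masks(side), t1_pre, sub,
                                       csf_reference, k_gm = k_gm,
                                       k_csf = k_csf, k_enh = k_enh,
                                       gm = contexts[[ref_side]]$gm,
                                       csf = contexts[[ref_side]]$csf)
  rows <- list(); results <- list(); sweeps <- list()
  for (algo in names(candidates)) {
    for (side in sides) {
      cand <- candidates[[algo]][[side]]
      if (is.null(cand)) next
      key <- paste(algo, side, sep = ".")
      if (!is.null(cand$prob)) {
        sw <- sweep_thresholds(cand$prob, contexts[[side]], thresholds)
        sweeps[[key]] <- sw
        for (i in seq_len(nrow(sw$table))) {
          if (sw$table$skipped[i]) next
          rows[[length(rows) + 1L]] <-
            correction_row(subject, side, algo, sw$table$threshold[i],
                           sw$results[[i]])
        }
      } else {
        res <- refine(cand$mask, contexts[[side]])
        results[[key]] <- res
        rows[[length(rows) + 1L]] <-
          correction_row(subject, side, algo, NA_real_, res)
      }
    }
  }
  table <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(sub, file.path(out_dir, "subtraction.nii.gz"))
    ctx0 <- contexts[[ref_side]]
    write_ranges_json(ctx0$gm, ctx0$csf, ctx0$rule,
                      file.path(out_dir, "ranges.json"))
    for (key in names(results)) {
      res <- results[[key]]
      write_mask(res$refined, file.path(out_dir, paste0(key, "_refined.nii.gz")))
      for (kind in c("added_gm", "removed_csf", "removed_enh"))
        write_mask(res[[kind]],
                   file.path(out_dir, paste0(key, "_", kind, ".nii.gz")))
    }
    utils::write.csv(table, file.path(out_dir, "corrections.csv"),
                     row.names = FALSE)
  }
  list(table = table, contexts = contexts, results = results, sweeps = sweeps)
}

#' Generate and refine a phantom cohort
#'
#' Streams through per-subject phantom specs (see [phantom_cohort()]):
#' generates each subject, refines every candidate on both sides, and
#' accumulates the long-format cohort table and the injected-error ledger.
#' Subjects whose generation or refinement fails are skipped with a warning
#' and listed in the failure manifest.
#'
#' @param specs list of `phantom_spec` (one per subject).
#' @param thresholds threshold grid for probability-map candidates.
#' @param ... passed to [run_refine_subject()].
#' @return list: `table` (cohort corrections), `ledger` (per-subject injected
#'   volumes), `failures` (character vector of failed subject ids).
#' @export
run_cohort <- function(specs, thresholds = seq(0, 1, 0.1), ...) {
  tables <- list(); ledgers <- list(); failures <- character(0)
  for (i in seq_along(specs)) {
    sid <- sprintf("S%03d", i)
    res <- tryCatch({
      bundle <- phantom_generate(specs[[i]])
      out <- run_refine_subject(bundle$t1_pre, bundle$t1_post,
                                bundle$candidates, bundle$csf_reference,
                                subject = sid, thresholds = thresholds, ...)
      led <- bundle$ledger
      led$subject <- sid
      list(table = out$table, ledger = led)
    }, error = function(e) {
      warning(sprintf("subject %s failed and was skipped: %s", sid,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) { failures <- c(failures, sid); next }
    tables[[sid]] <- res$table
    ledgers[[sid]] <- res$ledger
  }
  if (length(tables) == 0L) stop("every subject failed", call. = FALSE)
  list(table = do.call(rbind, c(tables, list(make.row.names = FALSE))),
       ledger = do.call(rbind, c(ledgers, list(make.row.names = FALSE))),
       failures = failures)
}
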