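#' Synthetic MRI phantom with known injected segmentation errors
#'
#' Generates paired pre/postcontrast T1 volumes, a ventricular CSF reference
#' mask and candidate hippocampal segmentations whose errors are known
#' voxel-for-voxel, so every pipeline stage can be validated without real MRI.
#'
#' The anatomy is coarse but topologically faithful to the tissue model the
#' method relies on: each hippocampus is a gray-matter ellipsoid containing an
#' interposed white-matter sheet, a few enhancing vessel voxels and a few
#' CSF-intensity cyst voxels (all of which legitimately belong to the label);
#' a CSF compartment caps its superior surface; an avidly enhancing choroid
#' plexus-like blob abuts the superior margin; and a separate box-shaped
#' lateral ventricle (with a partial-volume rim and an intraventricular
#' enhancing blob, as real ventricle labels have) serves as the CSF reference.
#'
#' Candidate segmentations realize requested error injections as whole voxels:
#' a gray-matter erosion (boundary voxels removed), a CSF rim (grown into the
#' CSF cap) and an enhancing blob (grown into the plexus). Injection sites are
#' disjoint across candidates so that every injected voxel lies in the
#' aggregate disagreement shell.
#'
#' @name phantom
NULL

ellipsoid <- function(dims, center, semiaxes) {
  x <- (seq_len(dims[1]) - center[1]) / semiaxes[1]
  y <- (seq_len(dims[2]) - center[2]) / semiaxes[2]
  z <- (seq_len(dims[3]) - center[3]) / semiaxes[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

box_mask <- function(dims, ranges) {
  a <- array(FALSE, dims)
  a[ranges[1, 1]:ranges[1, 2], ranges[2, 1]:ranges[2, 2],
    ranges[3, 1]:ranges[3, 2]] <- TRUE
  a
}

dilate_raw <- function(a, connectivity = 6) {
  offs <- conn_offsets(connectivity)
  acc <- a
  for (r in seq_len(nrow(offs))) acc <- acc | shift_array(a, offs[r, ])
  acc
}

# face-adjacency BFS growth of up to n voxels from `seeds` within `allowed`;
# deterministic (linear-index order within each ring)
grow_region <- function(allowed, seeds, n) {
  dims <- dim(allowed)
  sel <- array(FALSE, dims)
  if (n <= 0) return(sel)
  frontier <- which(seeds & allowed)
  taken <- 0L
  while (taken < n && length(frontier)) {
    take <- frontier[seq_len(min(n - taken, length(frontier)))]
    sel[take] <- TRUE
    taken <- taken + length(take)
    if (taken >= n) break
    frontier <- which(dilate_raw(sel) & allowed & !sel)
  }
  sel
}

ml_to_vox <- function(ml, spacing) as.integer(round(ml * 1000 / prod(spacing)))

# partition `region` into per-candidate y-stripes sized in proportion to the
# requested injection volumes, each holding a share of the seed ring (region
# voxels face-adjacent to the anatomy), so that every candidate's injection
# grows from its own seeds and sites stay disjoint by construction
y_stripes <- function(region, ring, weights, dims) {
  k <- length(weights)
  y_coord <- array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
                   dims)
  ys <- y_coord[ring & region]
  if (length(ys) == 0L) return(rep(list(region), k))
  w <- if (sum(weights) > 0) weights / sum(weights) else rep(1 / k, k)
  br <- stats::quantile(ys, probs = cumsum(c(0, w)), type = 1, names = FALSE)
  br[1] <- -Inf; br[length(br)] <- Inf
  lapply(seq_len(k), function(j) {
    if (w[j] == 0) return(region & FALSE)
    region & y_coord > br[j] & y_coord <= br[j + 1]
  })
}

#' Specify a synthetic phantom subject
#'
#' Defaults define the reference study conditions: 1 mm isotropic grid,
#' well-separated intensity bands (GM 100+/-5, WM 140+/-5, CSF 10+/-3,
#' arbitrary units), +300 postcontrast boost on enhancing voxels, additive
#' Gaussian noise of SD 5 (5% of the GM mean), and two mock candidate
#' algorithms with graded injected errors.
#'
#' @param grid_shape voxel dimensions, default c(64, 64, 44).
#' @param spacing voxel edge lengths in mm, default 1 mm isotropic.
#' @param gm_mean,gm_sd,wm_mean,wm_sd,csf_mean,csf_sd tissue intensity bands.
#' @param plexus_mean precontrast intensity of choroid plexus (isointense-ish,
#'   below the gray-matter band).
#' @param pv_mean intensity of the ventricle's partial-volume rim (between CSF
#'   and white matter).
#' @param enh_boost additive postcontrast intensity on enhancing voxels.
#' @param noise_sd additive Gaussian noise SD (applied to pre and post
#'   independently).
#' @param noise_free convenience switch: zero all SDs (tissue and noise) so
#'   intensity classification is exact.
#' @param hippo_center_right,hippo_center_left,hippo_semiaxes ellipsoid
#'   geometry per side (voxel units, 1-based indices).
#' @param csf_cap_scale the superior CSF compartment is the upper half of the
#'   hippocampus ellipsoid scaled by this factor, minus the hippocampus.
#' @param plexus_offset,plexus_semiaxes enhancing plexus blob geometry
#'   relative to each hippocampus center.
#' @param ventricle_box 3x2 matrix of index ranges for the CSF reference box.
#' @param vessel_voxels,cyst_voxels number of interior enhancing-vessel /
#'   CSF-cyst voxels per hippocampus.
#' @param errors named list of per-candidate injections, each a numeric
#'   vector with entries gm_erosion_ml, csf_rim_ml, enh_blob_ml (applied per
#'   side).
#' @param prob_algorithms names of `errors` entries for which a graded
#'   probability-map variant is also generated (truth voxels get p >= 0.6,
#'   injected-error voxels p <= 0.4, so the optimal threshold is known to lie
#'   in between).
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 44L),
                         spacing = c(1, 1, 1),
                         gm_mean = 100, gm_sd = 5,
                         wm_mean = 140, wm_sd = 5,
                         csf_mean = 10, csf_sd = 3,
                         plexus_mean = 80, pv_mean = 75,
                         enh_boost = 300,
                         noise_sd = 5,
                         noise_free = FALSE,
                         hippo_center_right = c(20, 32, 18),
                         hippo_center_left = c(44, 32, 18),
                         hippo_semiaxes = c(8, 14, 7),
                         csf_cap_scale = 1.3,
                         plexus_offset = c(0, 8, 5),
                         plexus_semiaxes = c(6, 12, 6),
                         ventricle_box = rbind(c(8, 20), c(6, 17), c(28, 40)),
                         vessel_voxels = 12L, cyst_voxels = 10L,
                         errors = list(
                           mockA = c(gm_erosion_ml = 0.1, csf_rim_ml = 0.2,
                                     enh_blob_ml = 0.3),
                           mockB = c(gm_erosion_ml = 0.05, csf_rim_ml = 0.08,
                                     enh_blob_ml = 0.12)),
                         prob_algorithms = character(0),
                         seed = 1L) {
  if (noise_free) gm_sd <- wm_sd <- csf_sd <- noise_sd <- 0
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  dims <- spec$grid_shape
  inside <- function(center, semiaxes) {
    all(center - semiaxes >= 1) && all(center + semiaxes <= dims)
  }
  cap_axes <- spec$hippo_semiaxes * spec$csf_cap_scale
  for (ctr in list(spec$hippo_center_right, spec$hippo_center_left)) {
    if (!inside(ctr, cap_axes) ||
        !inside(ctr + spec$plexus_offset, spec$plexus_semiaxes))
      stop("phantom geometry exceeds the grid", call. = FALSE)
  }
  vb <- spec$ventricle_box
  if (any(vb[, 1] < 1) || any(vb[, 2] > dims) || any(vb[, 1] >= vb[, 2]))
    stop("ventricle box exceeds the grid", call. = FALSE)
  if (abs(spec$gm_mean - spec$wm_mean) < 2 * (spec$gm_sd + spec$wm_sd + spec$noise_sd) ||
      abs(spec$gm_mean - spec$csf_mean) < 2 * (spec$gm_sd + spec$csf_sd + spec$noise_sd))
    stop("tissue intensity bands are not well separated for this noise level",
         call. = FALSE)
  if (length(spec$errors) < 2L)
    stop("need at least two candidate algorithms (aggregates require >= 2 masks)",
         call. = FALSE)
  invisible(TRUE)
}

# per-side static geometry
phantom_side_geometry <- function(spec, center) {
  dims <- spec$grid_shape
  truth <- ellipsoid(dims, center, spec$hippo_semiaxes)
  boundary <- truth & dilate_raw(!truth)          # inner 6-boundary
  interior <- truth & !boundary
  # erosion pool: boundary voxels face-adjacent to the interior, so every
  # eroded voxel is recoverable by a single dilation of the remaining label
  ero_pool <- boundary & dilate_raw(interior)
  zsup <- array(rep(seq_len(dims[3]) > center[3], each = dims[1] * dims[2]), dims)
  cap <- ellipsoid(dims, center, spec$hippo_semiaxes * spec$csf_cap_scale) &
    !truth & zsup
  plexus <- ellipsoid(dims, center + spec$plexus_offset, spec$plexus_semiaxes) &
    !truth
  # interior structures that legitimately belong to the label
  ix <- seq_len(dims[1])
  sheet <- array(FALSE, dims)
  sheet[, center[2], ] <- TRUE
  sheet <- sheet & interior
  zslab <- function(z) {
    a <- array(FALSE, dims); a[, , z] <- TRUE; a
  }
  line1 <- interior & !sheet & zslab(center[3]) &
    array(rep(ix == center[1], times = dims[2] * dims[3]), dims)
  vessels <- array(FALSE, dims)
  vessels[utils::head(which(line1), spec$vessel_voxels)] <- TRUE
  line2 <- interior & !sheet & !vessels & zslab(center[3] - 2) &
    array(rep(ix == center[1] + 1, times = dims[2] * dims[3]), dims)
  cysts <- array(FALSE, dims)
  cysts[utils::head(which(line2), spec$cyst_voxels)] <- TRUE
  wm <- sheet & !vessels & !cysts
  list(truth = truth, interior = interior, ero_pool = ero_pool,
       cap = cap & !plexus, plexus = plexus,
       wm = wm, vessels = vessels, cysts = cysts)
}

#' Generate a phantom subject
#'
#' Deterministic for a fixed spec (the spec's seed drives all randomness).
#' Injections are realized as whole voxels; when a requested volume cannot be
#' fully realized (region capacity), the realized volume is recorded in the
#' ledger.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_bundle` with fields `t1_pre`, `t1_post`,
#'   `truth` (per side), `csf_reference`, `enhancing_truth`, `vessels`,
#'   `cysts`, `candidates` (per algorithm, per side: mask, injection masks,
#'   optional probability map) and `ledger` (data frame of requested and
#'   realized injected volumes).
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dims <- spec$grid_shape
  grid_id <- paste0("phantom:", paste(dims, collapse = "x"))
  sides <- list(right = phantom_side_geometry(spec, spec$hippo_center_right),
                left  = phantom_side_geometry(spec, spec$hippo_center_left))

  vb <- spec$ventricle_box
  vent <- box_mask(dims, vb)
  # partial-volume rim along the superior wall, as whole-brain-segmentation
  # ventricle labels have where CSF borders white matter
  vent_rim <- array(FALSE, dims)
  vent_rim[vb[1, 1]:vb[1, 2], vb[2, 1]:vb[2, 2], vb[3, 2]] <- TRUE
  vent_core <- vent & !vent_rim
  vp <- rbind(c(vb[1, 1] + 3, vb[1, 1] + 5),
              c(vb[2, 1] + 3, vb[2, 1] + 6),
              c(vb[3, 1] + 3, vb[3, 1] + 5))
  vent_plexus <- box_mask(dims, vp)                # intraventricular plexus

  enh <- sides$right$plexus | sides$left$plexus |
    sides$right$vessels | sides$left$vessels | vent_plexus

  # precontrast intensities: air 0 elsewhere
  pre <- array(0, dims)
  paint <- function(vol, where, mean, sd) {
    n <- sum(where)
    if (n) vol[where] <- mean + (if (sd > 0) stats::rnorm(n, 0, sd) else 0)
    vol
  }
  for (s in sides) {
    pre <- paint(pre, s$cap, spec$csf_mean, spec$csf_sd)
    pre <- paint(pre, s$truth, spec$gm_mean, spec$gm_sd)
    pre <- paint(pre, s$wm, spec$wm_mean, spec$wm_sd)
    pre <- paint(pre, s$cysts, spec$csf_mean, spec$csf_sd)
    pre <- paint(pre, s$plexus, spec$plexus_mean, spec$gm_sd)
  }
  pre <- paint(pre, vent_core, spec$csf_mean, spec$csf_sd)
  pre <- paint(pre, vent_rim, spec$pv_mean, spec$csf_sd)
  pre <- paint(pre, vent_plexus, spec$plexus_mean, spec$gm_sd)
  if (spec$noise_sd > 0)
    pre <- pre + stats::rnorm(length(pre), 0, spec$noise_sd)
  post <- pre + spec$enh_boost * enh
  if (spec$noise_sd > 0)
    post <- post + stats::rnorm(length(post), 0, spec$noise_sd)

  mk_vol <- function(a) intensity_volume(a, spacing = spec$spacing,
                                         grid_id = grid_id)
  mk_msk <- function(a, label) binary_mask(a, spacing = spec$spacing,
                                           grid_id = grid_id, label = label)
  vox_ml <- prod(spec$spacing) / 1000

  candidates <- list()
  ledger <- list()
  algos <- names(spec$errors)
  for (side_name in names(sides)) {
    s <- sides[[side_name]]
    used_ero <- array(FALSE, dims)
    truth_adj <- dilate_raw(s$truth)
    w_rim <- vapply(spec$errors, function(e) e[["csf_rim_ml"]], numeric(1))
    w_blob <- vapply(spec$errors, function(e) e[["enh_blob_ml"]], numeric(1))
    cap_stripes <- y_stripes(s$cap, truth_adj, w_rim, dims)
    plexus_stripes <- y_stripes(s$plexus, truth_adj, w_blob, dims)
    for (j in seq_along(algos)) {
      algo <- algos[j]
      e <- spec$errors[[algo]]
      n_ero <- ml_to_vox(e[["gm_erosion_ml"]], spec$spacing)
      n_rim <- ml_to_vox(e[["csf_rim_ml"]], spec$spacing)
      n_blob <- ml_to_vox(e[["enh_blob_ml"]], spec$spacing)
      ero <- array(FALSE, dims)
      pool <- which(s$ero_pool & !used_ero)
      ero[utils::head(pool, n_ero)] <- TRUE
      used_ero <- used_ero | ero
      rim <- grow_region(cap_stripes[[j]], truth_adj, n_rim)
      blob <- grow_region(plexus_stripes[[j]], truth_adj, n_blob)
      cand <- (s$truth & !ero) | rim | blob
      candidates[[algo]][[side_name]] <- list(
        mask = mk_msk(cand, paste0(algo, "-", side_name)),
        injections = list(gm_erosion = mk_msk(ero, "gm_erosion"),
                          csf_rim = mk_msk(rim, "csf_rim"),
                          enh_blob = mk_msk(blob, "enh_blob")))
      if (algo %in% spec$prob_algorithms) {
        p <- array(0, dims)
        outer_layer <- s$truth & !s$interior
        p[s$interior] <- 0.95
        p[outer_layer] <- 0.65
        rim1 <- rim & truth_adj; blob1 <- blob & truth_adj
        p[rim] <- 0.15; p[rim1] <- 0.35
        p[blob] <- 0.12; p[blob1] <- 0.25
        candidates[[algo]][[side_name]]$prob <-
          probability_map(p, spacing = spec$spacing, grid_id = grid_id)
      }
      for (comp in c("gm_erosion", "csf_rim", "enh_blob")) {
        realized <- switch(comp, gm_erosion = sum(ero), csf_rim = sum(rim),
                           enh_blob = sum(blob))
        ledger[[length(ledger) + 1L]] <- data.frame(
          algorithm = algo, side = side_name, component = comp,
          requested_ml = unname(e[[paste0(comp, "_ml")]]),
          realized_vox = realized, realized_ml = realized * vox_ml)
      }
    }
  }

  structure(list(
    spec = spec,
    t1_pre = mk_vol(pre), t1_post = mk_vol(post),
    truth = list(right = mk_msk(sides$right$truth, "truth-right"),
                 left = mk_msk(sides$left$truth, "truth-left")),
    csf_reference = mk_msk(vent, "csf_reference"),
    enhancing_truth = mk_msk(enh, "enhancing-truth"),
    vessels = list(right = mk_msk(sides$right$vessels, "vessels"),
                   left = mk_msk(sides$left$vessels, "vessels")),
    cysts = list(right = mk_msk(sides$right$cysts, "cysts"),
                 left = mk_msk(sides$left$cysts, "cysts")),
    candidates = candidates,
    ledger = do.call(rbind, ledger)),
    class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> grid %s, %d candidate algorithm(s) x 2 sides\n",
              paste(dim(x$t1_pre$data), collapse = "x"),
              length(x$candidates)))
  print(x$ledger)
  invisible(x)
}

#' Specify a phantom cohort
#'
#' Produces one [phantom_spec()] per subject from a template: hippocampus
#' centers are jittered by up to 2 voxels and semi-axes by up to 1 voxel, and
#' per-algorithm injected error volumes are drawn from Gaussian profiles
#' (SD = 20% of the profile mean, truncated at 0). Specs are lightweight;
#' generate subjects one at a time with [phantom_generate()] (as
#' [run_cohort()] does) rather than materializing all volumes at once.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param profiles named list: algorithm -> c(gm_erosion_ml, csf_rim_ml,
#'   enh_blob_ml) mean injected volumes. Defaults to three mock algorithms
#'   with graded mean total errors of about 0.3, 0.6 and 1.0 mL.
#' @param template a [phantom_spec()] used for everything else.
#' @param seed cohort seed; each subject gets a derived seed.
#' @return list of `phantom_spec`, one per subject.
#' @export
phantom_cohort <- function(n_subjects,
                           profiles = list(
                             mockA = c(gm_erosion_ml = 0.10, csf_rim_ml = 0.12,
                                       enh_blob_ml = 0.08),
                             mockB = c(gm_erosion_ml = 0.15, csf_rim_ml = 0.30,
                                       enh_blob_ml = 0.15),
                             mockC = c(gm_erosion_ml = 0.25, csf_rim_ml = 0.45,
                                       enh_blob_ml = 0.30)),
                           template = phantom_spec(),
                           seed = 1L) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    sp <- template
    jit <- function(v, amount) v + sample(seq(-amount, amount), length(v),
                                          replace = TRUE)
    sp$hippo_center_right <- jit(sp$hippo_center_right, 2)
    sp$hippo_center_left <- jit(sp$hippo_center_left, 2)
    sp$hippo_semiaxes <- pmax(sp$hippo_semiaxes + sample(-1:1, 3, replace = TRUE),
                              3)
    sp$errors <- lapply(profiles, function(p) {
      drawn <- pmax(p + stats::rnorm(length(p), 0, 0.2 * p), 0)
      names(drawn) <- names(p)
      drawn
    })
    sp$seed <- seed + i
    validate_phantom_spec(sp)
    sp
  })
}
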