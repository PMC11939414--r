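#' 3D binary-mask morphology and set algebra
#'
#' The refinement procedure is built from a handful of mask primitives:
#' thresholding of probability maps, voxelwise set algebra across candidate
#' segmentations (the aggregate smallest/largest segmentations and the
#' disagreement shell), single-iteration dilation, and connected-component
#' island removal.
#'
#' @name morphology
NULL

# neighbourhood offsets for a given connectivity (6 = faces, 18 = +edges,
# 26 = +corners)
conn_offsets <- function(connectivity = 6) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  s <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s <= 2, "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

# shift a 3D array by integer offset d, zero/FALSE fill
shift_array <- function(a, d) {
  dims <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, dims)
  idx_dst <- idx_src <- vector("list", 3L)
  for (i in 1:3) {
    if (abs(d[i]) >= dims[i]) return(out)
    if (d[i] >= 0) {
      idx_dst[[i]] <- (1L + d[i]):dims[i]
      idx_src[[i]] <- 1L:(dims[i] - d[i])
    } else {
      idx_dst[[i]] <- 1L:(dims[i] + d[i])
      idx_src[[i]] <- (1L - d[i]):dims[i]
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Threshold a probability map into a binary mask
#'
#' A voxel is foreground iff its probability is strictly greater than `t`, so
#' `t = 1` always yields an empty mask (a probability map thresholded at its
#' own maximum carries no segmentation) and the result can only shrink as `t`
#' grows.
#'
#' @param p a `probability_map`.
#' @param t threshold in \[0, 1\].
#' @param label label for the resulting mask.
#' @return a `binary_mask` on the same grid.
#' @export
threshold_map <- function(p, t, label = sprintf("seg>%g", t)) {
  stopifnot(inherits(p, "probability_map"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("threshold `t` must be a single value in [0, 1]", call. = FALSE)
  mask_like(p, p$data > t, label = label)
}

check_mask_list <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("need a list of at least 2 masks", call. = FALSE)
  lapply(masks, function(m) stopifnot(inherits(m, "binary_mask")))
  for (m in masks[-1]) stopifnot_same_grid(masks[[1]], m)
  invisible(TRUE)
}

#' Aggregate smallest segmentation: voxelwise intersection
#'
#' Voxels shared by all candidate segmentations — the consensus core used as
#' the gray-matter intensity reference.
#'
#' @param masks list of >= 2 `binary_mask` objects on one grid.
#' @export
mask_intersection <- function(masks) {
  check_mask_list(masks)
  acc <- masks[[1]]$data
  for (m in masks[-1]) acc <- acc & m$data
  mask_like(masks[[1]], acc, label = "intersection")
}

#' Aggregate largest segmentation: voxelwise union
#'
#' Voxels present in any candidate segmentation — the maximal envelope that
#' constrains gray-matter addition.
#'
#' @inheritParams mask_intersection
#' @export
mask_union <- function(masks) {
  check_mask_list(masks)
  acc <- masks[[1]]$data
  for (m in masks[-1]) acc <- acc | m$data
  mask_like(masks[[1]], acc, label = "union")
}

#' Aggregate disagreement shell: union minus intersection
#'
#' Voxels claimed by some but not all candidates; marginal corrections are
#' restricted to this zone, which is what preserves interior enhancing vessels
#' and cysts that every algorithm agrees belong to the hippocampus.
#'
#' @inheritParams mask_intersection
#' @export
aggregate_shell <- function(masks) {
  check_mask_list(masks)
  u <- mask_union(masks)
  i <- mask_intersection(masks)
  mask_like(u, u$data & !i$data, label = "shell")
}

#' Dilate a mask by exactly one iteration
#'
#' Adds every background voxel adjacent to the mask under the given
#' structuring element (default: 6-connectivity, face neighbours), clipped to
#' the grid.
#'
#' @param m a `binary_mask`.
#' @param connectivity 6 (default), 18 or 26.
#' @export
dilate_once <- function(m, connectivity = 6) {
  stopifnot(inherits(m, "binary_mask"))
  if (!any(m$data)) {
    warning("dilating an empty mask; returning an empty mask", call. = FALSE)
    return(mask_like(m, m$data, label = m$label))
  }
  offs <- conn_offsets(connectivity)
  acc <- m$data
  for (r in seq_len(nrow(offs))) acc <- acc | shift_array(m$data, offs[r, ])
  mask_like(m, acc, label = paste0(m$label, "+dilated"))
}

# linear indices of foreground, and component membership via an adjacency
# graph over foreground voxels (igraph handles the labelling)
component_membership <- function(data, connectivity = 26) {
  idx <- which(data)
  n <- length(idx)
  if (n == 0L) return(list(idx = integer(0), membership = integer(0)))
  dims <- dim(data)
  rank <- array(0L, dims)
  rank[idx] <- seq_len(n)
  offs <- conn_offsets(connectivity)
  # half the offsets suffice: each undirected adjacency seen once
  offs <- offs[offs[, 1] * 9 + offs[, 2] * 3 + offs[, 3] > 0, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    sh <- shift_array(rank, offs[r, ])
    both <- which(data & sh > 0L)
    if (length(both)) {
      from <- c(from, rank[both])
      to <- c(to, sh[both])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  list(idx = idx, membership = memb)
}

#' Connected components of a mask
#'
#' Components are maximal under the given connectivity (default 26, so
#' diagonal touching counts) and returned sorted by voxel count descending,
#' ties broken by the smaller first linear (column-major) voxel index.
#'
#' @param m a `binary_mask`.
#' @param connectivity 6, 18 or 26 (default).
#' @return list of `binary_mask`, possibly empty.
#' @export
connected_components <- function(m, connectivity = 26) {
  stopifnot(inherits(m, "binary_mask"))
  cm <- component_membership(m$data, connectivity)
  if (length(cm$idx) == 0L) return(list())
  comp_ids <- sort(unique(cm$membership))
  sizes <- tabulate(cm$membership, nbins = max(cm$membership))[comp_ids]
  # idx is ascending, so the first occurrence of each id is its smallest index
  first_idx <- cm$idx[match(comp_ids, cm$membership)]
  ord <- order(-sizes, first_idx)
  lapply(comp_ids[ord], function(cid) {
    d <- array(FALSE, dim(m$data))
    d[cm$idx[cm$membership == cid]] <- TRUE
    mask_like(m, d, label = paste0(m$label, "-component"))
  })
}

#' Remove islands from a mask
#'
#' With an `anchor`, keeps every component that intersects the anchor (used
#' after gray-matter addition, where added voxels must stay connected to the
#' original segmentation). Without an anchor, keeps only the largest component
#' (used after CSF/enhancement subtraction).
#'
#' @param m a `binary_mask`.
#' @param anchor optional `binary_mask` on the same grid.
#' @param connectivity island connectivity, default 26.
#' @return a `binary_mask`, subset of `m`.
#' @export
remove_islands <- function(m, anchor = NULL, connectivity = 26) {
  stopifnot(inherits(m, "binary_mask"))
  if (!is.null(anchor)) {
    stopifnot(inherits(anchor, "binary_mask"))
    stopifnot_same_grid(m, anchor)
  }
  comps <- connected_components(m, connectivity)
  if (length(comps) == 0L) return(mask_like(m, m$data, label = m$label))
  keep <- array(FALSE, dim(m$data))
  if (is.null(anchor)) {
    keep <- comps[[1]]$data   # largest (tie: smallest first index)
  } else {
    hit <- FALSE
    for (cc in comps) {
      if (any(cc$data & anchor$data)) {
        keep <- keep | cc$data
        hit <- TRUE
      }
    }
    if (!hit)
      warning("anchor intersects no component; returning an empty mask",
              call. = FALSE)
  }
  mask_like(m, keep, label = m$label)
}
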