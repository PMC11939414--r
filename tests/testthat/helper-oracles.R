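# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the package internals: dilation scans every
# voxel's neighbourhood, components use an explicit-stack flood fill.

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  s <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[s == 1, , drop = FALSE],
         "18" = g[s <= 2, , drop = FALSE],
         "26" = g)
}

oracle_dilate <- function(a, connectivity = 6) {
  dims <- dim(a)
  offs <- neighbour_offsets(connectivity)
  out <- a
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (a[i, j, k]) next
      for (r in seq_len(nrow(offs))) {
        ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
        if (ii >= 1 && ii <= dims[1] && jj >= 1 && jj <= dims[2] &&
            kk >= 1 && kk <= dims[3] && a[ii, jj, kk]) {
          out[i, j, k] <- TRUE
          break
        }
      }
    }
  out
}

# flood fill with an explicit stack; returns an integer label array
oracle_label <- function(a, connectivity = 26) {
  dims <- dim(a)
  offs <- neighbour_offsets(connectivity)
  lab <- array(0L, dims)
  nextlab <- 0L
  for (start in which(a)) {
    if (lab[start] > 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    lab[start] <- nextlab
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      ijk <- arrayInd(v, dims)
      for (r in seq_len(nrow(offs))) {
        p <- ijk + offs[r, ]
        if (any(p < 1) || any(p > dims)) next
        w <- p[1] + (p[2] - 1L) * dims[1] + (p[3] - 1L) * dims[1] * dims[2]
        if (a[w] && lab[w] == 0L) {
          lab[w] <- nextlab
          stack <- c(stack, w)
        }
      }
    }
  }
  lab
}

random_mask <- function(dims = c(8, 8, 8), p = 0.25) {
  binary_mask(array(runif(prod(dims)) < p, dims))
}

# mask on a 1x1xn line grid with foreground at `idx`
line_mask <- function(n, idx, spacing = c(1, 1, 1)) {
  a <- array(FALSE, c(1, 1, n)); a[1, 1, idx] <- TRUE
  binary_mask(a, spacing = spacing)
}

line_vol <- function(values, spacing = c(1, 1, 1)) {
  intensity_volume(array(values, c(1, 1, length(values))), spacing = spacing)
}

pop_sd_oracle <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# small-grid phantom spec used throughout the refinement/assessment tests;
# geometry scaled down so a full generate+refine cycle stays fast
small_spec <- function(...,
                       errors = list(
                         mockA = c(gm_erosion_ml = 0.05, csf_rim_ml = 0.08,
                                   enh_blob_ml = 0.1),
                         mockB = c(gm_erosion_ml = 0.03, csf_rim_ml = 0.04,
                                   enh_blob_ml = 0.05))) {
  phantom_spec(grid_shape = c(40L, 40L, 32L),
               hippo_center_right = c(12, 20, 14),
               hippo_center_left = c(28, 20, 14),
               hippo_semiaxes = c(5, 9, 5),
               plexus_offset = c(0, 5, 4),
               plexus_semiaxes = c(4, 8, 4),
               ventricle_box = rbind(c(4, 14), c(4, 13), c(22, 30)),
               vessel_voxels = 6L, cyst_voxels = 5L,
               errors = errors,
               ...)
}

expect_conservation <- function(res, seg) {
  r <- res$record
  expect_identical(voxel_count(res$refined),
                   voxel_count(seg) + r$gm_added_vox - r$csf_removed_vox -
                     r$enh_removed_vox)
  expect_equal(r$total_ml,
               r$gm_added_ml + r$csf_removed_ml + r$enh_removed_ml)
}
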