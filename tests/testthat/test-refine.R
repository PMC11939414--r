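# A hand-built micro-scene on a line grid plus full phantom subjects exercise
# the three marginal correction steps and their bookkeeping.

test_that("csf margin is the overlap of shell and segmentation", {
  seg <- line_mask(5, 2:4)
  shell <- line_mask(5, 1:3)
  expect_equal(which(csf_margin(seg, shell)$data), 2:3)
  expect_equal(voxel_count(csf_margin(seg, line_mask(5, 5))), 0L)
  expect_equal(voxel_count(csf_margin(line_mask(5, integer(0)), shell)), 0L)
})

test_that("marginal gray-matter addition recovers an eroded rim and only that", {
  # 7x7x3 slab of GM at 100 surrounded by air; candidate eroded at the x edges
  dims <- c(9, 9, 5)
  t1a <- array(0, dims); slab <- array(FALSE, dims)
  slab[3:7, 3:7, 2:4] <- TRUE
  t1a[slab] <- 100
  t1 <- intensity_volume(t1a)
  truth <- binary_mask(slab)
  eroded <- slab; eroded[3, , ] <- FALSE         # one face of the slab missing
  seg <- binary_mask(eroded)
  gm <- gm_range(t1, seg)
  none <- binary_mask(array(FALSE, dims))
  out <- add_marginal_gm(seg, largest = truth, gm = gm, enhancing = none, t1 = t1)
  expect_identical(out$augmented$data, slab)      # exactly the rim recovered
  expect_identical(out$added$data, slab & !eroded)
  expect_false(any(out$added$data & seg$data))
  # a rim voxel flagged enhancing is excluded from addition
  enh <- binary_mask(slab & !eroded)
  out2 <- add_marginal_gm(seg, largest = truth, gm = gm, enhancing = enh, t1 = t1)
  expect_equal(voxel_count(out2$added), 0L)
  # segmentation already covering the body adds nothing
  out3 <- add_marginal_gm(truth, largest = truth, gm = gm, enhancing = none, t1 = t1)
  expect_equal(voxel_count(out3$added), 0L)
  expect_error(add_marginal_gm(none, truth, gm, none, t1), "empty")
})

test_that("marginal CSF removal takes in-range margin voxels and island casualties", {
  # line: [GM GM CSF GM GM] with the CSF voxel bridging two GM runs
  t1 <- line_vol(c(100, 100, 10, 100, 100, 0))
  seg <- line_mask(6, 1:5)
  csf <- csf_range(t1, line_mask(6, c(3, 6)), line_mask(6, integer(0)))
  # margin covers the bridge: removal disconnects voxels 4:5, the smaller run
  # (4:5) is an island casualty attributed to the CSF step
  margin <- line_mask(6, 3:5)
  out <- remove_marginal_csf(seg, margin, csf, t1)
  expect_equal(which(out$removed$data), 3:5)
  expect_equal(which(out$reduced$data), 1:2)
  # empty margin removes nothing
  out2 <- remove_marginal_csf(seg, line_mask(6, integer(0)), csf, t1)
  expect_equal(voxel_count(out2$removed), 0L)
  expect_identical(out2$reduced$data, seg$data)
  # margin must be inside the segmentation
  expect_error(remove_marginal_csf(seg, line_mask(6, 6), csf, t1), "subset")
  # removing everything warns
  expect_warning(out3 <- remove_marginal_csf(line_mask(6, 3), line_mask(6, 3),
                                             csf, t1),
                 "entire segmentation")
  expect_equal(which(out3$removed$data), 3L)
})

test_that("marginal enhancement removal uses the subtraction image and spares the interior", {
  sub <- line_vol(c(0, 0, 600, 0, 600, 0))
  rule <- structure(list(threshold = 300, mean = 0, sd = 300, k = 1),
                    class = "enhancement_rule")
  seg <- line_mask(6, 2:5)
  # margin excludes the interior enhancing voxel at 3; only voxel 5 removable
  margin <- line_mask(6, 5)
  out <- remove_marginal_enh(seg, margin, rule, sub)
  expect_equal(which(out$removed$data), 5L)
  expect_true(out$reduced$data[1, 1, 3])   # interior enhancement preserved
  # all-zero subtraction removes nothing
  z <- line_vol(rep(0, 6))
  out2 <- remove_marginal_enh(seg, margin, enhancement_rule(z), z)
  expect_equal(voxel_count(out2$removed), 0L)
})

test_that("full refinement on a noise-free phantom recovers injections voxel-exactly", {
  b <- phantom_generate(small_spec(noise_free = TRUE))
  sub <- compute_subtraction(b$t1_pre, b$t1_post)
  for (side in c("right", "left")) {
    cands <- lapply(b$candidates, function(a) a[[side]]$mask)
    ctx <- refine_context(cands, b$t1_pre, sub, b$csf_reference)
    for (algo in names(b$candidates)) {
      cand <- b$candidates[[algo]][[side]]
      res <- refine(cand$mask, ctx)
      expect_identical(res$added_gm$data, cand$injections$gm_erosion$data)
      expect_identical(res$removed_csf$data, cand$injections$csf_rim$data)
      expect_identical(res$removed_enh$data, cand$injections$enh_blob$data)
      expect_identical(res$refined$data, b$truth[[side]]$data)
      expect_true(res$deltas_disjoint)
      expect_conservation(res, cand$mask)
    }
  }
})

test_that("a perfect candidate on a noise-free phantom needs no correction", {
  sp <- small_spec(noise_free = TRUE)
  sp$errors <- list(perfectA = c(gm_erosion_ml = 0, csf_rim_ml = 0, enh_blob_ml = 0),
                    perfectB = c(gm_erosion_ml = 0, csf_rim_ml = 0, enh_blob_ml = 0))
  b <- phantom_generate(sp)
  sub <- compute_subtraction(b$t1_pre, b$t1_post)
  cands <- lapply(b$candidates, function(a) a$right$mask)
  expect_identical(cands$perfectA$data, b$truth$right$data)
  ctx <- refine_context(cands, b$t1_pre, sub, b$csf_reference)
  res <- refine(cands$perfectA, ctx)
  expect_equal(res$record$total_ml, 0)
})

test_that("bookkeeping conservation and delta disjointness hold across random phantoms", {
  set.seed(61)
  for (i in 1:40) {
    sp <- small_spec(seed = 1000 + i)
    # vary the injected errors subject to the region capacities
    sp$errors <- list(
      mockA = c(gm_erosion_ml = runif(1, 0, 0.08),
                csf_rim_ml = runif(1, 0, 0.12), enh_blob_ml = runif(1, 0, 0.12)),
      mockB = c(gm_erosion_ml = runif(1, 0, 0.08),
                csf_rim_ml = runif(1, 0, 0.12), enh_blob_ml = runif(1, 0, 0.12)))
    b <- phantom_generate(sp)
    sub <- compute_subtraction(b$t1_pre, b$t1_post)
    cands <- lapply(b$candidates, function(a) a$right$mask)
    ctx <- refine_context(cands, b$t1_pre, sub, b$csf_reference)
    for (algo in names(cands)) {
      res <- refine(cands[[algo]], ctx)
      expect_conservation(res, cands[[algo]])
      expect_true(res$deltas_disjoint)
      expect_true(res$record$gm_added_ml >= 0 &&
                    res$record$csf_removed_ml >= 0 &&
                    res$record$enh_removed_ml >= 0)
    }
  }
})

test_that("with acquisition noise the recovered corrections stay within 10% of the ledger", {
  sp <- small_spec(gm_sd = 0, wm_sd = 0, csf_sd = 0, noise_sd = 5, seed = 99,
                   errors = list(
                     mockA = c(gm_erosion_ml = 0.05, csf_rim_ml = 0.08,
                               enh_blob_ml = 0.1),
                     mockB = c(gm_erosion_ml = 0.03, csf_rim_ml = 0.04,
                               enh_blob_ml = 0.05)))
  b <- phantom_generate(sp)
  sub <- compute_subtraction(b$t1_pre, b$t1_post)
  cands <- lapply(b$candidates, function(a) a$right$mask)
  ctx <- refine_context(cands, b$t1_pre, sub, b$csf_reference)
  led <- b$ledger[b$ledger$side == "right", ]
  for (algo in names(cands)) {
    res <- refine(cands[[algo]], ctx)
    got <- c(res$record$gm_added_ml, res$record$csf_removed_ml,
             res$record$enh_removed_ml)
    sub_led <- led[led$algorithm == algo, ]
    want <- sub_led$realized_ml[match(c("gm_erosion", "csf_rim", "enh_blob"),
                                      sub_led$component)]
    expect_true(all(abs(got - want) <= 0.1 * want))
    expect_conservation(res, cands[[algo]])
  }
})

test_that("interior enhancing vessels and cysts are never removed", {
  for (noisy in c(FALSE, TRUE)) {
    sp <- if (noisy) small_spec(gm_sd = 0, wm_sd = 0, csf_sd = 0, noise_sd = 5,
                                seed = 3) else small_spec(noise_free = TRUE)
    b <- phantom_generate(sp)
    sub <- compute_subtraction(b$t1_pre, b$t1_post)
    for (side in c("right", "left")) {
      cands <- lapply(b$candidates, function(a) a[[side]]$mask)
      ctx <- refine_context(cands, b$t1_pre, sub, b$csf_reference)
      interior <- b$vessels[[side]]$data | b$cysts[[side]]$data
      expect_true(any(interior))
      expect_true(all(ctx$smallest$data[interior]))  # inside the consensus core
      for (algo in names(cands)) {
        res <- refine(cands[[algo]], ctx)
        expect_true(all(res$refined$data[interior]))
        expect_false(any(res$removed_csf$data[interior]))
        expect_false(any(res$removed_enh$data[interior]))
      }
    }
  }
})
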