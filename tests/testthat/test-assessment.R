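make_sweep_fixture <- function() {
  b <- phantom_generate(small_spec(noise_free = TRUE, prob_algorithms = "mockA"))
  sub <- compute_subtraction(b$t1_pre, b$t1_post)
  pm <- b$candidates$mockA$right$prob
  cands <- c(lapply(b$candidates, function(a) a$right$mask),
             lapply(seq(0, 0.9, 0.1), function(t) {
               m <- threshold_map(pm, t)
               if (any(m$data)) m else NULL
             }))
  cands <- cands[!vapply(cands, is.null, logical(1))]
  list(bundle = b, sub = sub, pm = pm,
       ctx = refine_context(cands, b$t1_pre, sub, b$csf_reference))
}

test_that("threshold sweep skips empty thresholds and matches the expected trends", {
  fx <- make_sweep_fixture()
  expect_warning(sw <- sweep_thresholds(fx$pm, fx$ctx), "empty")
  tab <- sw$table
  expect_equal(nrow(tab), 11L)
  expect_true(tab$skipped[tab$threshold == 1])   # max p < 1 under strict >
  ok <- !tab$skipped
  # GM added never decreases, CSF/enh removed never increase with threshold
  expect_true(all(diff(tab$gm_added_ml[ok]) >= 0))
  expect_true(all(diff(tab$csf_removed_ml[ok]) <= 0))
  expect_true(all(diff(tab$enh_removed_ml[ok]) <= 0))
  # the known optimum band of the constructed map
  expect_true(sw$best_threshold >= 0.4 && sw$best_threshold <= 0.6)
  # argmin equals the brute-force minimum over evaluated thresholds
  expect_equal(sw$best_threshold,
               tab$threshold[ok][which.min(tab$total_ml[ok])])
})

test_that("a map with no usable threshold errors out", {
  fx <- make_sweep_fixture()
  zz <- probability_map(array(0, dim(fx$pm$data)), spacing = fx$pm$spacing,
                        grid_id = fx$pm$grid_id)
  expect_error(suppressWarnings(sweep_thresholds(zz, fx$ctx)), "no threshold")
  expect_error(sweep_thresholds(fx$pm, fx$ctx, thresholds = c(0.5, 0.2)),
               "ascending")
})

test_that("fragmentation flag detects scatter, fragment-dominance and emptiness", {
  solid <- binary_mask(array(TRUE, c(4, 4, 4)))
  expect_false(fragmentation_flag(solid))
  scatter <- array(FALSE, c(21, 5, 5))
  scatter[seq(1, 21, 2), 3, 3] <- TRUE   # 11 isolated voxels
  expect_true(fragmentation_flag(binary_mask(scatter)))
  expect_true(fragmentation_flag(binary_mask(array(FALSE, c(3, 3, 3)))))
  # largest-component fraction rule: two similar blobs
  two <- array(FALSE, c(9, 4, 4))
  two[1:3, 1:3, 1:3] <- TRUE; two[7:9, 1:3, 1:3] <- TRUE
  expect_true(fragmentation_flag(binary_mask(two)))       # largest is 50%
  expect_false(fragmentation_flag(binary_mask(two), min_largest_fraction = 0.4))
})

test_that("summaries are linear in the components", {
  tab <- data.frame(
    algorithm = rep(c("a", "b"), each = 3),
    original_ml = c(4, 4.2, 3.9, 5, 5.1, 5.2),
    gm_added_ml = c(0.1, 0.2, 0.3, 0.2, 0.2, 0.2),
    csf_removed_ml = c(0.05, 0.05, 0.05, 0.2, 0.25, 0.15),
    enh_removed_ml = c(0.1, 0.1, 0.1, 0.5, 0.4, 0.6))
  tab$total_ml <- tab$gm_added_ml + tab$csf_removed_ml + tab$enh_removed_ml
  s <- summarize_corrections(tab)
  expect_equal(s$total_ml,
               s$gm_added_ml + s$csf_removed_ml + s$enh_removed_ml,
               tolerance = 1e-9)
  expect_equal(s$algorithm, c("a", "b"))   # ordered by mean total correction
  one <- summarize_corrections(tab[1, ])
  expect_equal(one$total_ml, tab$total_ml[1])
  expect_error(summarize_corrections(tab[0, ]), "non-empty")
})

test_that("published reference rows: component sums reproduce the printed totals", {
  ref <- read.csv(system.file("extdata", "published_mean_corrections.csv",
                              package = "hipporefine"))
  sums <- ref$gm_added_ml + ref$csf_removed_ml + ref$enh_removed_ml
  consistent <- c("e2dhipseg", "FastSurfer", "QuickNat")
  i <- ref$algorithm %in% consistent
  expect_equal(sums[i], ref$total_ml[i], tolerance = 1e-12)
})

test_that("the statistical cascade reports all stages with C(k,2) pairwise rows", {
  set.seed(71)
  tab <- data.frame(algorithm = rep(c("a", "b", "c"), each = 30),
                    total_ml = c(rnorm(30, 0.4, 0.05), rnorm(30, 0.6, 0.08),
                                 rnorm(30, 1.0, 0.1)))
  tab$original_ml <- 4; tab$gm_added_ml <- tab$csf_removed_ml <- 0
  tab$enh_removed_ml <- tab$total_ml
  st <- compare_algorithms(tab)
  expect_length(st$shapiro, 3L)
  expect_equal(nrow(st$tukey), choose(3, 2))
  expect_true(all(c("group1", "group2", "mean_difference", "p",
                    "ci_lower", "ci_upper", "significant") %in% names(st$tukey)))
  expect_identical(st$tukey$significant, st$tukey$p < 0.05)
  # tiny groups are excluded with a warning
  tab2 <- rbind(tab, data.frame(algorithm = "d", total_ml = 0.5,
                                original_ml = 4, gm_added_ml = 0,
                                csf_removed_ml = 0, enh_removed_ml = 0.5))
  expect_warning(st2 <- compare_algorithms(tab2), "fewer than")
  expect_equal(nrow(st2$tukey), choose(3, 2))
})

test_that("Tukey flags behave under the null and under strong separation", {
  set.seed(73)
  # identical distributions: significance should be rare
  false_pos <- 0L
  for (r in 1:100) {
    tab <- data.frame(algorithm = rep(c("a", "b"), each = 200),
                      total_ml = rnorm(400, 0.5, 0.1))
    tab$original_ml <- 4; tab$gm_added_ml <- tab$csf_removed_ml <- 0
    tab$enh_removed_ml <- tab$total_ml
    st <- compare_algorithms(tab)
    if (any(st$tukey$significant)) false_pos <- false_pos + 1L
  }
  expect_lte(false_pos, 10L)
  # 5 pooled SDs apart: always detected
  tab <- data.frame(algorithm = rep(c("a", "b"), each = 100),
                    total_ml = c(rnorm(100, 0.5, 0.1), rnorm(100, 1.0, 0.1)))
  tab$original_ml <- 4; tab$gm_added_ml <- tab$csf_removed_ml <- 0
  tab$enh_removed_ml <- tab$total_ml
  expect_true(all(compare_algorithms(tab)$tukey$significant))
})

test_that("refinement heatmaps average delta masks voxelwise", {
  b <- phantom_generate(small_spec(noise_free = TRUE))
  sub <- compute_subtraction(b$t1_pre, b$t1_post)
  cands <- lapply(b$candidates, function(a) a$right$mask)
  ctx <- refine_context(cands, b$t1_pre, sub, b$csf_reference)
  resA <- refine(cands$mockA, ctx)
  resB <- refine(cands$mockB, ctx)
  # identical results -> heatmap equals the indicator of the delta mask
  h1 <- refinement_heatmap(list(resA, resA), kind = "removed_csf")
  expect_equal(h1$data, resA$removed_csf$data + 0)
  # a voxel corrected in one of two subjects gets 0.5
  h2 <- refinement_heatmap(list(resA, resB), kind = "removed_csf")
  only_a <- resA$removed_csf$data & !resB$removed_csf$data
  expect_true(all(h2$data[only_a] == 0.5))
  expect_true(min(h2$data) >= 0 && max(h2$data) <= 1)
  # empty deltas average to zero
  h3 <- refinement_heatmap(list(resA, resB), kind = "added_gm")
  expect_equal(max(h3$data[!(resA$added_gm$data | resB$added_gm$data)]), 0)
})
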