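test_that("consensus mask applies the three-or-more-annotators rule", {
  base <- matrix(FALSE, 10, 10); base[3:7, 4] <- TRUE
  expect_equal(consensus_mask(rep(list(base), 5)), base)
  masks <- rep(list(matrix(FALSE, 10, 10)), 5)
  masks[[1]][5, 5] <- masks[[2]][5, 5] <- TRUE            # 2 votes
  masks[[1]][6, 6] <- masks[[2]][6, 6] <- masks[[3]][6, 6] <- TRUE  # 3 votes
  cons <- consensus_mask(masks)
  expect_false(cons[5, 5])
  expect_true(cons[6, 6])
  expect_error(consensus_mask(c(masks, list(matrix(FALSE, 3, 3)))), "shape")
})

test_that("dilated matching tolerates small displacements", {
  ref <- matrix(FALSE, 30, 30); ref[15, 5:25] <- TRUE
  cnt <- match_detection(ref, ref, 3)
  expect_equal(cnt$tp, cnt$p)
  expect_equal(cnt$fn, 0); expect_equal(cnt$fp, 0)
  empty <- matrix(FALSE, 30, 30)
  cnt0 <- match_detection(ref, empty, 3)
  expect_equal(cnt0$tp, 0); expect_equal(cnt0$fn, cnt0$p)
  expect_equal(cnt0$fp, 0)
  # 1-px shift forgiven by any dilation radius >= 1
  shifted <- matrix(FALSE, 30, 30); shifted[16, 5:25] <- TRUE
  cnt1 <- match_detection(ref, shifted, 1)
  expect_equal(cnt1$fn, 0); expect_equal(cnt1$fp, 0)
  # radius 0 reduces to exact pixel agreement
  cnt2 <- match_detection(ref, shifted, 0)
  expect_equal(cnt2$fn, cnt2$p); expect_equal(cnt2$fp, sum(shifted))
  expect_true(cnt2$tp + cnt2$fn == cnt2$p)
  expect_error(match_detection(ref, matrix(FALSE, 5, 5)), "shape")
})

test_that("rates use the positives-normalized FPR", {
  r <- rates(list(tp = 70, fp = 0, p = 100))
  expect_equal(r$tpr, 0.70)
  r2 <- rates(list(tp = 72, fp = 14, p = 100))
  expect_equal(r2$fpr, 0.14)
  expect_equal(r2$specificity, 0.86)
  r3 <- rates(list(tp = 50, fp = 0, p = 50))
  expect_equal(unlist(r3), c(tpr = 1, fpr = 0, specificity = 1))
  expect_error(rates(list(tp = 0, fp = 0, p = 0)), "undefined")
})

test_that("roc_grid emits one point per threshold triple with pooled counts", {
  sc <- generate_scene(scene_spec(image_size = c(160, 224), n_filaments = 2,
                                  n_flocs = 1,
                                  filament_length_px_range = c(40, 120),
                                  floc_radius_px_range = c(12, 20), seed = 9))
  cfg <- pipeline_config(resize_factor = 1)
  out1 <- roc_grid(list(sc$image), list(sc$truth$filament_mask),
                   10.5e-4, 6.4, 3.2, cfg)
  expect_equal(nrow(out1), 1L)
  expect_equal(out1$tp + out1$fn, sum(sc$truth$filament_mask))
  expect_true(out1$tpr >= 0 && out1$tpr <= 1)
  grid <- roc_grid(list(sc$image), list(sc$truth$filament_mask),
                   c(5e-4, 10.5e-4), 6.4, c(2.8, 3.2, 4.0), cfg)
  expect_equal(nrow(grid), 6L)
  expect_true(all(grid$specificity == 1 - grid$fpr))
  # RRG sweep at fixed variance/distance: sensitivity trades monotonically
  sub <- grid[grid$variance_threshold == 10.5e-4, ]
  sub <- sub[order(sub$rrg_threshold), ]
  expect_true(all(diff(sub$tpr) <= 1e-12))
  expect_true(all(diff(sub$fp) <= 0))
  pi_attr <- attr(grid, "per_image")
  expect_equal(nrow(pi_attr), 6L)   # one image x 6 triples
})

test_that("convex hull keeps the non-dominated frontier, collinear included", {
  one <- data.frame(fpr = 0.3, tpr = 0.6)
  expect_equal(nrow(convex_hull_points(one)), 1L)
  pts <- data.frame(fpr = c(0.10, 0.20, 0.30, 0.25),
                    tpr = c(0.50, 0.60, 0.70, 0.40))
  hull <- convex_hull_points(pts)
  # the (0.25, 0.40) point is dominated by (0.20, 0.60): excluded
  expect_false(any(hull$fpr == 0.25))
  # the three collinear frontier points are all retained
  expect_equal(nrow(hull), 3L)
  expect_equal(hull$fpr, c(0.10, 0.20, 0.30))
})

test_that("hull points are mutually non-dominated on random clouds", {
  set.seed(51)
  for (k in 1:20) {
    pts <- data.frame(fpr = runif(40), tpr = runif(40))
    hull <- convex_hull_points(pts)
    # no input point strictly dominates any hull point
    for (i in seq_len(nrow(hull)))
      expect_false(any(pts$tpr > hull$tpr[i] + 1e-12 &
                       pts$fpr < hull$fpr[i] - 1e-12))
    # and hull rows never dominate each other
    if (nrow(hull) >= 2) {
      for (i in seq_len(nrow(hull))) for (j in seq_len(nrow(hull))) {
        if (i == j) next
        expect_false(hull$tpr[i] < hull$tpr[j] - 1e-12 &&
                     hull$fpr[i] > hull$fpr[j] + 1e-12)
      }
    }
  }
})
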