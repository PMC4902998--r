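test_that("scene generation is deterministic and respects object counts", {
  sp <- scene_spec(image_size = c(200, 260), n_filaments = 3, n_flocs = 1,
                   seed = 12)
  a <- generate_scene(sp); b <- generate_scene(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$spines, b$truth$spines)
  expect_length(a$truth$spines, 3L)
  empty <- generate_scene(scene_spec(image_size = c(128, 128),
                                     n_filaments = 0, n_flocs = 0, seed = 1))
  expect_false(any(empty$truth$filament_mask))
  expect_false(any(empty$truth$floc_mask))
  five <- generate_scene(scene_spec(image_size = c(400, 500), n_filaments = 5,
                                    n_flocs = 0,
                                    filament_length_px_range = c(31, 150),
                                    seed = 2))
  expect_length(five$truth$spines, 5L)
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_scene(sp)); after <- runif(1)
  expect_identical(before, after)
})

test_that("stored spine lengths match recomputation from the stored paths", {
  sc <- generate_scene(scene_spec(image_size = c(300, 400), n_filaments = 4,
                                  n_flocs = 0, seed = 13))
  for (s in sc$truth$spines) {
    d <- abs(diff(s$path))
    # consecutive chain pixels are 8-adjacent
    expect_true(all(d <= 1) && all(rowSums(d) >= 1))
    len <- sum(ifelse(d[, 1] > 0 & d[, 2] > 0, sqrt(2), 1))
    expect_equal(s$geodesic_length_px, len, tolerance = 1e-9)
    # spines lie inside the rendered filament mask
    expect_true(all(sc$truth$filament_mask[s$path + 1L]))
  }
})

test_that("rendered filament width agrees with the requested width", {
  for (w in c(2.5, 4, 5)) {
    sc <- generate_scene(scene_spec(n_filaments = 1, n_flocs = 0,
                                    filament_width_px_range = c(w, w),
                                    filament_length_px_range = c(200, 200),
                                    curvature_sd = 0.005, seed = 3))
    edt <- euclidean_distance_map(sc$truth$filament_mask)
    sp <- sc$truth$spines[[1]]$path
    mid <- sp[round(nrow(sp) * 0.33):round(nrow(sp) * 0.67), , drop = FALSE]
    est <- 2 * mean(edt[mid + 1L])
    expect_lt(abs(est - w), 0.5)
  }
})

test_that("out-of-focus objects are rendered but excluded from ground truth", {
  sc <- generate_scene(scene_spec(image_size = c(260, 340), n_filaments = 1,
                                  n_flocs = 0, n_blurred_objects = 2,
                                  seed = 14))
  expect_equal(sum(sc$truth$labels == "out_of_focus"), 2L)
  expect_length(sc$truth$spines, 1L)  # only the in-focus filament
  # blurred structures leave intensity traces outside the truth masks
  off_mask <- !(sc$truth$filament_mask | sc$truth$floc_mask)
  resid <- abs(sc$image$pixels - 0.55)
  expect_gt(sum(resid[off_mask] > 0.03), 50)
})

test_that("the scenario suite covers the five difficult situations", {
  suite <- scenario_suite(7)
  expect_length(suite, 5L)
  expect_named(suite, c("isolated", "crossing", "touching_floc",
                        "high_floc_density", "mixed_focus"))
  # crossing scene: at least two spines share a pixel
  sp <- suite$crossing$truth$spines
  keys <- lapply(sp, function(s) paste(s$path[, 1], s$path[, 2]))
  shared <- FALSE
  for (i in 1:(length(keys) - 1)) for (j in (i + 1):length(keys))
    if (length(intersect(keys[[i]], keys[[j]])) > 0) shared <- TRUE
  expect_true(shared)
  # high-floc scene really is floc-heavy
  expect_gte(sum(suite$high_floc_density$truth$floc_mask), 5000)
  # mixed-focus scene holds blurred objects outside the masks
  expect_gte(sum(suite$mixed_focus$truth$labels == "out_of_focus"), 1L)
  expect_length(suite$mixed_focus$truth$spines, 3L)
})

test_that("infeasible packing errors out after bounded retries", {
  sp <- scene_spec(image_size = c(64, 64), n_filaments = 40,
                   filament_length_px_range = c(60, 60), seed = 5)
  expect_error(generate_scene(sp), "retries")
})
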