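test_that("skeletonization thins without breaking or thickening components", {
  # an already-thin line is unchanged
  line <- matrix(FALSE, 9, 30); line[5, 3:27] <- TRUE
  sk <- skeletonize(line)
  expect_length(sk, 1L)
  expect_equal(sum(sk[[1]]$mask), 25L)
  # a solid rectangle collapses to one connected 1-px-wide skeleton
  rect <- matrix(FALSE, 15, 60); rect[4:12, 6:55] <- TRUE
  sk <- skeletonize(rect)
  expect_length(sk, 1L)
  m <- sk[[1]]$mask
  expect_equal(max(filatrace:::.cc_label_cpp(m, 8L)), 1L)
  no22 <- !any(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] &
               m[-nrow(m), -1] & m[-1, -1])
  expect_true(no22)
  expect_equal(length(skeletonize(matrix(FALSE, 5, 5))), 0L)
})

test_that("a solid annulus thins to a closed loop with no endpoints", {
  an <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    d <- sqrt((i - 20)^2 + (j - 20)^2)
    an[i, j] <- d >= 8 & d <= 14
  }
  thin <- filatrace:::.thin_cpp(an)
  # hole preserved: complement still splits into outside + inside
  expect_equal(max(filatrace:::.cc_label_cpp(!thin, 4L)), 2L)
  sk <- skeletonize(an)
  expect_length(sk, 1L)
  expect_equal(nrow(find_endpoint_candidates(sk[[1]])), 0L)
  # the loop is returned whole as its own spine
  spines <- extract_spines(an)
  expect_length(spines, 1L)
  expect_equal(nrow(spines[[1]]$path), sum(sk[[1]]$mask))
  expect_gt(spines[[1]]$geodesic_length_px, 2 * pi * 8)
})

test_that("endpoint candidates pick border-nearest tips with index tie-break", {
  seg <- skeleton_component(matrix(TRUE, 1, 20))
  cand <- find_endpoint_candidates(seg)
  expect_equal(sort(cand[, 2]), c(0L, 19L))
  # tilted X: each arm tip is uniquely nearest one border
  bres <- function(m, a, b) {
    n <- max(abs(b - a)) + 1L
    pts <- cbind(round(seq(a[1], b[1], length.out = n)),
                 round(seq(a[2], b[2], length.out = n)))
    m[pts] <- TRUE
    m
  }
  x <- matrix(FALSE, 21, 27)
  ctr <- c(11, 14)
  tips <- list(c(1, 11), c(21, 17), c(7, 1), c(15, 27))
  for (tp in tips) x <- bres(x, ctr, tp)
  skx <- skeleton_component(x)
  cand <- find_endpoint_candidates(skx)
  expect_equal(nrow(cand), 4L)
  # brute-force nearest-to-border oracle over all endpoints
  cnt <- filatrace:::.neighbour_count_cpp(x)
  ep <- which(x & cnt == 1L, arr.ind = TRUE) - 1L
  bd <- cbind(ep[, 1], nrow(x) - 1L - ep[, 1], ep[, 2], ncol(x) - 1L - ep[, 2])
  expected <- unique(t(vapply(1:4, function(b)
    ep[which.min(bd[, b]), ], integer(2))))
  expect_equal(cand[order(cand[, 1], cand[, 2]), ],
               expected[order(expected[, 1], expected[, 2]), ],
               ignore_attr = TRUE)
  # two endpoints equidistant from the top border: smaller row-major index
  u <- matrix(FALSE, 10, 11)
  u[1:10, 2] <- TRUE; u[1:10, 9] <- TRUE; u[10, 2:9] <- TRUE
  sku <- skeleton_component(u)
  cu <- find_endpoint_candidates(sku)
  top <- cu[cu[, 1] == 0L, , drop = FALSE]
  expect_equal(unname(top[1, ]), c(0L, 1L))
})

test_that("geodesic distances follow unit and diagonal step costs", {
  seg <- skeleton_component(matrix(TRUE, 1, 12))
  d <- geodesic_distance(seg, c(0L, 0L))
  expect_equal(as.numeric(d), as.numeric(0:11))
  diagm <- matrix(FALSE, 2, 2); diagm[1, 1] <- diagm[2, 2] <- TRUE
  dd <- geodesic_distance(skeleton_component(diagm), c(0L, 0L))
  expect_equal(dd[2, 2], sqrt(2), tolerance = 1e-12)
  expect_equal(sqrt(2), 1.4142, tolerance = 1e-4)
  expect_error(geodesic_distance(seg, c(5L, 5L)), "origin")
})

test_that("geodesic distances equal an explicit Dijkstra oracle", {
  set.seed(31)
  for (k in 1:25) {
    m <- random_tree_skeleton(50)
    px <- which(m, arr.ind = TRUE) - 1L
    origin <- px[sample(nrow(px), 1L), ]
    mine <- geodesic_distance(skeleton_component(m), origin)
    oracle <- igraph_geodesic(m, origin)
    expect_equal(mine[m], oracle[m], tolerance = 1e-9)
  }
})

test_that("geodesic distance is symmetric and satisfies the triangle inequality", {
  set.seed(32)
  for (k in 1:6) {
    m <- random_tree_skeleton(40)
    skel <- skeleton_component(m)
    px <- which(m, arr.ind = TRUE) - 1L
    abc <- px[sample(nrow(px), min(3L, nrow(px))), , drop = FALSE]
    if (nrow(abc) < 3L) next
    dab <- geodesic_distance(skel, abc[1, ])[abc[2, 1] + 1, abc[2, 2] + 1]
    dba <- geodesic_distance(skel, abc[2, ])[abc[1, 1] + 1, abc[1, 2] + 1]
    expect_equal(dab, dba, tolerance = 1e-9)
    dac <- geodesic_distance(skel, abc[1, ])[abc[3, 1] + 1, abc[3, 2] + 1]
    dbc <- geodesic_distance(skel, abc[2, ])[abc[3, 1] + 1, abc[3, 2] + 1]
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("strongest geodesic ends match exhaustive search on simple shapes", {
  seg <- skeleton_component(matrix(TRUE, 1, 17))
  sge <- find_sge(seg, find_endpoint_candidates(seg))
  expect_equal(sge$max_dist, 16)
  expect_equal(sort(c(sge$end_a[2], sge$end_b[2])), c(0, 16))
  # L shape: arm lengths plus the diagonal corner cut (7 + sqrt2 + 8)
  L <- matrix(FALSE, 12, 12)
  L[2:10, 2] <- TRUE; L[10, 2:11] <- TRUE
  skL <- skeleton_component(L)
  sgeL <- find_sge(skL, find_endpoint_candidates(skL))
  expect_equal(sgeL$max_dist, 15 + sqrt(2), tolerance = 1e-12)
})

test_that("candidate-restricted SGE equals the all-endpoint-pairs oracle on trees", {
  set.seed(33)
  n_checked <- 0
  for (k in 1:20) {
    m <- random_tree_skeleton(45)
    cnt <- filatrace:::.neighbour_count_cpp(m)
    if (sum(m & cnt == 1L) < 2L) next
    skel <- skeleton_component(m)
    cand <- find_endpoint_candidates(skel)
    mine <- find_sge(skel, cand)
    oracle <- exhaustive_sge(m)
    # the 4 border-nearest candidates may in principle miss the diameter,
    # but on these small trees with <= 4 tips they cannot
    if (sum(m & cnt == 1L) <= 4L) {
      expect_equal(mine$max_dist, oracle$max_dist, tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 5)
})

test_that("spine extraction prunes branches by the summed-distance minimum", {
  # unbranched skeleton: spine is the whole skeleton
  seg <- skeleton_component(matrix(TRUE, 1, 23))
  sge <- find_sge(seg, find_endpoint_candidates(seg))
  sp <- extract_spine(seg, sge$end_a, sge$end_b)
  expect_equal(nrow(sp$path), 23L)
  expect_equal(sp$geodesic_length_px, sge$max_dist)
  # T shape: 41-px bar, 10-px stem; spine = the bar
  Tm <- matrix(FALSE, 15, 45)
  Tm[2, 2:42] <- TRUE
  Tm[3:12, 22] <- TRUE
  skT <- skeleton_component(Tm)
  sgeT <- find_sge(skT, find_endpoint_candidates(skT))
  spT <- extract_spine(skT, sgeT$end_a, sgeT$end_b)
  expect_equal(spT$geodesic_length_px, 40)
  expect_true(all(spT$path[, 1] == 1L))      # bar row only, stem excluded
  expect_equal(nrow(spT$path), 41L)
  # symmetric Y: spine joins the two longest arms
  Y <- matrix(FALSE, 25, 25)
  Y[cbind(12:2, 12:2)] <- TRUE    # up-left arm, 11 px
  Y[cbind(12:2, 12:22)] <- TRUE   # up-right arm
  Y[13:18, 12] <- TRUE            # short stem, 6 px
  skY <- skeleton_component(Y)
  sgeY <- find_sge(skY, find_endpoint_candidates(skY))
  spY <- extract_spine(skY, sgeY$end_a, sgeY$end_b)
  expect_equal(spY$geodesic_length_px, 20 * sqrt(2), tolerance = 1e-9)
  expect_false(any(spY$path[, 1] > 12))      # stem not part of the spine
})

test_that("spines equal the Dijkstra shortest path between the SGE on trees", {
  set.seed(34)
  for (k in 1:15) {
    m <- random_tree_skeleton(50)
    cnt <- filatrace:::.neighbour_count_cpp(m)
    if (sum(m & cnt == 1L) < 2L) next
    skel <- skeleton_component(m)
    sge <- find_sge(skel, find_endpoint_candidates(skel))
    sp <- extract_spine(skel, sge$end_a, sge$end_b)
    expect_equal(sp$geodesic_length_px, sge$max_dist, tolerance = 1e-9)
    d <- igraph_geodesic(m, sge$end_a)
    expect_equal(sp$geodesic_length_px,
                 d[sge$end_b[1] + 1, sge$end_b[2] + 1], tolerance = 1e-9)
    # spine pixels are a subset of the skeleton
    expect_true(all(m[sp$path + 1L]))
  }
})

test_that("branch reprocessing recovers the arms of crossing filaments", {
  # X-cross of two 80-px diagonals
  X <- matrix(FALSE, 81, 81)
  X[cbind(1:81, 1:81)] <- TRUE
  X[cbind(1:81, 81:1)] <- TRUE
  spines <- extract_spines(X, min_len_px = 31L)
  expect_gte(length(spines), 2L)
  covered <- spine_mask(spines, c(81, 81))
  expect_gte(sum(covered & X) / sum(X), 0.95)
  # short branches are pruned silently
  Tm <- matrix(FALSE, 15, 45)
  Tm[2, 2:42] <- TRUE; Tm[3:12, 22] <- TRUE
  skT <- skeleton_component(Tm)
  sgeT <- find_sge(skT, find_endpoint_candidates(skT))
  spT <- extract_spine(skT, sgeT$end_a, sgeT$end_b)
  expect_length(reprocess_branches(skT, spT, 31L), 0L)
  # unbranched skeleton leaves no residual
  seg <- skeleton_component(matrix(TRUE, 1, 40))
  sge <- find_sge(seg, find_endpoint_candidates(seg))
  sp <- extract_spine(seg, sge$end_a, sge$end_b)
  expect_length(reprocess_branches(seg, sp), 0L)
})
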