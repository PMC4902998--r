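#' Consensus reference mask from several annotators
#'
#' A pixel is a true filament pixel when it was marked by at least
#' `min_votes` annotators (default 3, the majority of five experts).
#'
#' @param annotator_masks list of logical matrices of identical shape.
#' @param min_votes minimum number of annotators marking a pixel.
#' @return A logical consensus mask.
#' @export
consensus_mask <- function(annotator_masks, min_votes = 3L) {
  stopifnot(length(annotator_masks) >= min_votes)
  dims <- dim(annotator_masks[[1L]])
  for (m in annotator_masks)
    if (!all(dim(m) == dims)) stop("annotator mask shapes differ")
  votes <- Reduce(`+`, lapply(annotator_masks, function(m) m * 1L))
  votes >= min_votes
}

#' Match a detection against a reference marking
#'
#' Pixelwise comparison tolerant to small displacements: true positives
#' are reference pixels covered by the disc-dilated detection, false
#' negatives the remaining reference pixels, false positives the detected
#' pixels not covered by the disc-dilated reference, and true negatives
#' everything else. With `dilation_radius = 0` this reduces to exact
#' pixel agreement.
#'
#' @param reference logical matrix of consensus filament pixels.
#' @param detected logical matrix of detected filament pixels.
#' @param dilation_radius disc radius (px) of the matching tolerance.
#' @return A list of class `eval_counts`: `tp`, `fp`, `fn`, `tn`, `p`
#'   (positives = tp + fn) and `n` (negatives).
#' @export
match_detection <- function(reference, detected, dilation_radius = 3L) {
  if (!all(dim(reference) == dim(detected)))
    stop("reference and detection shapes differ")
  if (dilation_radius < 0) stop("dilation_radius must be >= 0")
  det_d <- dilate_disc(detected, dilation_radius)
  ref_d <- dilate_disc(reference, dilation_radius)
  tp <- sum(reference & det_d)
  fn <- sum(reference & !det_d)
  fp <- sum(detected & !ref_d)
  total <- length(reference)
  structure(list(tp = tp, fp = fp, fn = fn, tn = total - tp - fn - fp,
                 p = tp + fn, n = total - (tp + fn)),
            class = "eval_counts")
}

#' Detection rates under the positives-normalized FPR
#'
#' `TPR = TP / P`. The false positive rate is deliberately normalized by
#' the positives rather than the negatives: the negatives are dominated by
#' background and non-filament objects, so `FP / N` would be vanishingly
#' small and misleading. Hence `FPR = FP / P` (which can exceed 1) and
#' `specificity = 1 - FPR`.
#'
#' @param counts an `eval_counts` object from [match_detection()], or any
#'   list with `tp`, `fp` and `p`.
#' @return A list with `tpr`, `fpr` and `specificity`.
#' @export
rates <- function(counts) {
  if (is.null(counts$p) || counts$p <= 0)
    stop("rates undefined: no positive pixels in the reference")
  tpr <- counts$tp / counts$p
  fpr <- counts$fp / counts$p
  list(tpr = tpr, fpr = fpr, specificity = 1 - fpr)
}

#' ROC grid over the three pipeline thresholds
#'
#' Runs the full detection pipeline on every image for every combination
#' of variance, distance and RRG thresholds, pools the match counts across
#' images, and emits one ROC point per threshold triple. The variance
#' threshold acts as the coarse adjustment, distance and RRG as
#' progressively finer ones, so the stage results are cached accordingly
#' (preprocessing once per image, binarization per variance value, spines
#' per variance-distance pair).
#'
#' @param images list of [gray_image] objects.
#' @param references list of logical reference masks, one per image, at
#'   the processed (downsampled) resolution.
#' @param variance_grid,distance_grid,rrg_grid numeric threshold grids.
#' @param config base [pipeline_config]; its three grid thresholds are
#'   overridden, everything else (size rules, matching radius, resize
#'   factor) is used as given.
#' @return A data frame with one row per threshold triple: the thresholds,
#'   pooled counts, `tpr`, `fpr`, `specificity`. Per-image rates are
#'   attached as attribute `"per_image"` for dispersion analysis.
#' @export
roc_grid <- function(images, references, variance_grid, distance_grid,
                     rrg_grid, config = pipeline_config()) {
  stopifnot(length(images) == length(references),
            length(variance_grid) >= 1, length(distance_grid) >= 1,
            length(rrg_grid) >= 1)
  enhanced <- lapply(images, function(img) {
    pre <- preprocess_stage(img, config)
    list(varmap = variance_transform(pre$enhanced, config$variance_window,
                                     config$variance_sample),
         dim = dim(pre$enhanced$pixels))
  })
  rows <- list()
  per_image <- list()
  for (vt in variance_grid) {
    masks <- lapply(enhanced, function(e) {
      m <- binarize(e$varmap, vt)
      m <- remove_small_objects(m, config$min_area_px)
      fill_small_holes(m, config$max_hole_diameter_px)
    })
    for (dt in distance_grid) {
      spines_per_image <- lapply(masks, function(m) {
        if (!any(m)) return(list())
        dm <- euclidean_distance_map(m)
        dil <- if (is.null(config$floc_dilation_radius)) dt
               else config$floc_dilation_radius
        thin <- remove_flocs(m, extract_floc_mask(dm, dt, dil))
        extract_spines(thin, config$min_filament_len_px)
      })
      for (rt in rrg_grid) {
        pooled <- c(tp = 0, fp = 0, fn = 0, tn = 0, p = 0)
        for (i in seq_along(images)) {
          recs <- filter_by_rrg(spines_per_image[[i]], rt,
                                image_id = sprintf("img%03d", i))
          det <- spine_mask(recs, enhanced[[i]]$dim)
          cnt <- match_detection(references[[i]], det,
                                 config$eval_dilation_radius_px)
          pooled <- pooled + c(cnt$tp, cnt$fp, cnt$fn, cnt$tn, cnt$p)
          r <- if (cnt$p > 0) rates(cnt) else
            list(tpr = NA_real_, fpr = NA_real_, specificity = NA_real_)
          per_image[[length(per_image) + 1L]] <- data.frame(
            image = i, variance_threshold = vt, distance_threshold = dt,
            rrg_threshold = rt, tpr = r$tpr, fpr = r$fpr)
        }
        pr <- rates(as.list(pooled))
        rows[[length(rows) + 1L]] <- data.frame(
          variance_threshold = vt, distance_threshold = dt,
          rrg_threshold = rt, tp = pooled[["tp"]], fp = pooled[["fp"]],
          fn = pooled[["fn"]], tn = pooled[["tn"]],
          tpr = pr$tpr, fpr = pr$fpr, specificity = pr$specificity)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_image") <- do.call(rbind, per_image)
  out
}

#' Rasterize filament records into a detection mask
#'
#' @param records list of `filament_record` objects.
#' @param dim `(rows, cols)` of the target mask.
#' @return A logical matrix with the spine pixels of all records set.
#' @export
spine_mask <- function(records, dim) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  for (r in records) {
    p <- if (inherits(r, "filament_record")) r$spine$path else r$path
    m[cbind(p[, 1L] + 1L, p[, 2L] + 1L)] <- TRUE
  }
  m
}

#' Upper-left convex hull of a set of ROC points
#'
#' Returns the subset of points lying on the upper-left convex hull in
#' (FPR, TPR) space: the non-dominated frontier of the threshold search.
#' Collinear frontier points are retained; points with both a lower TPR
#' and a higher FPR than some other point are always excluded.
#'
#' @param points data frame with `fpr` and `tpr` columns (e.g. from
#'   [roc_grid()]).
#' @param tol collinearity tolerance for the turn test.
#' @return The hull rows of `points`, sorted by FPR.
#' @export
convex_hull_points <- function(points, tol = 1e-12) {
  stopifnot(nrow(points) >= 1L, all(c("fpr", "tpr") %in% names(points)))
  o <- order(points$fpr, -points$tpr)
  pts <- points[o, , drop = FALSE]
  # drop repeated fpr values except the best tpr at each
  first <- !duplicated(pts$fpr)
  pts <- pts[first, , drop = FALSE]
  n <- nrow(pts)
  if (n == 1L) { rownames(pts) <- NULL; return(pts) }
  # monotone-chain upper hull over (fpr, tpr); keep collinear points
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      cross <- (pts$fpr[b] - pts$fpr[a]) * (pts$tpr[i] - pts$tpr[a]) -
               (pts$tpr[b] - pts$tpr[a]) * (pts$fpr[i] - pts$fpr[a])
      if (cross > tol) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  # truncate after the maximal TPR: beyond it every point is dominated
  tmax <- max(pts$tpr[hull])
  keep <- hull[seq_len(max(which(pts$tpr[hull] >= tmax - tol)))]
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
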