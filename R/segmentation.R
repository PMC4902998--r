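#' Local-variance transform
#'
#' Per-pixel variance of the intensities in a small odd window (default
#' 3x3, reflect padding). Sharp in-focus transitions produce high local
#' variance while strongly blurred (out-of-focus) structures stay low, so
#' thresholding this map selects the optically defined in-focus sample
#' volume.
#'
#' @param image a [gray_image] (typically the enhanced image) or a numeric
#'   matrix.
#' @param window odd window side (>= 3).
#' @param sample use the sample (n-1) instead of the population (n)
#'   normalization.
#' @return A non-negative numeric matrix of the same shape.
#' @export
variance_transform <- function(image, window = 3L, sample = FALSE) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  px <- if (inherits(image, "gray_image")) image$pixels else image
  n <- window^2
  s1 <- box_sum(px, window)
  s2 <- box_sum(px^2, window)
  v <- s2 / n - (s1 / n)^2
  if (sample) v <- v * n / (n - 1)
  v[v < 0] <- 0  # guard against catastrophic cancellation on flat areas
  v
}

#' Threshold a variance map into a binary mask
#'
#' Pixels whose local variance is at least `variance_threshold` become
#' object. A fixed threshold across all images guarantees that the same
#' virtual sample volume is evaluated everywhere; blurred out-of-focus
#' objects fall below it and are discarded.
#'
#' @param varmap variance map from [variance_transform()].
#' @param variance_threshold positive threshold (on `[0,1]`-scale
#'   intensities; the ROC-optimal default in [pipeline_config()] is
#'   10.5e-4).
#' @return A logical matrix.
#' @export
binarize <- function(varmap, variance_threshold) {
  if (variance_threshold <= 0) stop("variance_threshold must be > 0")
  varmap >= variance_threshold
}

#' Remove small connected components
#'
#' Deletes 8-connected components with fewer than `min_area_px` pixels.
#' The default 77 px is the area of the smallest expected filament
#' (2.5 px wide by 31 px long).
#'
#' @param mask logical matrix.
#' @param min_area_px minimum retained component area (px).
#' @return A logical matrix.
#' @export
remove_small_objects <- function(mask, min_area_px = 77L) {
  if (min_area_px < 1) stop("min_area_px must be >= 1")
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(mask)
  lab <- .cc_label_cpp(mask, 8L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Restricted hole filling
#'
#' Fills enclosed background regions whose equivalent-area diameter
#' `2 * sqrt(area / pi)` is smaller than `max_hole_diameter_px`. Larger
#' enclosed regions -- e.g. loops formed by curved filaments -- and any
#' background region touching the image border are left untouched. Holes
#' are 4-connected (the standard dual of 8-connected objects).
#'
#' @param mask logical matrix.
#' @param max_hole_diameter_px largest hole diameter that is filled;
#'   the default 2.5 px is the smallest expected filament width.
#' @return A logical matrix.
#' @export
fill_small_holes <- function(mask, max_hole_diameter_px = 2.5) {
  if (max_hole_diameter_px <= 0) stop("max_hole_diameter_px must be > 0")
  storage.mode(mask) <- "logical"
  bg <- !mask
  if (!any(bg)) return(mask)
  lab <- .cc_label_cpp(bg, 4L)
  border_labels <- unique(c(lab[1L, ], lab[nrow(lab), ],
                            lab[, 1L], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  sizes <- tabulate(lab)
  eq_diam <- 2 * sqrt(sizes / pi)
  fill <- setdiff(which(eq_diam < max_hole_diameter_px), border_labels)
  out <- mask
  out[lab %in% fill] <- TRUE
  out
}
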