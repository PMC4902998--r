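#' Euclidean distance map
#'
#' Assigns to every object pixel its exact Euclidean distance to the
#' nearest background pixel (0 on background). Used as a per-pixel
#' thickness measure: thick flocs reach large interior distances while
#' filaments, only a few pixels wide, never do.
#'
#' @param mask logical matrix.
#' @return A non-negative numeric matrix of the same shape.
#' @export
euclidean_distance_map <- function(mask) {
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  if (!any(!mask)) stop("mask has no background pixel")
  dm <- EBImage::distmap(mask * 1, metric = "euclidean")
  matrix(as.numeric(dm), nrow(mask), ncol(mask))
}

#' Extract the floc (agglomerate) mask by distance filtering
#'
#' Keeps the pixels whose distance-map value is at least
#' `distance_threshold` -- the eroded cores of thick agglomerates, since
#' border pixels and all thin objects are removed -- then dilates them
#' with a disc to approximate the original floc extent. The dilation
#' radius defaults to the threshold itself, which is the erosion depth of
#' the retained core.
#'
#' @param distmap distance map from [euclidean_distance_map()].
#' @param distance_threshold positive thickness threshold (px).
#' @param dilation_radius disc radius for the reconstruction dilation;
#'   defaults to `distance_threshold`.
#' @return A logical floc mask.
#' @export
extract_floc_mask <- function(distmap, distance_threshold,
                              dilation_radius = distance_threshold) {
  if (distance_threshold <= 0) stop("distance_threshold must be > 0")
  core <- distmap >= distance_threshold
  dilate_disc(core, dilation_radius)
}

#' Remove floc regions from a mask
#'
#' `mask AND NOT floc_mask`: subtracts the reconstructed agglomerate
#' regions, leaving only thin components.
#'
#' @param mask logical matrix (post-cleaning binary image).
#' @param floc_mask logical matrix from [extract_floc_mask()].
#' @return A logical matrix.
#' @export
remove_flocs <- function(mask, floc_mask) {
  if (!all(dim(mask) == dim(floc_mask)))
    stop("mask and floc_mask shapes differ")
  mask & !floc_mask
}
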