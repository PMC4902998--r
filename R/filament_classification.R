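#' Reduced radius of gyration of a pixel set
#'
#' The radius of gyration (square root of the summed second central
#' moments) normalized by the radius of the circle with the same area:
#' \deqn{RRG = \sqrt{M_{2x} + M_{2y}} / (D_{eq}/2),\quad
#'       D_{eq} = 2\sqrt{A/\pi}}
#' with \eqn{M_{2x}, M_{2y}} the per-axis second moments about the
#' centroid and \eqn{A = N} the pixel count. A perfect disc gives
#' \eqn{\sqrt{2}/2}; elongated shapes give much larger values, which makes
#' the RRG an effective filter separating filament spines from the compact
#' debris shed by agglomerate edges.
#'
#' @param pixels n x 2 matrix of pixel coordinates (any consistent origin).
#' @return A list of class `shape_stats`: `n_pixels`, `centroid`, `m2x`,
#'   `m2y`, `area_equiv_diameter`, `rrg`.
#' @export
compute_rrg <- function(pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2L)
  n <- nrow(pixels)
  if (n < 1L) stop("pixel set is empty")
  xg <- mean(pixels[, 1L]); yg <- mean(pixels[, 2L])
  m2x <- sum((pixels[, 1L] - xg)^2) / n
  m2y <- sum((pixels[, 2L] - yg)^2) / n
  deq <- 2 * sqrt(n / pi)
  structure(list(n_pixels = n, centroid = c(xg, yg), m2x = m2x, m2y = m2y,
                 area_equiv_diameter = deq,
                 rrg = sqrt(m2x + m2y) / (deq / 2)),
            class = "shape_stats")
}

#' Physical scale of a processed image
#'
#' @param pixel_pitch_um camera pixel size in micrometres.
#' @param magnification objective magnification.
#' @param downsample_factor cumulative resize factor of the analyzed image.
#' @return A classed parameter list.
#' @export
scale_params <- function(pixel_pitch_um = 6.45, magnification = 40,
                         downsample_factor = 2L) {
  stopifnot(pixel_pitch_um > 0, magnification > 0, downsample_factor > 0)
  structure(list(pixel_pitch_um = pixel_pitch_um,
                 magnification = magnification,
                 downsample_factor = as.integer(downsample_factor)),
            class = "scale_params")
}

#' Convert a geodesic spine length from pixels to micrometres
#'
#' `length_um = length_px * downsample_factor * pixel_pitch_um /
#' magnification`; at the default scale (factor 2, 6.45 um pitch, x40) one
#' pixel of geodesic length corresponds to 0.3225 um.
#'
#' @param geodesic_length_px spine length in pixels (>= 0).
#' @param scale a [scale_params] object.
#' @return Length in micrometres.
#' @export
spine_length_um <- function(geodesic_length_px, scale = scale_params()) {
  stopifnot(all(geodesic_length_px >= 0))
  geodesic_length_px * scale$downsample_factor * scale$pixel_pitch_um /
    scale$magnification
}

#' Filter spines by elongation and build filament records
#'
#' Spines whose RRG (computed on the pruned spine pixel set) is at least
#' `rrg_threshold` are accepted as filaments; the rest are discarded as
#' debris from agglomerate edges. Accepted spines are converted to
#' physical length.
#'
#' @param spines list of `spine` objects.
#' @param rrg_threshold positive acceptance threshold (default 3.2, the
#'   ROC-optimal operating point).
#' @param scale a [scale_params] for the length conversion.
#' @param image_id identifier stored on each record.
#' @return List of `filament_record` objects.
#' @export
filter_by_rrg <- function(spines, rrg_threshold = 3.2,
                          scale = scale_params(), image_id = "image") {
  if (rrg_threshold <= 0) stop("rrg_threshold must be > 0")
  out <- list()
  for (sp in spines) {
    rrg <- compute_rrg(sp$path)$rrg
    if (rrg >= rrg_threshold) {
      out[[length(out) + 1L]] <- structure(
        list(spine = sp, rrg = rrg,
             length_um = spine_length_um(sp$geodesic_length_px, scale),
             image_id = image_id),
        class = "filament_record")
    }
  }
  out
}

#' @export
print.filament_record <- function(x, ...) {
  cat(sprintf("<filament_record> %s: %.2f um (%.2f px), RRG %.2f\n",
              x$image_id, x$length_um, x$spine$geodesic_length_px, x$rrg))
  invisible(x)
}

#' Total extended filament length
#'
#' Per image, the TEFL is the sum of the physical lengths of all accepted
#' filaments. Across a batch, the online TEFL (oTEFL) is the mean of the
#' per-image TEFLs.
#'
#' @param records list of `filament_record` objects (possibly from several
#'   images).
#' @param per_image if `TRUE`, return the named per-image TEFL vector; if
#'   `FALSE` (default), return their mean (0 when there are no records).
#' @return Named numeric vector (`per_image = TRUE`) or a single number.
#' @export
tefl <- function(records, per_image = FALSE) {
  if (length(records) == 0) {
    return(if (per_image) setNames(numeric(0), character(0)) else 0)
  }
  lens <- vapply(records, function(r) r$length_um, numeric(1L))
  ids <- vapply(records, function(r) as.character(r$image_id), character(1L))
  per <- tapply(lens, ids, sum)
  per <- setNames(as.numeric(per), names(per))
  if (per_image) per else mean(per)
}
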