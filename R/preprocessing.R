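#' Bicubic downsampling
#'
#' Resizes the image by an integer factor in both directions with the Keys
#' bicubic kernel (a = -0.5). When shrinking, the kernel support is widened
#' by the factor (antialiasing), so the operation doubles as a mild low-pass
#' filter. Output dimensions are the input dimensions integer-divided by the
#' factor; the image's `downsample_factor` metadata is multiplied
#' accordingly, keeping physical length conversion consistent.
#'
#' @param image a [gray_image].
#' @param factor integer resize factor (>= 1); 1 returns the input.
#' @param antialias widen the kernel when shrinking (default `TRUE`).
#' @return A [gray_image] of reduced size.
#' @export
downsample <- function(image, factor = 2L, antialias = TRUE) {
  stopifnot(inherits(image, "gray_image"))
  if (factor < 1) stop("resize factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  if (image$height_px < factor || image$width_px < factor)
    stop("image smaller than the resize factor")
  wr <- bicubic_weights(image$height_px, factor, antialias)
  wc <- bicubic_weights(image$width_px, factor, antialias)
  px <- clamp01(wr %*% image$pixels %*% t(wc))
  gray_image(px, pixel_pitch_um = image$pixel_pitch_um,
             magnification = image$magnification,
             downsample_factor = image$downsample_factor * factor)
}

# Keys cubic convolution kernel, a = -0.5
cubic_kernel <- function(s) {
  s <- abs(s)
  a <- -0.5
  ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
         ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
}

# dense (n_out x n_in) resampling matrix for one axis; reflect at edges
bicubic_weights <- function(n_in, factor, antialias) {
  n_out <- n_in %/% factor
  scale <- if (antialias) factor else 1
  support <- 2 * scale
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    x <- (i - 0.5) * factor + 0.5            # center in 1-based input coords
    lo <- floor(x - support); hi <- ceiling(x + support)
    s <- lo:hi
    w <- cubic_kernel((x - s) / scale)
    keep <- w != 0
    s <- s[keep]; w <- w[keep]
    # reflect out-of-range sample positions back inside
    s <- ifelse(s < 1, 2 - s, s)
    s <- ifelse(s > n_in, 2 * n_in - s, s)
    s <- pmin(pmax(s, 1), n_in)
    w <- w / sum(w)
    for (k in seq_along(s)) W[i, s[k]] <- W[i, s[k]] + w[k]
  }
  W
}

#' Gamma correction
#'
#' Raises every pixel of a `[0, 1]` image to the power `gamma`
#' (default 0.6). Exponents below 1 expand the dark range, giving a better
#' encoding of the faint transitions around thin objects.
#'
#' @param image a [gray_image].
#' @param gamma positive exponent.
#' @return A [gray_image].
#' @export
gamma_correct <- function(image, gamma = 0.6) {
  stopifnot(inherits(image, "gray_image"))
  if (gamma <= 0) stop("gamma must be > 0")
  out <- image
  out$pixels <- image$pixels^gamma
  out
}

#' Contrast enhancement: high-boost sharpening + top/bottom-hat
#'
#' Thin objects appear either darker (in focus) or brighter (off focus
#' towards the objective) than the background, so transitions must be
#' enhanced in both directions. Two stages: (1) high-boost sharpening, the
#' image plus `boost` times its high-pass residual (image minus its 3x3
#' local mean); (2) the image plus its grayscale top-hat (image minus
#' opening) minus its bottom-hat (closing minus image), both with a diamond
#' structuring element of radius `se_radius`. The result is clipped to
#' `[0, 1]`.
#'
#' @param image a [gray_image].
#' @param se_radius radius of the diamond structuring element (>= 1).
#' @param boost gain applied to the high-pass residual.
#' @return A [gray_image] with class `enhanced_image` prepended and a
#'   `provenance` field listing the applied stages.
#' @export
enhance_contrast <- function(image, se_radius = 3L, boost = 1.0) {
  stopifnot(inherits(image, "gray_image"))
  if (se_radius < 1) stop("se_radius must be >= 1")
  g <- image$pixels
  # stage 1: high boost (unsharp residual against the 3x3 mean)
  hp <- g - box_sum(g, 3L) / 9
  g <- g + boost * hp
  # stage 2: top-hat added, bottom-hat subtracted (diamond SE)
  se <- diamond_kernel(se_radius)
  top <- g - EBImage::opening(g, se)
  bot <- EBImage::closing(g, se) - g
  out <- image
  out$pixels <- clamp01(g + top - bot)
  out$provenance <- c("high_boost", "tophat_bottomhat")
  class(out) <- c("enhanced_image", class(image))
  out
}

# diamond (city-block ball) structuring element of the given radius
diamond_kernel <- function(radius) {
  n <- as.integer(radius)
  off <- seq.int(-n, n)
  d <- outer(abs(off), abs(off), "+")
  matrix(as.numeric(d <= n), 2L * n + 1L, 2L * n + 1L)
}
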