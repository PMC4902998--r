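#' Synthetic scene specification
#'
#' Parameters of the synthetic micrograph generator. The defaults emulate
#' the analyzed (factor-2 downsampled) frames of the in situ microscope: a
#' 520 x 696 px field, thin dark curvilinear filaments 2.5-5 px wide and
#' 31-620 px long (the expected 0.8-1.2 um diameters and 10-200 um lengths
#' at x40 with 6.45 um pixels), large irregular dark flocs, strongly
#' blurred low-contrast out-of-focus copies, and additive Gaussian noise on
#' a mid-gray background.
#'
#' @param image_size `(rows, cols)` of the scene.
#' @param n_filaments number of in-focus filaments.
#' @param filament_length_px_range,filament_width_px_range sampling ranges.
#' @param filament_contrast signed contrast against the background
#'   (negative = darker, as for in-focus objects).
#' @param curvature_sd standard deviation of the per-pixel heading change
#'   (rad); small values give the smooth, rarely-turning curves typical of
#'   filamentous bacteria.
#' @param n_flocs number of floc blobs.
#' @param floc_radius_px_range floc base-radius range.
#' @param floc_contrast signed floc contrast.
#' @param floc_texture_amp intensity s.d. of the grainy internal texture of
#'   flocs. Dense aggregates are strongly textured in bright field; this is
#'   what makes the variance transform mark floc bodies solid (a uniform
#'   disc would binarize as a hollow ring and escape the thickness filter).
#' @param floc_texture_sigma spatial correlation (px) of the floc texture.
#' @param n_blurred_objects number of out-of-focus objects (blurred
#'   filaments/flocs excluded from the ground-truth masks).
#' @param blur_sigma_px Gaussian blur sigma for out-of-focus rendering
#'   (>= 5 for convincingly defocused objects).
#' @param blur_attenuation contrast attenuation factor of blurred objects.
#' @param noise_sigma additive Gaussian noise sigma on the `[0,1]` scale;
#'   the default 0.005 is about 1.3 gray levels of an 8-bit sensor, the
#'   regime in which the default variance threshold separates the noise
#'   floor from in-focus transitions.
#' @param background_level background intensity in `[0, 1]`.
#' @param crossing force the first two filaments to cross.
#' @param touching_floc force the first floc to touch the first filament.
#' @param seed integer seed; the single source of randomness.
#' @return A classed list.
#' @export
scene_spec <- function(image_size = c(520L, 696L),
                       n_filaments = 5L,
                       filament_length_px_range = c(31, 620),
                       filament_width_px_range = c(2.5, 5.0),
                       filament_contrast = -0.25,
                       curvature_sd = 0.03,
                       n_flocs = 2L,
                       floc_radius_px_range = c(15, 60),
                       floc_contrast = -0.3,
                       floc_texture_amp = 0.08,
                       floc_texture_sigma = 1.5,
                       n_blurred_objects = 0L,
                       blur_sigma_px = 6,
                       blur_attenuation = 0.5,
                       noise_sigma = 0.005,
                       background_level = 0.55,
                       crossing = FALSE,
                       touching_floc = FALSE,
                       seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 64),
            n_filaments >= 0, n_flocs >= 0, n_blurred_objects >= 0,
            background_level >= 0, background_level <= 1)
  structure(as.list(environment()), class = "scene_spec")
}

# one bounded-curvature random curve: continuous points at unit spacing,
# grown from a midpoint in both directions
grow_curve <- function(mid, heading, length_px, curvature_sd, h, w, margin) {
  half <- function(theta, n) {
    pts <- matrix(NA_real_, n, 2L)
    p <- mid
    for (i in seq_len(n)) {
      theta <- theta + rnorm(1L, 0, curvature_sd)
      p <- p + c(sin(theta), cos(theta))
      if (p[1L] < margin || p[1L] > h - margin ||
          p[2L] < margin || p[2L] > w - margin) return(NULL)
      pts[i, ] <- p
    }
    pts
  }
  n1 <- floor(length_px / 2); n2 <- length_px - n1
  a <- half(heading, n1)
  b <- half(heading + pi, n2)
  if (is.null(a) || is.null(b)) return(NULL)
  rbind(a[rev(seq_len(nrow(a))), , drop = FALSE], matrix(mid, 1L), b)
}

# integer spine chain (0-based row/col, like spine paths) from a continuous
# curve in 1-based pixel coordinates: floor(x + .5) rounding keeps
# consecutive pixels 8-adjacent because curve points are at unit spacing
curve_to_chain <- function(pts) {
  px <- floor(pts + 0.5) - 1
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px <- px[keep, , drop = FALSE]
  storage.mode(px) <- "integer"
  colnames(px) <- c("row", "col")
  px
}

quasi_euclidean_length <- function(chain) {
  if (nrow(chain) < 2L) return(0)
  d <- abs(diff(chain))
  sum(ifelse(d[, 1L] > 0 & d[, 2L] > 0, sqrt(2), 1))
}

# stamp a tube of the given width around continuous curve points
stamp_tube <- function(mask, pts, width) {
  h <- nrow(mask); w <- ncol(mask)
  rad <- width / 2
  n <- ceiling(rad)
  for (k in seq_len(nrow(pts))) {
    y <- pts[k, 1L]; x <- pts[k, 2L]
    ri <- max(1L, floor(y - n)):min(h, ceiling(y + n))
    ci <- max(1L, floor(x - n)):min(w, ceiling(x + n))
    d2 <- outer((ri - y)^2, (ci - x)^2, "+")
    mask[ri, ci] <- mask[ri, ci] | (d2 <= rad^2)
  }
  mask
}

# irregular blob: radial Fourier perturbation of a disc
stamp_floc <- function(mask, center, radius, irregularity = 0.12) {
  h <- nrow(mask); w <- ncol(mask)
  amp <- runif(4L, 0, irregularity)
  pha <- runif(4L, 0, 2 * pi)
  rmax <- radius * (1 + sum(amp))
  ri <- max(1L, floor(center[1L] - rmax)):min(h, ceiling(center[1L] + rmax))
  ci <- max(1L, floor(center[2L] - rmax)):min(w, ceiling(center[2L] + rmax))
  dy <- ri - center[1L]; dx <- ci - center[2L]
  d <- sqrt(outer(dy^2, dx^2, "+"))
  th <- atan2(matrix(dy, length(dy), length(dx)),
              matrix(dx, length(dy), length(dx), byrow = TRUE))
  rb <- radius * (1 + Reduce(`+`, lapply(1:4, function(k)
    amp[k] * cos((k + 1) * th + pha[k]))))
  mask[ri, ci] <- mask[ri, ci] | (d <= rb)
  mask
}

#' Generate a synthetic micrograph with exact ground truth
#'
#' Renders the scene described by a [scene_spec]: in-focus filaments as
#' smooth bounded-curvature tubes (with their exact integer spine chains
#' and quasi-euclidean lengths recorded), flocs as irregular blobs,
#' out-of-focus objects as strongly blurred, contrast-attenuated copies
#' (excluded from the ground-truth masks), plus additive Gaussian noise.
#' The same seed always yields the identical scene; the caller's RNG state
#' is left untouched.
#'
#' @param spec a [scene_spec].
#' @return A list with `image` (a [gray_image] carrying
#'   `downsample_factor = 2`, i.e. already at the analyzed scale) and
#'   `truth`: `filament_mask`, `floc_mask`, `spines` (list of
#'   `path`/`geodesic_length_px`), and per-object `labels`
#'   (`"in_focus"` / `"out_of_focus"`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec, max_retries = 60L) {
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  filament_mask <- matrix(FALSE, h, w)
  floc_mask <- matrix(FALSE, h, w)
  occupied <- matrix(FALSE, h, w)
  spines <- list()
  labels <- character(0)
  margin <- 4

  place_filament <- function(forced_mid = NULL) {
    for (try in seq_len(max_retries)) {
      # resampled per attempt: a length that cannot fit at one heading may
      # fit at another, and small frames simply truncate the feasible range
      L <- round(runif(1L, spec$filament_length_px_range[1L],
                       spec$filament_length_px_range[2L]))
      width <- runif(1L, spec$filament_width_px_range[1L],
                     spec$filament_width_px_range[2L])
      mid <- if (is.null(forced_mid))
        c(runif(1L, h * 0.15, h * 0.85), runif(1L, w * 0.15, w * 0.85))
      else forced_mid
      pts <- grow_curve(mid, runif(1L, 0, 2 * pi), L, spec$curvature_sd,
                        h, w, margin)
      if (is.null(pts)) next
      tube <- stamp_tube(matrix(FALSE, h, w), pts, width)
      if (is.null(forced_mid) && any(tube & occupied)) next
      return(list(pts = pts, tube = tube, width = width))
    }
    stop("could not place a filament after ", max_retries, " retries; ",
         "the scene is too crowded for the requested objects")
  }
  place_floc <- function(forced_center = NULL) {
    for (try in seq_len(max_retries)) {
      R <- runif(1L, spec$floc_radius_px_range[1L],
                 spec$floc_radius_px_range[2L])
      if (2 * (R + margin) >= min(h, w)) next  # cannot fit in this frame
      ctr <- if (is.null(forced_center))
        c(runif(1L, R + margin, h - R - margin),
          runif(1L, R + margin, w - R - margin))
      else  # keep a forced (touching) floc inside the frame
        pmin(pmax(forced_center, margin + 10), c(h, w) - margin - 10)
      blob <- stamp_floc(matrix(FALSE, h, w), ctr, R)
      if (is.null(forced_center) && any(blob & occupied)) next
      return(blob)
    }
    stop("could not place a floc after ", max_retries, " retries; ",
         "the scene is too crowded for the requested objects")
  }

  # in-focus filaments
  filament_objs <- list()
  for (i in seq_len(spec$n_filaments)) {
    forced_mid <- NULL
    if (spec$crossing && i == 2L && length(filament_objs) >= 1L) {
      p1 <- filament_objs[[1L]]$pts
      forced_mid <- p1[round(nrow(p1) / 2), ]
    }
    f <- place_filament(forced_mid)
    filament_objs[[i]] <- f
    filament_mask <- filament_mask | f$tube
    occupied <- occupied | dilate_disc(f$tube, 3)
    chain <- curve_to_chain(f$pts)
    spines[[length(spines) + 1L]] <-
      list(path = chain, geodesic_length_px = quasi_euclidean_length(chain))
    labels <- c(labels, "in_focus")
  }

  # flocs
  for (i in seq_len(spec$n_flocs)) {
    forced_center <- NULL
    if (spec$touching_floc && i == 1L && length(filament_objs) >= 1L) {
      p1 <- filament_objs[[1L]]$pts
      endp <- p1[nrow(p1), ]
      R <- mean(spec$floc_radius_px_range)
      heading <- atan2(endp[1L] - p1[nrow(p1) - 5L, 1L],
                       endp[2L] - p1[nrow(p1) - 5L, 2L])
      forced_center <- endp + (R - 1) * c(sin(heading), cos(heading))
    }
    blob <- place_floc(forced_center)
    floc_mask <- floc_mask | blob
    occupied <- occupied | dilate_disc(blob, 3)
    labels <- c(labels, "in_focus")
  }

  field <- matrix(0, h, w)
  field <- field + spec$filament_contrast * filament_mask
  field <- field + spec$floc_contrast * floc_mask
  if (any(floc_mask) && spec$floc_texture_amp > 0) {
    # grainy internal structure of the aggregates
    tex <- as.matrix(EBImage::gblur(matrix(rnorm(h * w), h, w),
                                    sigma = spec$floc_texture_sigma))
    tex <- tex / stats::sd(tex) * spec$floc_texture_amp
    field[floc_mask] <- field[floc_mask] + tex[floc_mask]
  }

  # out-of-focus objects: blurred + attenuated, absent from the masks
  for (i in seq_len(spec$n_blurred_objects)) {
    layer <- matrix(0, h, w)
    if (i %% 2L == 1L) {
      f <- place_filament()
      layer[f$tube] <- spec$filament_contrast
      occupied <- occupied | dilate_disc(f$tube, 3)
    } else {
      blob <- place_floc()
      layer[blob] <- spec$floc_contrast
      occupied <- occupied | dilate_disc(blob, 3)
    }
    blurred <- as.matrix(EBImage::gblur(layer, sigma = spec$blur_sigma_px))
    field <- field + spec$blur_attenuation * blurred
    labels <- c(labels, "out_of_focus")
  }

  px <- spec$background_level + field +
    matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
  image <- gray_image(clamp01(px), downsample_factor = 2L)
  list(image = image,
       truth = list(filament_mask = filament_mask, floc_mask = floc_mask,
                    spines = spines, labels = labels))
}

#' Fixed battery of evaluation scenarios
#'
#' Five scenes covering the situations that make filament detection hard:
#' isolated filaments; crossing filaments; a filament touching a floc;
#' high floc density; and mixed focus (in-focus filaments next to strongly
#' blurred out-of-focus objects).
#'
#' @param seed integer seed; scene `i` uses `seed + i`.
#' @return Named list of five `list(image, truth)` scenes.
#' @export
scenario_suite <- function(seed = 1L) {
  specs <- list(
    isolated = scene_spec(n_filaments = 4L, n_flocs = 0L, seed = seed + 1L),
    crossing = scene_spec(n_filaments = 3L, n_flocs = 0L, crossing = TRUE,
                          filament_length_px_range = c(120, 400),
                          seed = seed + 2L),
    touching_floc = scene_spec(n_filaments = 3L, n_flocs = 2L,
                               touching_floc = TRUE, seed = seed + 3L),
    high_floc_density = scene_spec(n_filaments = 3L, n_flocs = 8L,
                                   floc_radius_px_range = c(15, 45),
                                   seed = seed + 4L),
    mixed_focus = scene_spec(n_filaments = 3L, n_flocs = 1L,
                             n_blurred_objects = 3L, seed = seed + 5L))
  lapply(specs, generate_scene)
}
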