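#' Grayscale micrograph container
#'
#' A `gray_image` is a 2-D intensity field normalized to `[0, 1]` together
#' with the optical metadata needed to convert pixel distances to
#' micrometres: the camera pixel pitch, the objective magnification, and the
#' cumulative downsampling factor applied so far.
#'
#' @param pixels numeric matrix with values in `[0, 1]` (rows = image rows).
#' @param pixel_pitch_um physical pixel size of the sensor in micrometres.
#' @param magnification objective magnification.
#' @param downsample_factor cumulative resize factor already applied
#'   (1 for a freshly loaded full-resolution frame).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, pixel_pitch_um = 6.45, magnification = 40,
                       downsample_factor = 1L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(pixels < -1e-9 | pixels > 1 + 1e-9, na.rm = TRUE))
    stop("intensities must lie in [0, 1]")
  structure(
    list(pixels = clamp01(pixels),
         height_px = nrow(pixels), width_px = ncol(pixels),
         pixel_pitch_um = pixel_pitch_um, magnification = magnification,
         downsample_factor = as.integer(downsample_factor)),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, pitch %.2f um, x%g, downsampled x%d\n",
              x$height_px, x$width_px, x$pixel_pitch_um, x$magnification,
              x$downsample_factor))
  cat(sprintf("  intensity range [%.4f, %.4f]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Load a micrograph as a normalized grayscale image
#'
#' Reads an 8-bit (or convertible) monochrome raster and scales it to
#' `[0, 1]` by the format maximum. PNG and TIFF are decoded with the png and
#' tiff packages; uncompressed 8-bit palette/24-bit BMP is supported
#' directly. Multi-channel input is converted by channel averaging with a
#' warning.
#'
#' @param path path to a PNG, TIFF or BMP file.
#' @param pixel_pitch_um,magnification optical metadata stored on the image.
#' @return A [gray_image].
#' @export
load_gray_image <- function(path, pixel_pitch_um = 6.45, magnification = 40) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    bmp = read_bmp(path),
    stop("unsupported image format: .", ext))
  if (length(dim(px)) == 3L) {
    warning("multi-channel input converted to grayscale by channel average")
    px <- apply(px[, , seq_len(min(3L, dim(px)[3L])), drop = FALSE],
                c(1L, 2L), mean)
  }
  gray_image(px, pixel_pitch_um = pixel_pitch_um,
             magnification = magnification, downsample_factor = 1L)
}

#' Load a binary mask image
#'
#' Reads an annotator/reference mask (PNG or TIFF): pixels above 0.5 of the
#' format maximum are object.
#'
#' @param path path to a PNG or TIFF file.
#' @return A logical matrix.
#' @export
load_mask <- function(path) {
  img <- load_gray_image(path)
  img$pixels > 0.5
}

# minimal reader for uncompressed BMP (8-bit grayscale palette or 24-bit),
# returning intensities in [0, 1]
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * 256^(0:1))
  off   <- u32(11L)
  w     <- u32(19L)
  h     <- u32(23L)
  bpp   <- u16(29L)
  compr <- u32(31L)
  if (compr != 0) stop("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L)) stop("only 8-bit and 24-bit BMP supported")
  bytes_pp <- bpp %/% 8L
  stride <- ((w * bytes_pp + 3L) %/% 4L) * 4L
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    # BMP rows are stored bottom-up
    start <- off + (r - 1L) * stride
    row <- as.integer(raw[start + seq_len(w * bytes_pp)])
    if (bpp == 8L) v <- row
    else v <- colMeans(matrix(row, nrow = 3L))
    out[h - r + 1L, ] <- v
  }
  if (bpp == 8L) {
    # map through the palette (assume grayscale palette; use first channel)
    pal_n <- (off - 54L) %/% 4L
    if (pal_n > 0) {
      pal <- as.integer(raw[54L + seq_len(pal_n * 4L)])
      blue <- pal[seq(1L, pal_n * 4L, by = 4L)]
      out <- matrix(blue[out + 1L], nrow(out), ncol(out))
    }
  }
  out / 255
}

#' Pipeline configuration
#'
#' All tunable thresholds of the detection pipeline in one place. The
#' defaults are the ROC-optimal operating point (variance threshold
#' 10.5e-4, distance threshold 6.4, RRG threshold 3.2) together with the
#' size rules derived from the smallest expected filament (0.8 um diameter,
#' 10 um length at x40, 6.45 um pixels, factor-2 downsampling: 2.5 px wide,
#' 31 px long, 77 px minimum area).
#'
#' @param gamma exponent of the gamma correction (> 0).
#' @param se_radius radius of the diamond structuring element for the
#'   top/bottom-hat enhancement.
#' @param boost gain of the high-boost sharpening stage.
#' @param variance_threshold binarization threshold on the 3x3 local
#'   variance of `[0,1]` intensities; defines the in-focus sample volume.
#' @param distance_threshold Euclidean distance-map threshold separating
#'   thick flocs from thin filaments (px).
#' @param rrg_threshold minimum reduced radius of gyration of a spine to be
#'   accepted as a filament.
#' @param min_area_px connected components smaller than this are removed.
#' @param min_filament_len_px minimum expected filament length (px); also
#'   the cutoff for reprocessing skeleton branches.
#' @param max_hole_diameter_px only enclosed holes with equivalent diameter
#'   below this are filled.
#' @param eval_dilation_radius_px disc radius used when matching detections
#'   against reference markings.
#' @param resize_factor bicubic downsampling factor applied by
#'   [process_image()] before any other stage.
#' @param variance_window side of the local-variance window (odd).
#' @param variance_sample use the sample (n-1) instead of the population (n)
#'   normalization for the local variance.
#' @param floc_dilation_radius disc radius used to reconstruct floc extent
#'   after distance filtering; `NULL` means equal to `distance_threshold`.
#' @return A classed list of parameters.
#' @export
pipeline_config <- function(gamma = 0.6, se_radius = 3L, boost = 1.0,
                            variance_threshold = 10.5e-4,
                            distance_threshold = 6.4,
                            rrg_threshold = 3.2,
                            min_area_px = 77L,
                            min_filament_len_px = 31L,
                            max_hole_diameter_px = 2.5,
                            eval_dilation_radius_px = 3L,
                            resize_factor = 2L,
                            variance_window = 3L,
                            variance_sample = FALSE,
                            floc_dilation_radius = NULL) {
  stopifnot(gamma > 0, se_radius >= 1, variance_threshold > 0,
            distance_threshold > 0, rrg_threshold > 0, min_area_px >= 1,
            min_filament_len_px >= 1, max_hole_diameter_px > 0,
            eval_dilation_radius_px >= 0, resize_factor >= 1,
            variance_window %% 2 == 1)
  structure(list(
    gamma = gamma, se_radius = as.integer(se_radius), boost = boost,
    variance_threshold = variance_threshold,
    distance_threshold = distance_threshold,
    rrg_threshold = rrg_threshold,
    min_area_px = as.integer(min_area_px),
    min_filament_len_px = as.integer(min_filament_len_px),
    max_hole_diameter_px = max_hole_diameter_px,
    eval_dilation_radius_px = as.integer(eval_dilation_radius_px),
    resize_factor = as.integer(resize_factor),
    variance_window = as.integer(variance_window),
    variance_sample = isTRUE(variance_sample),
    floc_dilation_radius = floc_dilation_radius),
    class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(x[[nm]])) "= distance_threshold"
                else format(x[[nm]])))
  invisible(x)
}

#' Write filament records and per-image summaries to CSV
#'
#' One `filament` row per detected filament (image id, spine pixel count,
#' geodesic length in px, RRG, physical length in um) followed by one
#' `image_summary` row per image with the filament count and the TEFL
#' (total extended filament length, the sum of the per-filament lengths).
#'
#' @param records list of filament records from [process_image()].
#' @param path output CSV path (UTF-8, header row, '.' decimal separator).
#' @return The written data frame, invisibly.
#' @export
write_filament_csv <- function(records, path) {
  df <- records_to_df(records)
  img_ids <- unique(df$image_id[df$record_type == "filament"])
  summaries <- lapply(img_ids, function(id) {
    rows <- df[df$record_type == "filament" & df$image_id == id, ]
    data.frame(image_id = id, record_type = "image_summary",
               filament_id = NA_integer_, spine_px = NA_integer_,
               geodesic_length_px = NA_real_, rrg = NA_real_,
               length_um = NA_real_, n_filaments = nrow(rows),
               tefl_um = sum(rows$length_um), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(df), summaries))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write CSV to: ", path)
  invisible(out)
}

records_to_df <- function(records) {
  base <- data.frame(image_id = character(), record_type = character(),
                     filament_id = integer(), spine_px = integer(),
                     geodesic_length_px = numeric(), rrg = numeric(),
                     length_um = numeric(), n_filaments = integer(),
                     tefl_um = numeric(), stringsAsFactors = FALSE)
  if (length(records) == 0) return(base)
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(image_id = as.character(r$image_id),
               record_type = "filament", filament_id = i,
               spine_px = nrow(r$spine$path),
               geodesic_length_px = r$spine$geodesic_length_px,
               rrg = r$rrg, length_um = r$length_um,
               n_filaments = NA_integer_, tefl_um = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
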