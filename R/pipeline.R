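# shared preprocessing stages: resize -> gamma -> contrast enhancement
preprocess_stage <- function(image, config) {
  resized <- downsample(image, config$resize_factor)
  gam <- gamma_correct(resized, config$gamma)
  enhanced <- enhance_contrast(gam, config$se_radius, config$boost)
  list(resized = resized, gamma = gam, enhanced = enhanced)
}

#' Run the full detection pipeline on one image
#'
#' Executes, in fixed order: bicubic downsampling, gamma correction,
#' high-boost + top/bottom-hat enhancement, local-variance binarization,
#' small-object removal, restricted hole filling, distance-map floc
#' removal, skeletonization with geodesic spine pruning (including
#' reprocessing of long branches), RRG debris filtering, and conversion of
#' the accepted spine lengths to micrometres.
#'
#' @param image a [gray_image].
#' @param config a [pipeline_config].
#' @param image_id identifier attached to the records.
#' @param trace keep all intermediate stage outputs (default `TRUE`).
#' @return A list with `records` (list of `filament_record`), `tefl_um`
#'   (their summed length) and, when requested, `trace`: the per-stage
#'   intermediates (`resized`, `gamma`, `enhanced`, `varmap`, `binary`,
#'   `cleaned`, `distmap`, `floc_mask`, `thin_mask`, `spines`) with
#'   per-stage timings in `timing_s`.
#' @export
process_image <- function(image, config = pipeline_config(),
                          image_id = "image", trace = TRUE) {
  stopifnot(inherits(image, "gray_image"), inherits(config, "pipeline_config"))
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  pre <- preprocess_stage(image, config)
  timing["preprocess"] <- tic() - t0

  t0 <- tic()
  varmap <- variance_transform(pre$enhanced, config$variance_window,
                               config$variance_sample)
  binary <- binarize(varmap, config$variance_threshold)
  cleaned <- fill_small_holes(remove_small_objects(binary, config$min_area_px),
                              config$max_hole_diameter_px)
  timing["binarize"] <- tic() - t0

  t0 <- tic()
  if (any(cleaned)) {
    dm <- euclidean_distance_map(cleaned)
    dil <- if (is.null(config$floc_dilation_radius)) config$distance_threshold
           else config$floc_dilation_radius
    floc <- extract_floc_mask(dm, config$distance_threshold, dil)
    thin_mask <- remove_flocs(cleaned, floc)
  } else {
    dm <- matrix(0, nrow(cleaned), ncol(cleaned))
    floc <- cleaned
    thin_mask <- cleaned
  }
  timing["floc_removal"] <- tic() - t0

  t0 <- tic()
  spines <- extract_spines(thin_mask, config$min_filament_len_px)
  timing["spines"] <- tic() - t0

  t0 <- tic()
  scale <- scale_params(image$pixel_pitch_um, image$magnification,
                        pre$resized$downsample_factor)
  records <- filter_by_rrg(spines, config$rrg_threshold, scale, image_id)
  timing["classify"] <- tic() - t0

  out <- list(records = records,
              tefl_um = sum(vapply(records, `[[`, numeric(1L), "length_um")))
  if (trace)
    out$trace <- list(resized = pre$resized, gamma = pre$gamma,
                      enhanced = pre$enhanced, varmap = varmap,
                      binary = binary, cleaned = cleaned, distmap = dm,
                      floc_mask = floc, thin_mask = thin_mask,
                      spines = spines, timing_s = timing)
  out
}

#' Process a batch of micrographs
#'
#' Runs [process_image()] over a set of image files (or in-memory images)
#' and summarizes: per-image filament count and TEFL, plus the batch mean
#' TEFL (the online TEFL, oTEFL). Unreadable files are skipped with a
#' warning and reported in the summary.
#'
#' @param paths character vector of image paths, or a list of
#'   [gray_image] objects.
#' @param config a [pipeline_config].
#' @return A list with `records` (all filament records), `summary` (data
#'   frame: image_id, n_filaments, tefl_um), `otefl_um`, and `skipped`.
#' @export
process_batch <- function(paths, config = pipeline_config()) {
  if (length(paths) == 0) stop("no images to process")
  records <- list()
  summaries <- list()
  skipped <- character(0)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (is.character(p)) {
      id <- basename(p)
      img <- tryCatch(load_gray_image(p), error = function(e) {
        warning("skipping unreadable image: ", p)
        NULL
      })
      if (is.null(img)) { skipped <- c(skipped, p); next }
    } else {
      id <- if (!is.null(names(paths)[i]) && nzchar(names(paths)[i]))
        names(paths)[i] else sprintf("image%03d", i)
      img <- p
    }
    res <- process_image(img, config, image_id = id, trace = FALSE)
    records <- c(records, res$records)
    summaries[[length(summaries) + 1L]] <- data.frame(
      image_id = id, n_filaments = length(res$records),
      tefl_um = res$tefl_um, stringsAsFactors = FALSE)
  }
  if (length(summaries) == 0) stop("no readable images in batch")
  summary <- do.call(rbind, summaries)
  list(records = records, summary = summary,
       otefl_um = mean(summary$tefl_um), skipped = skipped)
}
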