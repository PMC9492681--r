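#' Flask-bottom photograph with calibration metadata
#'
#' @param pixels numeric array, `H x W x 3` (RGB, intensities in `[0, 1]`
#'   or raw 8/16-bit counts) or `H x W` for a single channel.
#' @param flask_inner_diameter_cm inner flask diameter in cm, the length
#'   reference for pixel calibration.
#' @param calibration_circle optional numeric `c(row, col, radius_px)` of
#'   the flask rim circle in pixel coordinates (origin top-left,
#'   row-major).
#' @return An object of class `flask_image`.
#' @export
flask_image <- function(pixels, flask_inner_diameter_cm,
                        calibration_circle = NULL) {
  d <- dim(pixels)
  if (is.null(d) || length(d) < 2 || d[1] < 16 || d[2] < 16)
    stop("pixels must be at least 16 x 16")
  if (!is.numeric(flask_inner_diameter_cm) || flask_inner_diameter_cm <= 0)
    stop("flask_inner_diameter_cm must be positive")
  if (!is.null(calibration_circle)) {
    cc <- calibration_circle
    if (length(cc) != 3 || cc[3] <= 0 ||
        cc[1] < 1 || cc[1] > d[1] || cc[2] < 1 || cc[2] > d[2])
      stop("calibration_circle must be c(row, col, radius_px) inside the image")
  }
  structure(list(pixels = pixels,
                 flask_inner_diameter_cm = flask_inner_diameter_cm,
                 calibration_circle = calibration_circle),
            class = "flask_image")
}

#' Read a flask-bottom photograph from PNG/TIFF
#'
#' @param path image path (8- or 16-bit PNG or TIFF).
#' @inheritParams flask_image
#' @return A [flask_image()] with intensities in `[0, 1]` (EBImage
#'   convention), array layout `H x W x channels`, origin top-left.
#' @export
read_flask_image <- function(path, flask_inner_diameter_cm,
                             calibration_circle = NULL) {
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  # EBImage stores (x, y[, c]); transpose to row-major (row, col[, c])
  px <- if (length(dim(px)) == 2) t(px) else aperm(px, c(2, 1, 3))
  flask_image(px, flask_inner_diameter_cm, calibration_circle)
}

#' Extract the blue channel used for segmentation
#'
#' Material contrasts best against the flask background in the blue
#' channel, which is the only channel the segmentation consumes.
#'
#' @param img a [flask_image()] or a raw `H x W x 3` array.
#' @return `H x W` numeric matrix (dtype preserving).  A single-channel
#'   input is passed through with a warning.
#' @export
extract_blue_channel <- function(img) {
  px <- if (inherits(img, "flask_image")) img$pixels else img
  if (length(dim(px)) == 2) {
    warning("single-channel image: passing through unchanged")
    return(px)
  }
  if (dim(px)[3] < 3) stop("expected an RGB image with 3 channels")
  px[, , 3]
}

#' Segmentation parameters for the material size pipeline
#'
#' Stage 1 separates foreground from background by a global threshold on
#' the (optionally Gaussian-smoothed) blue channel; stage 2 splits the
#' connected foreground objects into bundled (large, connected pieces) and
#' scattered (small unassociated aggregates) by an area rule.
#'
#' @param smooth_sigma Gaussian smoothing sigma in px before thresholding.
#'   0 (default) disables smoothing; raise it for noisy photographs.
#' @param threshold `"otsu"` for an automatic bimodal threshold or
#'   `"fixed"`.
#' @param fixed_threshold threshold used when `threshold = "fixed"`.
#' @param min_object_px objects smaller than this are discarded as pixel
#'   noise.
#' @param min_bundle_area_px objects at or above this area (px) are
#'   classed bundled, smaller ones scattered.
#' @param min_bundle_area_cm2 optional area threshold in cm^2; overrides
#'   `min_bundle_area_px` when a pixel scale is available.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma = 0, threshold = c("otsu", "fixed"),
                       fixed_threshold = 0.5, min_object_px = 2,
                       min_bundle_area_px = 200, min_bundle_area_cm2 = NULL) {
  threshold <- match.arg(threshold)
  stopifnot(smooth_sigma >= 0, min_object_px >= 0, min_bundle_area_px > 0)
  structure(list(smooth_sigma = smooth_sigma, threshold = threshold,
                 fixed_threshold = fixed_threshold,
                 min_object_px = min_object_px,
                 min_bundle_area_px = min_bundle_area_px,
                 min_bundle_area_cm2 = min_bundle_area_cm2),
            class = "seg_params")
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a small union-find over
# label ids.
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Two-stage segmentation of material in a blue-channel image
#'
#' Stage 1: optional Gaussian smoothing followed by a global threshold
#' (automatic Otsu by default) gives the foreground mask.  Stage 2:
#' 8-connected components; each object is classed `bundled` if its area
#' reaches the bundle threshold, otherwise `scattered`.  Objects touching
#' the image border are kept (flask rims crop material arbitrarily).
#'
#' @param blue `H x W` numeric matrix (blue channel).
#' @param params a [seg_params()].
#' @param pixel_scale_cm_per_px optional calibration from
#'   [calibrate_pixels()]; adds calibrated areas in cm^2.
#' @return An object of class `segmentation_result`: `label_mask` (`H x W`
#'   integer, 0 = background), `object_table` (data.frame with `label`,
#'   `class`, `area_px`, `area_cm2`), `threshold`, `discarded_px` (pixels
#'   dropped as sub-`min_object_px` noise) and `background_px`.
#' @export
segment_material <- function(blue, params = seg_params(),
                             pixel_scale_cm_per_px = NA_real_) {
  if (length(dim(blue)) != 2) stop("blue must be a 2-D intensity matrix")
  b <- blue
  if (max(b) > 1) b <- b / if (max(b) <= 255) 255 else 65535
  if (params$smooth_sigma > 0)
    b <- EBImage::imageData(EBImage::gblur(EBImage::Image(b),
                                           sigma = params$smooth_sigma))
  thr <- if (params$threshold == "fixed") params$fixed_threshold
         else if (diff(range(b)) < 1e-10) Inf  # flat image: no foreground
         else EBImage::otsu(EBImage::Image(b))
  mask <- b > thr
  lab <- .label8(mask)
  areas <- tabulate(lab[lab > 0])
  discarded_px <- 0L
  if (any(areas < params$min_object_px)) {
    small <- which(areas < params$min_object_px)
    discarded_px <- sum(areas[small])
    lab[lab %in% small] <- 0L
    keep <- setdiff(seq_along(areas), small)
    lab[lab > 0] <- match(lab[lab > 0], keep)
    areas <- areas[keep]
  }
  scale2 <- pixel_scale_cm_per_px^2
  bundle_px <- params$min_bundle_area_px
  if (!is.null(params$min_bundle_area_cm2) && is.finite(scale2))
    bundle_px <- params$min_bundle_area_cm2 / scale2
  tab <- data.frame(
    label = seq_along(areas),
    class = ifelse(areas >= bundle_px, "bundled", "scattered"),
    area_px = areas,
    area_cm2 = areas * scale2)
  structure(list(label_mask = lab, object_table = tab, threshold = thr,
                 discarded_px = discarded_px,
                 background_px = length(blue) - sum(areas) - discarded_px,
                 pixel_scale_cm_per_px = pixel_scale_cm_per_px,
                 params = params),
            class = "segmentation_result")
}

#' Pixel-to-centimetre calibration from the flask rim circle
#'
#' The known inner flask diameter spans the calibration circle, giving
#' `scale = diameter_cm / (2 * radius_px)` in cm per pixel; areas convert
#' by `scale^2`.  The circle is supplied manually as image metadata — it
#' is never guessed.
#'
#' @param img a [flask_image()].
#' @param explicit_scale optional cm-per-px scale overriding the circle.
#' @return cm-per-pixel scale (scalar).
#' @export
calibrate_pixels <- function(img, explicit_scale = NULL) {
  if (!is.null(explicit_scale)) {
    stopifnot(is.numeric(explicit_scale), explicit_scale > 0)
    return(explicit_scale)
  }
  if (is.null(img$calibration_circle))
    stop("no calibration circle and no explicit scale: cannot calibrate")
  img$flask_inner_diameter_cm / (2 * img$calibration_circle[3])
}

#' Mean of the top tail of a size distribution
#'
#' Computes the `prob` percentile of `x` (linear-interpolation percentile,
#' `stats::quantile` type 7) and returns the mean of all values at or
#' above that threshold.
#'
#' @param x numeric vector of sizes (non-empty).
#' @param prob percentile defining the tail (default 0.95, i.e. the top
#'   five percentile).
#' @return List with `threshold`, `mean` and `n_tail`.
#' @examples
#' top_tail_mean(1:100)   # threshold 95.05, mean 98
#' @export
top_tail_mean <- function(x, prob = 0.95) {
  stopifnot(length(x) > 0, all(is.finite(x)))
  thr <- unname(stats::quantile(x, prob, type = 7))
  tail <- x[x >= thr]
  list(threshold = thr, mean = mean(tail), n_tail = length(tail))
}

#' Representative material size of one image
#'
#' Summarises the bundled objects of a segmentation as the mean of the
#' top-five-percentile piece areas.  Only bundled pieces count as
#' "material"; scattered debris is excluded.
#'
#' @param seg a [segment_material()] result.
#' @return An object of class `size_summary`: `representative_size_cm2`,
#'   `n_bundled_objects`, `percentile_threshold_cm2`,
#'   `pixel_scale_cm_per_px` and `empty` (`TRUE` when no bundled object
#'   was found, in which case sizes are 0 by convention).  When the
#'   segmentation is uncalibrated the `*_cm2` fields hold px^2 values and
#'   `pixel_scale_cm_per_px` is `NA`.
#' @export
representative_size <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  tab <- seg$object_table[seg$object_table$class == "bundled", ]
  scale <- seg$pixel_scale_cm_per_px
  if (nrow(tab) == 0) {
    return(structure(list(representative_size_cm2 = 0,
                          n_bundled_objects = 0L,
                          percentile_threshold_cm2 = 0,
                          pixel_scale_cm_per_px = scale, empty = TRUE),
                     class = "size_summary"))
  }
  areas <- if (all(is.finite(tab$area_cm2))) tab$area_cm2 else tab$area_px
  tt <- top_tail_mean(areas, 0.95)
  structure(list(representative_size_cm2 = tt$mean,
                 n_bundled_objects = nrow(tab),
                 percentile_threshold_cm2 = tt$threshold,
                 pixel_scale_cm_per_px = scale, empty = FALSE),
            class = "size_summary")
}

#' Full size pipeline for a single flask image
#'
#' Blue-channel extraction, calibration, segmentation and top-tail
#' summary in one call.
#'
#' @param img a [flask_image()].
#' @param params a [seg_params()].
#' @param explicit_scale optional cm-per-px override for calibration.
#' @return A list with `summary` ([representative_size()] output) and
#'   `segmentation` (the full [segment_material()] result).
#' @export
size_pipeline <- function(img, params = seg_params(), explicit_scale = NULL) {
  scale <- calibrate_pixels(img, explicit_scale)
  seg <- segment_material(extract_blue_channel(img), params, scale)
  list(summary = representative_size(seg), segmentation = seg)
}

#' Batch size measurement over many flask images
#'
#' Runs [size_pipeline()] per image; per-image failures are recorded in
#' the output and do not abort the batch.  When `groups` is supplied the
#' per-condition mean representative size is also returned.
#'
#' @param images list of [flask_image()].
#' @param params a [seg_params()].
#' @param groups optional character/factor vector, one entry per image.
#' @return List with `per_image` (data.frame: `image`, `group`,
#'   `representative_size_cm2`, `n_bundled_objects`,
#'   `percentile_threshold_cm2`, `error`) and `per_group` (data.frame of
#'   group means, or `NULL` when no groups given).
#' @export
batch_size_measure <- function(images, params = seg_params(), groups = NULL) {
  stopifnot(length(images) >= 1)
  if (!is.null(groups)) stopifnot(length(groups) == length(images))
  rows <- lapply(seq_along(images), function(i) {
    res <- tryCatch(size_pipeline(images[[i]], params)$summary,
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(image = i, representative_size_cm2 = NA_real_,
                 n_bundled_objects = NA_integer_,
                 percentile_threshold_cm2 = NA_real_,
                 error = conditionMessage(res))
    } else {
      data.frame(image = i,
                 representative_size_cm2 = res$representative_size_cm2,
                 n_bundled_objects = res$n_bundled_objects,
                 percentile_threshold_cm2 = res$percentile_threshold_cm2,
                 error = NA_character_)
    }
  })
  per_image <- do.call(rbind, rows)
  per_image$group <- if (is.null(groups)) NA_character_ else as.character(groups)
  per_group <- NULL
  if (!is.null(groups)) {
    ok <- is.na(per_image$error)
    per_group <- stats::aggregate(
      representative_size_cm2 ~ group, data = per_image[ok, ], FUN = mean)
    names(per_group)[2] <- "mean_size_cm2"
    per_group$n_images <- as.vector(table(per_image$group[ok])[per_group$group])
  }
  list(per_image = per_image, per_group = per_group)
}
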