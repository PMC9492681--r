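# Seeded generators for every pipeline stage.  Each generator returns the
# synthetic input together with an exact ground-truth sidecar (areas are
# counted on the rasterised masks, never taken from the analytic shapes),
# so downstream errors are attributable to the pipeline, not the fixture.

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a condition-size table with a planted unimodal response
#'
#' Draws shake-flask conditions spanning a planted log-Gaussian size
#' response and simulates noisy size measurements.  In the default
#' `"pva"` mode the conditions are placed on an even grid of log10 P_V,A
#' values spanning `peak +/- span_widths * width` (flask diameter and fill
#' volume drawn at random, shaking frequency solved by the inverse model),
#' so the planted peak is exact and recoverable.  In `"kla"` or `"power"`
#' mode conditions are drawn at random and the response is planted on the
#' realised log10 kLa or log10 P/V_L values (peak at their midrange),
#' which deliberately decouples the response from P_V,A.
#'
#' @param n_conditions number of distinct conditions.
#' @param n_replicates replicate size measurements per condition.
#' @param diameters flask inner diameters (m) to draw from.
#' @param orbit_diameter shaker orbit diameter, m.
#' @param volume_range_mL fill-volume range to draw from, mL.
#' @param peak_log10_pva,width planted peak location and width of the
#'   response in log10 predictor units.
#' @param amplitude_cm2,baseline_cm2 planted response amplitude and
#'   baseline, cm^2.
#' @param noise_sd_fraction measurement noise SD as a fraction of the
#'   amplitude.
#' @param span_widths half-span of the condition grid in units of `width`.
#' @param response_predictor which predictor the response is planted on.
#' @param medium a [medium_properties()].
#' @param seed integer seed; identical seed and config give identical
#'   output.
#' @return List with `records` (data.frame ready for [annotate_pva()]:
#'   condition columns, `replicate`, `size_cm2`) and `truth` (planted
#'   parameters, per-condition true predictor and noiseless mean size).
#' @export
gen_condition_table <- function(n_conditions = 30, n_replicates = 3,
                                diameters = c(0.065, 0.085, 0.105),
                                orbit_diameter = 0.05,
                                volume_range_mL = c(40, 160),
                                peak_log10_pva = log10(1.09), width = 0.153,
                                amplitude_cm2 = 6, baseline_cm2 = 0.5,
                                noise_sd_fraction = 0.1, span_widths = 2.5,
                                response_predictor = c("pva", "kla", "power"),
                                medium = medium_properties(), seed = 1) {
  response_predictor <- match.arg(response_predictor)
  stopifnot(n_conditions >= 2, n_replicates >= 1, noise_sd_fraction >= 0)
  .with_seed(seed, {
    if (response_predictor == "pva") {
      u <- seq(peak_log10_pva - span_widths * width,
               peak_log10_pva + span_widths * width,
               length.out = n_conditions)
      conds <- lapply(u, function(ui) {
        for (try in 1:50) {
          d <- sample(diameters, 1)
          v_mL <- stats::runif(1, volume_range_mL[1], volume_range_mL[2])
          sol <- solve_frequency(vessel_geometry(d, orbit_diameter),
                                 fill_volume_m3 = v_mL * 1e-6,
                                 target_pva_milli = 10^ui,
                                 medium = medium, bracket = c(0.02, 25))
          if (sol$converged)
            return(list(d = d, v_mL = v_mL, rpm = sol$value * 60))
        }
        stop("could not realise target P_V,A = ", 10^ui, " mW m^2/s")
      })
      peak <- peak_log10_pva
    } else {
      d <- sample(diameters, n_conditions, replace = TRUE)
      v_mL <- stats::runif(n_conditions, volume_range_mL[1], volume_range_mL[2])
      n_s <- stats::runif(n_conditions, 1, 8)
      conds <- Map(function(di, vi, ni) list(d = di, v_mL = vi, rpm = ni * 60),
                   d, v_mL, n_s)
      pred <- vapply(conds, function(cc) {
        cond <- culture_conditions(vessel_geometry(cc$d, orbit_diameter),
                                   fill_volume_mL = cc$v_mL,
                                   shaking_rpm = cc$rpm)
        h <- modified_volumetric_power(cond, medium)
        if (response_predictor == "kla") h$kla else h$power_per_volume
      }, numeric(1))
      u <- log10(pred)
      peak <- mean(range(u))
      width <- max(diff(range(u)) / (2 * span_widths), 0.05)
    }
    mean_size <- amplitude_cm2 *
      exp(-(u - peak)^2 / (2 * width^2)) + baseline_cm2
    rows <- lapply(seq_len(n_conditions), function(i) {
      sz <- pmax(0, mean_size[i] +
                   stats::rnorm(n_replicates, 0,
                                noise_sd_fraction * amplitude_cm2))
      data.frame(label = sprintf("cond_%02d", i),
                 flask_inner_diameter_m = conds[[i]]$d,
                 orbit_diameter_m = orbit_diameter,
                 fill_volume_mL = conds[[i]]$v_mL,
                 shaking_rpm = conds[[i]]$rpm,
                 replicate = seq_len(n_replicates),
                 size_cm2 = sz)
    })
    list(records = do.call(rbind, rows),
         truth = list(response_predictor = response_predictor,
                      peak_log10 = peak, width = width,
                      amplitude_cm2 = amplitude_cm2,
                      baseline_cm2 = baseline_cm2,
                      noise_sd_fraction = noise_sd_fraction,
                      log10_predictor = u, mean_size_cm2 = mean_size))
  })
}

# Rasterise a filled disk into logical matrix coordinates.
.disk_pixels <- function(h, w, row, col, radius) {
  r0 <- max(1, floor(row - radius)); r1 <- min(h, ceiling(row + radius))
  c0 <- max(1, floor(col - radius)); c1 <- min(w, ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  which(d2 <= radius^2, arr.ind = TRUE) +
    matrix(c(r0 - 1L, c0 - 1L), nrow = sum(d2 <= radius^2), ncol = 2,
           byrow = TRUE)
}

#' Generate a synthetic flask-bottom photograph with planted objects
#'
#' Renders an RGB image emulating a photographed flask bottom: a smooth
#' background gradient, a calibration (rim) circle, `n_bundled` large
#' material disks and `n_scattered` small debris specks, all
#' non-overlapping.  The rim reflection is drawn in the red and green
#' channels only, so the blue segmentation channel carries nothing but
#' material and background; calibration uses the circle metadata, never
#' the rendered ring.
#'
#' @param height,width image size, px.
#' @param n_bundled,n_scattered planted object counts.
#' @param bundled_radius_px,scattered_radius_px radius ranges (px) the two
#'   classes are drawn from.
#' @param background,gradient background level and left-to-right gradient
#'   amplitude (intensities in `[0, 1]`).
#' @param foreground blue-channel intensity of material pixels.
#' @param circle_radius_px calibration circle radius, px.
#' @param flask_inner_diameter_cm nominal flask diameter for calibration.
#' @param noise_sd optional Gaussian pixel noise SD (0 disables).
#' @param seed integer seed.
#' @return List with `image` (a [flask_image()]) and `truth`: `objects`
#'   (data.frame `id`, `class`, `row`, `col`, `radius_px`, `area_px` with
#'   areas counted on the rasterised mask), `label_mask`, and
#'   `scale_cm_per_px`.
#' @export
gen_flask_image <- function(height = 512, width = 512, n_bundled = 5,
                            n_scattered = 50,
                            bundled_radius_px = c(15, 30),
                            scattered_radius_px = c(1, 3),
                            background = 0.08, gradient = 0.08,
                            foreground = 0.85, circle_radius_px = 220,
                            flask_inner_diameter_cm = 8.5, noise_sd = 0,
                            seed = 1) {
  stopifnot(n_bundled >= 0, n_scattered >= 0, foreground > background + gradient)
  .with_seed(seed, {
    h <- height; w <- width
    ctr <- c(h / 2, w / 2)
    place_r <- circle_radius_px * 0.88
    n_total <- n_bundled + n_scattered
    radii <- c(stats::runif(n_bundled, bundled_radius_px[1], bundled_radius_px[2]),
               stats::runif(n_scattered, scattered_radius_px[1],
                            scattered_radius_px[2]))
    centers <- matrix(NA_real_, n_total, 2)
    for (i in seq_len(n_total)) {
      placed <- FALSE
      for (try in 1:5000) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * (place_r - radii[i] - 2)
        cand <- ctr + rad * c(cos(ang), sin(ang))
        ok <- TRUE
        if (i > 1) {
          prev <- seq_len(i - 1)
          ok <- all(sqrt((centers[prev, 1] - cand[1])^2 +
                           (centers[prev, 2] - cand[2])^2) >
                      radii[prev] + radii[i] + 3)
        }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) stop("infeasible packing: too many/large objects for frame")
    }
    grad <- matrix(rep(gradient * (seq_len(w) - 1) / (w - 1), each = h), h, w)
    bgm <- background + grad
    px <- array(rep(bgm, 3), dim = c(h, w, 3))
    # rim ring, red+green only
    rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    dist <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
    ring <- abs(dist - circle_radius_px) <= 1.5
    for (ch in 1:2) { sl <- px[, , ch]; sl[ring] <- 0.6; px[, , ch] <- sl }
    label_mask <- matrix(0L, h, w)
    blue <- px[, , 3]; green <- px[, , 2]
    for (i in seq_len(n_total)) {
      pix <- .disk_pixels(h, w, centers[i, 1], centers[i, 2], radii[i])
      label_mask[pix] <- i
      blue[pix] <- foreground
      green[pix] <- 0.45 * foreground
    }
    px[, , 3] <- blue; px[, , 2] <- green
    if (noise_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, noise_sd)
      px <- pmin(pmax(px, 0), 1)
    }
    areas <- tabulate(label_mask[label_mask > 0], nbins = n_total)
    objects <- data.frame(
      id = seq_len(n_total),
      class = rep(c("bundled", "scattered"), c(n_bundled, n_scattered)),
      row = centers[, 1], col = centers[, 2], radius_px = radii,
      area_px = areas)
    img <- flask_image(px, flask_inner_diameter_cm,
                       calibration_circle = c(ctr, circle_radius_px))
    list(image = img,
         truth = list(objects = objects, label_mask = label_mask,
                      scale_cm_per_px = flask_inner_diameter_cm /
                        (2 * circle_radius_px)))
  })
}

#' Generate a two-channel stain field with a planted overlap fraction
#'
#' Builds a disk-shaped material ROI, carves random cell blobs inside it
#' and stains exactly `round(overlap_fraction * n_cellfree)` of the
#' cell-free pixels (exact pixel accounting), emulating protein-like
#' (high-overlap) or lipid-like (near-zero-overlap) staining.  A fraction
#' of cell pixels is also stained for realism; it does not enter the
#' statistic.
#'
#' @param height,width field size, px.
#' @param overlap_fraction planted fraction of cell-free pixels stained,
#'   in `[0, 1]`.
#' @param n_cell_blobs,cell_radius_px cell blob count and radius range.
#' @param roi_radius_px ROI disk radius, px.
#' @param background,foreground channel intensities of unlabelled and
#'   labelled pixels.
#' @param stain_on_cells_fraction fraction of cell pixels also stained.
#' @param noise_sd Gaussian intensity noise SD (default 0.05; set 0 for
#'   exact mask recovery).
#' @param seed integer seed.
#' @return List with `field` (a [two_channel_field()]) and `truth`:
#'   logical `cell_mask`, `stain_mask`, `roi_mask`, counts, the requested
#'   `planted_fraction` and the exactly `achieved_overlap_percent`
#'   (`100 * round(f * n_cellfree) / n_cellfree`).
#' @export
gen_coloc_field <- function(height = 256, width = 256, overlap_fraction = 0.3,
                            n_cell_blobs = 25, cell_radius_px = c(4, 12),
                            roi_radius_px = 100, background = 0.1,
                            foreground = 0.85,
                            stain_on_cells_fraction = 0.2, noise_sd = 0.05,
                            seed = 1) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  .with_seed(seed, {
    h <- height; w <- width; ctr <- c(h / 2, w / 2)
    rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    roi <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= roi_radius_px^2
    cell <- matrix(FALSE, h, w)
    for (i in seq_len(n_cell_blobs)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * roi_radius_px * 0.92
      r <- stats::runif(1, cell_radius_px[1], cell_radius_px[2])
      cell[.disk_pixels(h, w, ctr[1] + rad * cos(ang),
                        ctr[2] + rad * sin(ang), r)] <- TRUE
    }
    cell <- cell & roi
    cellfree <- roi & !cell
    n_cf <- sum(cellfree)
    if (n_cf == 0) stop("no cell-free pixels: cannot plant an overlap fraction")
    k <- round(overlap_fraction * n_cf)
    stain <- matrix(FALSE, h, w)
    if (k > 0) stain[sample(which(cellfree), k)] <- TRUE
    n_on_cells <- round(stain_on_cells_fraction * sum(cell))
    if (n_on_cells > 0) stain[sample(which(cell), n_on_cells)] <- TRUE
    mk <- function(mask) {
      ch <- matrix(background, h, w)
      ch[mask] <- foreground
      if (noise_sd > 0) ch <- pmin(pmax(ch + stats::rnorm(length(ch), 0, noise_sd), 0), 1)
      ch
    }
    field <- two_channel_field(mk(cell), mk(stain),
                               channel_names = c("cells", "stain"))
    list(field = field,
         truth = list(cell_mask = cell, stain_mask = stain, roi_mask = roi,
                      cellfree_px = n_cf, stained_cellfree_px = k,
                      planted_fraction = overlap_fraction,
                      achieved_overlap_percent = 100 * k / n_cf))
  })
}
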