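make_rgb <- function(r, g, b) {
  px <- array(0, dim = c(dim(r), 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  px
}

test_that("blue channel extraction is exact and dtype preserving", {
  h <- 32; w <- 48
  ramp <- matrix(seq(0, 1, length.out = h * w), h, w)
  px <- make_rgb(ramp, ramp / 2, ramp^2)
  expect_identical(extract_blue_channel(px), ramp^2)
  # pure blue / pure red at 8-bit scale
  blue255 <- make_rgb(matrix(0, h, w), matrix(0, h, w), matrix(255, h, w))
  expect_true(all(extract_blue_channel(blue255) == 255))
  red <- make_rgb(matrix(1, h, w), matrix(0, h, w), matrix(0, h, w))
  expect_true(all(extract_blue_channel(red) == 0))
  expect_warning(out <- extract_blue_channel(ramp), "single-channel")
  expect_identical(out, ramp)
})

test_that("segmentation finds a planted disk with pixel-exact area", {
  h <- w <- 200
  blue <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  disk <- (rows - 100)^2 + (cols - 100)^2 <= 20^2
  blue[disk] <- 0.9
  seg <- segment_material(blue)
  tab <- seg$object_table
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$class, "bundled")
  expect_identical(tab$area_px, sum(disk))           # rasterised oracle
  expect_lt(abs(tab$area_px - pi * 20^2) / (pi * 20^2), 0.02)  # pixelation bound
  # area conservation
  expect_identical(sum(tab$area_px) + seg$background_px + seg$discarded_px,
                   length(blue))
})

test_that("blank images yield a valid empty segmentation", {
  seg <- segment_material(matrix(0, 64, 64))
  expect_identical(nrow(seg$object_table), 0L)
  s <- representative_size(seg)
  expect_true(s$empty)
  expect_identical(s$representative_size_cm2, 0)
})

test_that("8-connectivity joins diagonally touching material", {
  blue <- matrix(0, 20, 20)
  blue[5:8, 5:8] <- 0.9
  blue[9:12, 9:12] <- 0.9   # touches only at the corner
  seg <- segment_material(blue, seg_params(min_object_px = 1,
                                           min_bundle_area_px = 5))
  expect_identical(nrow(seg$object_table), 1L)
  expect_identical(seg$object_table$area_px, 32L)
})

test_that("planted bundled and scattered objects are recovered exactly", {
  g <- gen_flask_image(seed = 11)   # 5 bundled + 50 scattered, noiseless
  pl <- size_pipeline(g$image)
  tab <- pl$segmentation$object_table
  expect_identical(sum(tab$class == "bundled"), 5L)
  expect_identical(sum(tab$class == "scattered"), 50L)
  # per-object area match via the label found at each planted centre
  lab <- pl$segmentation$label_mask
  for (i in seq_len(nrow(g$truth$objects))) {
    o <- g$truth$objects[i, ]
    li <- lab[round(o$row), round(o$col)]
    expect_gt(li, 0)
    expect_identical(tab$area_px[tab$label == li], o$area_px)
  }
  # calibrated bundled areas within 2% of the analytic disk areas
  scale <- g$truth$scale_cm_per_px
  bund <- g$truth$objects[g$truth$objects$class == "bundled", ]
  expect_true(all(abs(bund$area_px - pi * bund$radius_px^2) /
                    (pi * bund$radius_px^2) < 0.02))
  expect_equal(pl$summary$pixel_scale_cm_per_px, scale)
})

test_that("pixel calibration follows the diameter / radius arithmetic", {
  px <- array(0.1, dim = c(600, 600, 3))
  img <- flask_image(px, 8.5, calibration_circle = c(300, 300, 250))
  sc <- calibrate_pixels(img)
  expect_equal(sc, 0.017)
  expect_equal(1000 * sc^2, 0.289)    # 1000 px^2 object in cm^2
  # identity calibration: radius chosen so scale = 1
  img1 <- flask_image(px, 8.5, calibration_circle = c(300, 300, 4.25))
  expect_equal(calibrate_pixels(img1), 1)
  # doubling the radius halves the scale, quartering areas
  img2 <- flask_image(px, 8.5, calibration_circle = c(300, 300, 500))
  expect_equal(calibrate_pixels(img2), sc / 2)
  img_nc <- flask_image(px, 8.5)
  expect_error(calibrate_pixels(img_nc), "cannot calibrate")
  expect_equal(calibrate_pixels(img_nc, explicit_scale = 0.02), 0.02)
})

test_that("top-tail mean matches the exhaustive sort-based oracle", {
  expect_equal(top_tail_mean(1:100),
               list(threshold = 95.05, mean = 98, n_tail = 5))
  set.seed(7)
  for (n in c(1, 3, 20, 137)) {
    x <- rlnorm(n)
    tt <- top_tail_mean(x)
    thr <- oracle_percentile(x, 0.95)
    expect_equal(tt$threshold, thr)
    expect_equal(tt$mean, mean(x[x >= thr]))
  }
  # constant distribution and singleton
  expect_equal(top_tail_mean(rep(2, 10))$mean, 2)
  expect_equal(top_tail_mean(2)$mean, 2)
})

test_that("representative size is rotation and relabelling invariant", {
  g <- gen_flask_image(seed = 23, n_bundled = 4, n_scattered = 20)
  base <- size_pipeline(g$image)$summary
  rot <- function(m) t(m)[, nrow(m):1]   # 90 degree rotation
  px <- g$image$pixels
  pxr <- array(0, dim = c(dim(px)[2], dim(px)[1], 3))
  for (ch in 1:3) pxr[, , ch] <- rot(px[, , ch])
  cc <- g$image$calibration_circle
  imgr <- flask_image(pxr, g$image$flask_inner_diameter_cm,
                      calibration_circle = c(dim(px)[1] + 1 - cc[2], cc[1],
                                             cc[3]))
  rots <- size_pipeline(imgr)$summary
  expect_equal(rots$representative_size_cm2, base$representative_size_cm2)
  expect_identical(rots$n_bundled_objects, base$n_bundled_objects)
})

test_that("batch measurement aggregates groups and survives per-image failure", {
  g <- gen_flask_image(seed = 5, n_bundled = 3, n_scattered = 10)
  broken <- flask_image(g$image$pixels, 8.5)   # no circle -> calibration error
  out <- batch_size_measure(list(g$image, g$image, g$image, broken),
                            groups = c("a", "a", "a", "b"))
  expect_identical(out$per_image$error[4] > "", TRUE)
  expect_true(all(is.na(out$per_image$error[1:3])))
  expect_identical(length(unique(out$per_image$representative_size_cm2[1:3])), 1L)
  expect_equal(out$per_group$mean_size_cm2[out$per_group$group == "a"],
               out$per_image$representative_size_cm2[1])
})
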