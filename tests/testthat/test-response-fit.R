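test_that("annotation reproduces the forward model row by row", {
  set.seed(3)
  rec <- data.frame(flask_inner_diameter_m = runif(10, 0.05, 0.12),
                    orbit_diameter_m = 0.05,
                    fill_volume_mL = runif(10, 20, 200),
                    shaking_rpm = runif(10, 60, 400),
                    size_cm2 = runif(10, 0, 5))
  ann <- annotate_pva(rec)
  for (i in 1:10) {
    expect_equal(ann$Pva_mW_m2_s[i],
                 oracle_pva_milli(rec$flask_inner_diameter_m[i], 0.05,
                                  rec$fill_volume_mL[i] * 1e-6,
                                  rec$shaking_rpm[i] / 60),
                 tolerance = 1e-12)
  }
  # static row: every power quantity 0, flagged
  rec0 <- rec[1, ]; rec0$shaking_rpm <- 0
  ann0 <- annotate_pva(rec0)
  expect_identical(ann0$Pva_mW_m2_s, 0)
  expect_true(ann0$static)
  expect_true(is.na(ann0$Ne_mod))
})

test_that("noiseless unimodal data is recovered to high precision", {
  g <- gen_condition_table(seed = 4, noise_sd_fraction = 0, n_replicates = 1)
  ann <- annotate_pva(g$records)
  ft <- fit_unimodal(ann$Pva_mW_m2_s, ann$size_cm2)
  expect_true(ft$converged)
  expect_equal(ft$peak_log10_pva, g$truth$peak_log10, tolerance = 1e-6)
  expect_equal(ft$width, g$truth$width, tolerance = 1e-6)
  k <- g$truth$width * sqrt(2 * log(2))
  expect_equal(ft$derived_band$lower, 10^(g$truth$peak_log10 - k),
               tolerance = 1e-6)
  expect_equal(ft$derived_band$upper, 10^(g$truth$peak_log10 + k),
               tolerance = 1e-6)
  expect_gt(ft$goodness, 1 - 1e-9)
})

test_that("degenerate responses fail explicitly, never with a fabricated band", {
  flat <- fit_unimodal(10^seq(-1, 1, length.out = 12), rep(2.5, 12))
  expect_false(flat$converged)
  expect_match(flat$message, "flat")
  expect_null(flat$derived_band)
  few <- fit_unimodal(c(1, 2, 3), c(1, 2, 1))
  expect_false(few$converged)
})

test_that("empirical band brackets the high-mean conditions", {
  x <- c(0.3, 0.6, 1.0, 1.6, 3.0)
  size <- c(0.5, 3, 6, 3.2, 0.4)
  b <- empirical_band(x, size, alpha = 0.5)
  expect_equal(b$lower, 0.6)
  expect_equal(b$upper, 1.6)
})

test_that("the composite parameter ranks first when the response is planted on it", {
  g <- gen_condition_table(seed = 8, response_predictor = "pva",
                           noise_sd_fraction = 0.05)
  ann <- annotate_pva(g$records)
  rk <- compare_parameters(ann)
  expect_identical(rk$predictor[1], "Pva_mW_m2_s")
  expect_true(all(rk$r_squared <= 1 & rk$r_squared >= 0, na.rm = TRUE))
})

test_that("kLa ranks first under the symmetric construction", {
  g <- gen_condition_table(seed = 9, response_predictor = "kla",
                           noise_sd_fraction = 0.05)
  ann <- annotate_pva(g$records)
  rk <- compare_parameters(ann)
  expect_identical(rk$predictor[1], "kLa_per_s")
})

test_that("single-diameter tables are flagged as confounded", {
  g <- gen_condition_table(seed = 10, diameters = 0.085,
                           noise_sd_fraction = 0.05)
  ann <- annotate_pva(g$records)
  expect_warning(rk <- compare_parameters(ann), "confounded")
  expect_true(attr(rk, "confounded"))
})

test_that("ranking is invariant to row order and size rescaling", {
  g <- gen_condition_table(seed = 12, noise_sd_fraction = 0.05)
  ann <- annotate_pva(g$records)
  rk1 <- compare_parameters(ann)
  set.seed(1)
  shuf <- ann[sample(nrow(ann)), ]
  shuf$size_cm2 <- shuf$size_cm2 * 1000
  rk2 <- compare_parameters(shuf)
  expect_identical(rk1$predictor, rk2$predictor)
  expect_equal(rk1$r_squared, rk2$r_squared, tolerance = 1e-6)
})
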