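test_that("Reynolds number matches direct evaluation and handles static cultures", {
  expect_equal(reynolds_number(std_cond(rpm = 0)), 0)

  # rho = 1000, n = 1, d = 0.1, eta = 1e-3  ->  1e4 by hand
  cond <- culture_conditions(vessel_geometry(0.1), fill_volume_mL = 50,
                             shaking_per_s = 1)
  m <- medium_properties(rho = 1000, eta_app = 1e-3)
  expect_equal(reynolds_number(cond, m), 1e4)

  # standard bench condition against the hand formula
  expect_equal(reynolds_number(std_cond()),
               995.67 * (250 / 60) * 0.085^2 / 7.97e-4, tolerance = 1e-12)
  expect_error(vessel_geometry(-0.1), "positive")
  expect_error(medium_properties(rho = 0), "positive")
})

test_that("modified Newton number correlation is exact at Re = 1 and decreasing", {
  expect_identical(modified_newton_number(1), 70 + 25 + 1.5)
  # term-by-term at Re = 1e4
  expect_equal(modified_newton_number(1e4),
               70 / 1e4 + 25 * 1e4^-0.6 + 1.5 * 1e4^-0.2, tolerance = 1e-15)
  re <- 10^seq(0, 7, length.out = 200)
  expect_true(all(diff(modified_newton_number(re)) < 0))
  expect_true(all(modified_newton_number(re) > 0))
  # dominant-term limit: Ne' / (1.5 Re^-0.2) -> 1
  expect_equal(modified_newton_number(1e12) / (1.5 * 1e12^-0.2), 1,
               tolerance = 1e-3)
  expect_error(modified_newton_number(0), "Re > 0")
  expect_error(modified_newton_number(-5), "Re > 0")
})

test_that("volumetric power input follows the chained correlations", {
  expect_equal(volumetric_power_input(std_cond(rpm = 0)), 0)
  # frozen from two independent evaluations (R and Python) of the chain
  expect_equal(volumetric_power_input(std_cond()), 464.17560930577537,
               tolerance = 1e-12)
  # cubic power law at fixed Ne': doubling n with Ne held fixed gives x8
  ne <- modified_newton_number(reynolds_number(std_cond()))
  direct <- function(n) ne * 995.67 * n^3 * 0.085^4 / (8e-5)^(2 / 3)
  expect_equal(direct(2 * 250 / 60) / direct(250 / 60), 8, tolerance = 1e-12)
})

test_that("kLa correlation is linear in n and matches the frozen value", {
  expect_equal(kla(std_cond(rpm = 0)), 0)
  expect_equal(kla(std_cond()), 3.221524151531476, tolerance = 1e-12)
  expect_equal(kla(std_cond(rpm = 500)), 2 * kla(std_cond(rpm = 250)),
               tolerance = 1e-14)
})

test_that("modified volumetric power composes its factors and respects units", {
  h <- modified_volumetric_power(std_cond())
  expect_equal(h$pva_si,
               0.085^5 * h$kla * h$power_per_volume, tolerance = 1e-12)
  expect_identical(h$pva_milli, 1000 * h$pva_si)
  # frozen independent evaluation (R and Python agree)
  expect_equal(h$pva_milli, 6.634960417347881, tolerance = 1e-12)
  h0 <- modified_volumetric_power(std_cond(rpm = 0))
  expect_identical(h0$pva_si, 0)
  expect_true(is.na(h0$newton_mod))
})

test_that("P_V,A is strictly increasing in n and decreasing in V_L", {
  n_grid <- seq(0.25, 20, length.out = 60)
  pva_n <- vapply(n_grid, function(n)
    modified_volumetric_power(std_cond(rpm = n * 60))$pva_milli, numeric(1))
  expect_true(all(diff(pva_n) > 0))
  v_grid <- seq(2e-5, 4e-4, length.out = 40)
  pva_v <- vapply(v_grid, function(v)
    modified_volumetric_power(culture_conditions(
      vessel_geometry(0.085), fill_volume_m3 = v,
      shaking_per_s = 4))$pva_milli, numeric(1))
  expect_true(all(diff(pva_v) < 0))
})

test_that("regime classification uses a closed optimal interval", {
  band <- regime_band(0.72, 1.65)
  expect_identical(classify_regime(1.0, band), "optimal")
  expect_identical(classify_regime(0.72, band), "optimal")
  expect_identical(classify_regime(1.65, band), "optimal")
  expect_identical(classify_regime(c(0.3, 2.5, 0), band),
                   c("low", "high", "low"))
  expect_error(regime_band(2, 1), "lower < upper")
  expect_error(regime_band(-1, 1))
  expect_error(classify_regime(-0.1, band))
})
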