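# Shared fixtures: the standard 250 mL bench condition (d = 0.085 m,
# d0 = 0.05 m, 80 mL, 250 rpm) and the default medium (water at 30 C).

std_medium <- medium_properties()

std_cond <- function(d = 0.085, d0 = 0.05, v_mL = 80, rpm = 250) {
  culture_conditions(vessel_geometry(d, d0), fill_volume_mL = v_mL,
                     shaking_rpm = rpm)
}

# Independent forward evaluation of the model, written straight from the
# defining formulas with no package calls — the oracle for chained tests.
oracle_pva_milli <- function(d, d0, v_m3, n_per_s, m = std_medium) {
  re <- m$rho * n_per_s * d^2 / m$eta_app
  if (n_per_s == 0) return(0)
  ne <- 70 / re + 25 * re^-0.6 + 1.5 * re^-0.2
  pv <- ne * m$rho * n_per_s^3 * d^4 / v_m3^(2 / 3)
  k <- 0.5 * d^(73 / 36) * n_per_s * d0^(1 / 4) * v_m3^(-8 / 9) *
    m$diffusion_coeff^(1 / 2) * m$nu^(-13 / 54) * m$gravity^(-7 / 54)
  1000 * d^5 * k * pv
}

# Sort-based linear-interpolation percentile, independent of
# stats::quantile: h = (n - 1) p + 1, interpolate between order statistics.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}
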