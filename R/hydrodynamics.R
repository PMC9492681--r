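#' Flask Reynolds number
#'
#' Re = rho * n * d^2 / eta_app for an orbitally shaken flask.  A static
#' culture (n = 0) gives Re = 0.
#'
#' @param cond a [culture_conditions()].
#' @param medium a [medium_properties()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(cond, medium = medium_properties()) {
  stopifnot(inherits(cond, "culture_conditions"),
            inherits(medium, "medium_properties"))
  medium$rho * cond$shaking_frequency * cond$vessel$inner_diameter^2 /
    medium$eta_app
}

#' Modified Newton number for unbaffled shake flasks
#'
#' Power-number correlation Ne' = 70/Re + 25*Re^-0.6 + 1.5*Re^-0.2,
#' strictly decreasing and positive for Re > 0.  The correlation diverges
#' at Re = 0; static cultures are handled upstream by the n = 0
#' short-circuit in [volumetric_power_input()].
#'
#' @param reynolds Reynolds number, must be > 0 (vectorised).
#' @return Dimensionless modified Newton number Ne'.
#' @examples
#' modified_newton_number(1)    # 96.5 exactly
#' @export
modified_newton_number <- function(reynolds) {
  if (any(!is.finite(reynolds)) || any(reynolds <= 0))
    stop("modified Newton number requires Re > 0")
  70 / reynolds + 25 * reynolds^-0.6 + 1.5 * reynolds^-0.2
}

#' Volumetric power input P/V_L
#'
#' Rate of mechanical energy transfer into a shaken flask per unit culture
#' volume: P/V_L = Ne' * rho * n^3 * d^4 / V_L^(2/3), in W/m^3.  Returns 0
#' for a static culture, the continuous limit (Ne' * n^3 scales as n^2 as
#' n -> 0).
#'
#' @inheritParams reynolds_number
#' @return Volumetric power input, W/m^3.
#' @export
volumetric_power_input <- function(cond, medium = medium_properties()) {
  n <- cond$shaking_frequency
  if (n == 0) return(0)
  ne <- modified_newton_number(reynolds_number(cond, medium))
  ne * medium$rho * n^3 * cond$vessel$inner_diameter^4 /
    cond$fill_volume^(2 / 3)
}

#' Volumetric oxygen mass-transfer coefficient kLa
#'
#' Dimensional orbital-shaker correlation
#' kLa = 0.5 * d^(73/36) * n * d0^(1/4) * V_L^(-8/9) * D^(1/2) *
#' nu^(-13/54) * g^(-7/54), in 1/s.  The transfer coefficient k_L and the
#' specific interfacial area a are never separated by the correlation; only
#' their product is modelled.  Exact in the linear factor n, so kLa = 0 for
#' static cultures.
#'
#' @inheritParams reynolds_number
#' @return kLa in 1/s.
#' @export
kla <- function(cond, medium = medium_properties()) {
  stopifnot(inherits(cond, "culture_conditions"),
            inherits(medium, "medium_properties"))
  d <- cond$vessel$inner_diameter
  0.5 * d^(73 / 36) * cond$shaking_frequency *
    cond$vessel$orbit_diameter^(1 / 4) * cond$fill_volume^(-8 / 9) *
    medium$diffusion_coeff^(1 / 2) * medium$nu^(-13 / 54) *
    medium$gravity^(-7 / 54)
}

#' Modified volumetric power P_V,A
#'
#' The composite scale-up predictor P_V,A = d^5 * kLa * (P/V_L), combining
#' the volumetric power input with the oxygen mass-transfer coefficient and
#' a d^5 correction that unifies size measurements across flask sizes.
#' Material size is maximal in an intermediate band of P_V,A.
#'
#' @inheritParams reynolds_number
#' @return An object of class `hydro_result`: a list with fields
#'   `reynolds`, `newton_mod`, `power_per_volume` (W/m^3), `kla` (1/s),
#'   `pva_si` (W m^2/s) and `pva_milli` (mW m^2/s, the reporting unit of
#'   the optimal band).  `newton_mod` is `NA` for static cultures, where
#'   the power correlation is undefined but every power quantity is 0.
#' @examples
#' cond <- culture_conditions(vessel_geometry(0.085),
#'                            fill_volume_mL = 80, shaking_rpm = 250)
#' modified_volumetric_power(cond)
#' @export
modified_volumetric_power <- function(cond, medium = medium_properties()) {
  re <- reynolds_number(cond, medium)
  ne <- if (re > 0) modified_newton_number(re) else NA_real_
  pv <- volumetric_power_input(cond, medium)
  k <- kla(cond, medium)
  pva <- cond$vessel$inner_diameter^5 * k * pv
  structure(list(reynolds = re, newton_mod = ne, power_per_volume = pv,
                 kla = k, pva_si = pva, pva_milli = 1000 * pva),
            class = "hydro_result")
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf("Re = %.4g, Ne' = %.4g, P/V_L = %.4g W/m^3, kLa = %.4g 1/s\n",
              x$reynolds, x$newton_mod, x$power_per_volume, x$kla))
  cat(sprintf("P_V,A = %.4g mW m^2/s\n", x$pva_milli))
  invisible(x)
}

#' Optimal operating band of P_V,A
#'
#' The default band 0.72-1.65 mW m^2/s is the empirically optimal range for
#' large-material formation.
#'
#' @param lower,upper band edges, mW m^2/s, `0 < lower < upper`.
#' @return An object of class `regime_band`.
#' @export
regime_band <- function(lower = 0.72, upper = 1.65) {
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1 ||
      length(upper) != 1 || !is.finite(lower) || !is.finite(upper) ||
      lower <= 0 || upper <= lower)
    stop("regime band requires 0 < lower < upper")
  structure(list(lower = lower, upper = upper), class = "regime_band")
}

#' Classify a P_V,A value into the low / optimal / high regime
#'
#' Both band boundaries are inclusive: the optimal range is stated as a
#' closed interval.
#'
#' @param pva_milli P_V,A in mW m^2/s (vectorised), must be >= 0.
#' @param band a [regime_band()].
#' @return Character vector over `"low"`, `"optimal"`, `"high"`.
#' @export
classify_regime <- function(pva_milli, band = regime_band()) {
  if (!inherits(band, "regime_band")) stop("band must be a regime_band")
  if (any(!is.finite(pva_milli)) || any(pva_milli < 0))
    stop("pva_milli must be finite and >= 0")
  ifelse(pva_milli < band$lower, "low",
         ifelse(pva_milli > band$upper, "high", "optimal"))
}
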