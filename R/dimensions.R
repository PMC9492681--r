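# Exact dimensional bookkeeping for the model equations.
#
# The kLa correlation is dimensional (its prefactor 0.5 carries no units),
# so the only internal consistency check available is that its exponents
# combine to 1/s.  Exponents are carried as integer num/den pairs so the
# sums are exact, not floating point.

frac <- function(num, den = 1L) {
  g <- gcd_int(abs(num), abs(den))
  if (g > 0) { num <- num / g; den <- den / g }
  if (den < 0) { num <- -num; den <- -den }
  c(num = as.integer(num), den = as.integer(den))
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

frac_add <- function(a, b) frac(a["num"] * b["den"] + b["num"] * a["den"],
                                a["den"] * b["den"])

frac_scale <- function(a, k) frac(a["num"] * k["num"], a["den"] * k["den"])

# Base dimensions of each physical quantity as exponents of (mass, length,
# time); each exponent a frac.
.base_dims <- function() {
  dim3 <- function(m, l, t) list(mass = frac(m), length = frac(l), time = frac(t))
  list(
    rho    = dim3(1, -3, 0),   # kg/m^3
    eta    = dim3(1, -1, -1),  # Pa.s
    n      = dim3(0, 0, -1),   # 1/s
    d      = dim3(0, 1, 0),
    d0     = dim3(0, 1, 0),
    V_L    = dim3(0, 3, 0),
    D      = dim3(0, 2, -1),   # m^2/s
    nu     = dim3(0, 2, -1),
    g      = dim3(0, 1, -2)
  )
}

# Combine quantities raised to rational powers: terms is a named list
# mapping quantity name -> frac exponent.
.combine_dims <- function(terms) {
  base <- .base_dims()
  out <- list(mass = frac(0), length = frac(0), time = frac(0))
  for (q in names(terms)) {
    bd <- base[[q]]
    for (ax in names(out))
      out[[ax]] <- frac_add(out[[ax]], frac_scale(bd[[ax]], terms[[q]]))
  }
  out
}

.frac_num <- function(f) unname(f["num"]) / unname(f["den"])

#' Symbolic dimensional analysis of the model equations
#'
#' Verifies by exact rational exponent arithmetic that the kLa correlation
#' yields 1/s (its length exponent sums to zero) and that the volumetric
#' power input yields W/m^3 (kg m^-1 s^-3).
#'
#' @return A list with elements `kla` and `power_per_volume`, each a named
#'   numeric vector of (mass, length, time) exponents, plus an `exact`
#'   attribute confirming every exponent reduced to an integer.
#' @examples
#' model_dimensions()$kla   # c(mass = 0, length = 0, time = -1)
#' @export
model_dimensions <- function() {
  # kLa = 0.5 d^(73/36) n d0^(1/4) V_L^(-8/9) D^(1/2) nu^(-13/54) g^(-7/54)
  kla_terms <- list(d = frac(73, 36), n = frac(1), d0 = frac(1, 4),
                    V_L = frac(-8, 9), D = frac(1, 2),
                    nu = frac(-13, 54), g = frac(-7, 54))
  # P/V_L = Ne' rho n^3 d^4 / V_L^(2/3)   (Ne' dimensionless)
  pv_terms <- list(rho = frac(1), n = frac(3), d = frac(4), V_L = frac(-2, 3))

  kla_d <- .combine_dims(kla_terms)
  pv_d <- .combine_dims(pv_terms)
  exact <- all(vapply(c(kla_d, pv_d), function(f) f["den"] == 1L, logical(1)))
  out <- list(
    kla = vapply(kla_d, .frac_num, numeric(1)),
    power_per_volume = vapply(pv_d, .frac_num, numeric(1))
  )
  attr(out, "exact") <- exact
  out
}
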