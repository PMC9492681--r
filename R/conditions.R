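#' Liquid medium properties for hydrodynamic calculations
#'
#' Bundles the physical constants of the culture medium used throughout the
#' volumetric-power and oxygen-transfer correlations.  Defaults are the
#' properties of water at the standard growth temperature of 30 degrees C,
#' which approximate the culture at inoculation.
#'
#' @param rho liquid density, kg/m^3.
#' @param eta_app apparent dynamic viscosity, Pa s.
#' @param nu kinematic viscosity, m^2/s.
#' @param diffusion_coeff oxygen diffusion coefficient D, m^2/s.
#' @param gravity gravitational acceleration, m/s^2.
#'
#' @return An object of class `medium_properties`.
#' @examples
#' medium_properties()
#' @export
medium_properties <- function(rho = 995.67,
                              eta_app = 7.97e-4,
                              nu = 8.005e-7,
                              diffusion_coeff = 2.5655e-5,
                              gravity = 9.807) {
  vals <- c(rho = rho, eta_app = eta_app, nu = nu,
            diffusion_coeff = diffusion_coeff, gravity = gravity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all medium properties must be finite and strictly positive")
  structure(as.list(vals), class = "medium_properties")
}

#' Shake-flask vessel geometry
#'
#' @param inner_diameter inner flask diameter d, m.  Enters the composite
#'   predictor at the fifth power, so it must always be given explicitly.
#' @param orbit_diameter shaker orbit diameter d0, m (default 0.05 m).
#' @param label free-text description, e.g. `"250 mL Erlenmeyer"`.
#'
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(inner_diameter, orbit_diameter = 0.05, label = "") {
  if (!is.numeric(inner_diameter) || length(inner_diameter) != 1 ||
      !is.finite(inner_diameter) || inner_diameter <= 0)
    stop("inner_diameter must be a single positive number (metres)")
  if (!is.numeric(orbit_diameter) || length(orbit_diameter) != 1 ||
      !is.finite(orbit_diameter) || orbit_diameter <= 0)
    stop("orbit_diameter must be a single positive number (metres)")
  structure(list(inner_diameter = inner_diameter,
                 orbit_diameter = orbit_diameter,
                 label = as.character(label)),
            class = "vessel_geometry")
}

#' One shake-flask culture condition
#'
#' Volume and shaking frequency each accept exactly one of two explicitly
#' unit-tagged arguments; everything is stored internally in SI (m^3, 1/s).
#' Bench protocols quote mL and rpm while the correlations need SI, and the
#' d^5 sensitivity of the model makes silent unit mistakes catastrophic,
#' hence the tagged interface.
#'
#' @param vessel a [vessel_geometry()].
#' @param fill_volume_m3,fill_volume_mL culture volume V_L (give one).
#' @param shaking_per_s,shaking_rpm shaking frequency n (give one).
#'   `shaking_per_s = 0` encodes a static culture.
#'
#' @return An object of class `culture_conditions` with fields `vessel`,
#'   `fill_volume` (m^3) and `shaking_frequency` (1/s).
#' @examples
#' v <- vessel_geometry(0.085, label = "250 mL Erlenmeyer")
#' culture_conditions(v, fill_volume_mL = 80, shaking_rpm = 250)
#' @export
culture_conditions <- function(vessel,
                               fill_volume_m3 = NULL, fill_volume_mL = NULL,
                               shaking_per_s = NULL, shaking_rpm = NULL) {
  if (!inherits(vessel, "vessel_geometry"))
    stop("vessel must be a vessel_geometry object")
  if (is.null(fill_volume_m3) == is.null(fill_volume_mL))
    stop("give exactly one of fill_volume_m3 or fill_volume_mL")
  if (is.null(shaking_per_s) == is.null(shaking_rpm))
    stop("give exactly one of shaking_per_s or shaking_rpm")
  v <- if (is.null(fill_volume_m3)) fill_volume_mL * 1e-6 else fill_volume_m3
  n <- if (is.null(shaking_per_s)) shaking_rpm / 60 else shaking_per_s
  if (!is.finite(v) || v <= 0) stop("fill volume must be positive")
  if (!is.finite(n) || n < 0) stop("shaking frequency must be >= 0")
  structure(list(vessel = vessel, fill_volume = v, shaking_frequency = n),
            class = "culture_conditions")
}

#' Nominal flask-size presets
#'
#' Inner diameters for nominal Erlenmeyer sizes.  These are assumed,
#' catalogue-typical values, not measured ones: always prefer an explicitly
#' measured diameter, since the predictor scales with d^5.
#'
#' @return A data.frame with columns `nominal_mL`, `inner_diameter_m` and
#'   `assumed` (always `TRUE`).
#' @export
flask_presets <- function() {
  data.frame(nominal_mL = c(125, 250, 500),
             inner_diameter_m = c(0.065, 0.085, 0.105),
             assumed = TRUE)
}

#' @export
print.medium_properties <- function(x, ...) {
  cat("Medium properties (SI):\n")
  cat(sprintf("  rho = %g kg/m^3, eta_app = %g Pa.s, nu = %g m^2/s\n",
              x$rho, x$eta_app, x$nu))
  cat(sprintf("  D = %g m^2/s, g = %g m/s^2\n", x$diffusion_coeff, x$gravity))
  invisible(x)
}

#' @export
print.culture_conditions <- function(x, ...) {
  cat(sprintf("Culture condition%s: d = %g m, d0 = %g m, V_L = %g mL, n = %g rpm\n",
              if (nzchar(x$vessel$label)) paste0(" [", x$vessel$label, "]") else "",
              x$vessel$inner_diameter, x$vessel$orbit_diameter,
              x$fill_volume * 1e6, x$shaking_frequency * 60))
  invisible(x)
}
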