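#' Annotate a condition-size table with hydrodynamic quantities
#'
#' @param records data.frame with columns `flask_inner_diameter_m`,
#'   `orbit_diameter_m`, `fill_volume_mL`, `shaking_rpm` and at least one
#'   measurement column (conventionally `size_cm2`); extra columns such as
#'   `replicate` are carried through.
#' @param medium a [medium_properties()].
#' @param band a [regime_band()].
#' @return `records` with appended columns `Re`, `Ne_mod`,
#'   `P_per_V_W_m3`, `kLa_per_s`, `Pva_mW_m2_s`, `regime` and `static`
#'   (`TRUE` for rpm = 0 rows, where every power quantity is 0 and `Ne_mod`
#'   is `NA`).
#' @export
annotate_pva <- function(records, medium = medium_properties(),
                         band = regime_band()) {
  req <- c("flask_inner_diameter_m", "orbit_diameter_m", "fill_volume_mL",
           "shaking_rpm")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  hyd <- lapply(seq_len(nrow(records)), function(i) {
    cond <- culture_conditions(
      vessel_geometry(records$flask_inner_diameter_m[i],
                      records$orbit_diameter_m[i]),
      fill_volume_mL = records$fill_volume_mL[i],
      shaking_rpm = records$shaking_rpm[i])
    h <- modified_volumetric_power(cond, medium)
    data.frame(Re = h$reynolds, Ne_mod = h$newton_mod,
               P_per_V_W_m3 = h$power_per_volume, kLa_per_s = h$kla,
               Pva_mW_m2_s = h$pva_milli)
  })
  out <- cbind(records, do.call(rbind, hyd))
  out$regime <- classify_regime(out$Pva_mW_m2_s, band)
  out$static <- records$shaking_rpm == 0
  out
}

#' Fit a unimodal (log-Gaussian) size response and derive the optimal band
#'
#' Least-squares fit of
#' `size = amplitude * exp(-(log10(x) - peak)^2 / (2 * width^2)) + baseline`
#' to a positive predictor `x` (typically P_V,A in mW m^2/s).  The
#' operating band is the interval where the fitted response stays at or
#' above `baseline + f * amplitude`; with the default `f = 0.5` this is
#' the full-width-half-maximum analogue, with closed-form edges
#' `peak +/- width * sqrt(2 * log(1/f))` in log10 units.
#'
#' Degenerate inputs (flat response, too few distinct predictor values) or
#' optimiser failure yield `converged = FALSE` with a message — never a
#' fabricated band.
#'
#' @param x positive predictor values.
#' @param size response sizes (cm^2), same length.
#' @param f band fraction of the amplitude, in (0, 1).
#' @param average_replicates average `size` over identical `x` before
#'   fitting (replicates of one condition share its predictor value).
#' @return An object of class `optimal_range_fit`: `peak_log10_pva`,
#'   `width`, `amplitude`, `baseline`, `derived_band` (a [regime_band()]
#'   in the predictor's units, `NULL` on failure), `goodness` (R^2
#'   truncated to [0, 1]), `converged`, `message`, `n_points`.
#' @export
fit_unimodal <- function(x, size, f = 0.5, average_replicates = TRUE) {
  stopifnot(length(x) == length(size), f > 0, f < 1)
  ok <- is.finite(x) & is.finite(size) & x > 0
  x <- x[ok]; size <- size[ok]
  fail <- function(msg) structure(
    list(peak_log10_pva = NA_real_, width = NA_real_, amplitude = NA_real_,
         baseline = NA_real_, derived_band = NULL, goodness = NA_real_,
         converged = FALSE, message = msg, n_points = length(x)),
    class = "optimal_range_fit")
  if (average_replicates) {
    size <- as.numeric(tapply(size, x, mean))
    x <- sort(unique(x))
  }
  if (length(unique(x)) < 5)
    return(fail("need >= 5 distinct predictor values spanning the peak"))
  if (diff(range(size)) < 1e-12 * max(abs(size), 1))
    return(fail("flat response: no curvature to fit"))
  u <- log10(x)
  start <- list(A = max(size) - min(size), mu = u[which.max(size)],
                w = max(stats::sd(u) / 2, 0.02), b = min(size))
  fit <- tryCatch(
    minpack.lm::nlsLM(size ~ A * exp(-(u - mu)^2 / (2 * w^2)) + b,
                      start = start,
                      lower = c(A = 0, mu = -Inf, w = 1e-6, b = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear least squares did not converge"))
  p <- stats::coef(fit)
  if (p[["A"]] <= 0) return(fail("fitted amplitude is zero: no peak"))
  resid <- size - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((size - mean(size))^2)
  k <- p[["w"]] * sqrt(2 * log(1 / f))
  structure(list(peak_log10_pva = p[["mu"]], width = p[["w"]],
                 amplitude = p[["A"]], baseline = p[["b"]],
                 derived_band = regime_band(10^(p[["mu"]] - k),
                                            10^(p[["mu"]] + k)),
                 goodness = min(max(r2, 0), 1), converged = TRUE,
                 message = "converged", n_points = length(x)),
            class = "optimal_range_fit")
}

#' @export
print.optimal_range_fit <- function(x, ...) {
  if (!x$converged) {
    cat("unimodal fit failed:", x$message, "\n")
  } else {
    cat(sprintf("peak at log10 = %.4g (%.4g mW m^2/s), width %.4g, R^2 = %.3f\n",
                x$peak_log10_pva, 10^x$peak_log10_pva, x$width, x$goodness))
    cat(sprintf("derived band: %.4g - %.4g\n",
                x$derived_band$lower, x$derived_band$upper))
  }
  invisible(x)
}

#' Empirical (nonparametric) optimal band
#'
#' Model-free alternative to [fit_unimodal()]: average size per distinct
#' predictor value, keep the conditions whose mean size reaches
#' `alpha * max`, and report the predictor range they span.
#'
#' @inheritParams fit_unimodal
#' @param alpha fraction of the maximum mean size, in (0, 1).
#' @return A [regime_band()] in the predictor's units.
#' @export
empirical_band <- function(x, size, alpha = 0.5) {
  stopifnot(length(x) == length(size), alpha > 0, alpha < 1)
  m <- tapply(size, x, mean)
  xs <- as.numeric(names(m))
  keep <- xs[m >= alpha * max(m)]
  regime_band(min(keep), max(keep))
}

#' Rank candidate predictors of material size
#'
#' Fits the unimodal response against each of P/V_L, kLa and P_V,A and
#' ranks them by goodness of fit.  The three predictors are confounded
#' when every record shares one flask diameter, so single-diameter tables
#' are flagged.
#'
#' @param records an [annotate_pva()]-annotated data.frame with a
#'   `size_cm2` column.
#' @param f band fraction passed to [fit_unimodal()].
#' @return data.frame (`predictor`, `r_squared`, `converged`) sorted by
#'   descending R^2, with attribute `confounded` (`TRUE` when fewer than
#'   two distinct diameters are present; also raised as a warning).
#' @export
compare_parameters <- function(records, f = 0.5) {
  stopifnot("size_cm2" %in% names(records))
  preds <- c("P_per_V_W_m3", "kLa_per_s", "Pva_mW_m2_s")
  miss <- setdiff(preds, names(records))
  if (length(miss)) stop("records not annotated: run annotate_pva() first")
  confounded <- length(unique(records$flask_inner_diameter_m)) < 2
  if (confounded)
    warning("single flask diameter: P/V_L, kLa and P_V,A are confounded")
  rows <- lapply(preds, function(p) {
    ft <- fit_unimodal(records[[p]], records$size_cm2, f = f)
    data.frame(predictor = p,
               r_squared = if (ft$converged) ft$goodness else NA_real_,
               converged = ft$converged)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r_squared, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "confounded") <- confounded
  out
}
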