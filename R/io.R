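#' Default run configuration
#'
#' All tunable constants of the pipeline in one nested list: medium
#' constants (water at 30 degrees C), the optimal P_V,A band, vessel
#' presets, segmentation, colocalization and response-fit parameters.
#'
#' @return A named list of configuration blocks.
#' @export
default_config <- function() {
  list(
    medium = list(rho = 995.67, eta_app = 7.97e-4, nu = 8.005e-7,
                  diffusion_coeff = 2.5655e-5, gravity = 9.807),
    band = list(lower = 0.72, upper = 1.65),
    vessel_presets = list(nominal_mL = c(125, 250, 500),
                          inner_diameter_m = c(0.065, 0.085, 0.105)),
    segmentation = list(smooth_sigma = 0, threshold = "otsu",
                        fixed_threshold = 0.5, min_object_px = 2,
                        min_bundle_area_px = 200),
    coloc = list(threshold = "otsu", fixed_cell = 0.5, fixed_stain = 0.5,
                 closing_radius = 5, denominator = "cellfree"),
    fit = list(half_max_fraction = 0.5, average_replicates = TRUE)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) file, fills missing blocks and keys from
#' [default_config()], rejects unknown keys and validates constants.  An
#' empty file yields the full default configuration.
#'
#' @param path path to a YAML/JSON config file, or `NULL` for pure
#'   defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config file must contain a mapping")
    cfg <- .merge_config(cfg, user, "config")
  }
  .validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  .validate_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.merge_config <- function(base, user, where) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop(sprintf("unknown config key%s under %s: %s",
                 if (length(unknown) > 1) "s" else "", where,
                 paste(unknown, collapse = ", ")))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      .merge_config(base[[k]], user[[k]], paste0(where, "$", k))
    else user[[k]]
  }
  base
}

.validate_config <- function(cfg) {
  m <- cfg$medium
  vals <- unlist(m[c("rho", "eta_app", "nu", "diffusion_coeff", "gravity")])
  if (length(vals) != 5 || any(!is.finite(vals)) || any(vals <= 0))
    stop("config: all medium constants must be present, finite and positive")
  b <- cfg$band
  if (!is.numeric(b$lower) || !is.numeric(b$upper) ||
      b$lower <= 0 || b$upper <= b$lower)
    stop("config: band requires 0 < lower < upper")
  s <- cfg$segmentation
  if (s$smooth_sigma < 0 || s$min_object_px < 0 || s$min_bundle_area_px <= 0)
    stop("config: invalid segmentation parameters")
  if (cfg$coloc$closing_radius < 0)
    stop("config: coloc closing_radius must be >= 0")
  f <- cfg$fit$half_max_fraction
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("config: fit half_max_fraction must lie in (0, 1)")
  invisible(cfg)
}

#' Medium properties from a configuration
#' @param cfg configuration list from [load_config()].
#' @return A [medium_properties()] object.
#' @export
config_medium <- function(cfg) do.call(medium_properties, cfg$medium)

#' Regime band from a configuration
#' @param cfg configuration list from [load_config()].
#' @return A [regime_band()] object.
#' @export
config_band <- function(cfg) regime_band(cfg$band$lower, cfg$band$upper)

#' Read a unit-tagged culture-conditions CSV
#'
#' Expected columns: `label`, `flask_inner_diameter_m`, `orbit_diameter_m`,
#' `fill_volume_mL`, `shaking_rpm` (units declared in the header names;
#' converted to SI on read).  Rows with a missing or non-positive diameter
#' or volume are rejected with their row numbers: the d^5 sensitivity of
#' the model makes a silently defaulted diameter dangerous.
#'
#' @param path CSV path.
#' @return A list of [culture_conditions()], names taken from `label`.
#' @export
read_conditions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "flask_inner_diameter_m", "orbit_diameter_m",
                "fill_volume_mL", "shaking_rpm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("conditions CSV missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$flask_inner_diameter_m) |
                 df$flask_inner_diameter_m <= 0 |
                 !is.finite(df$fill_volume_mL) | df$fill_volume_mL <= 0 |
                 !is.finite(df$shaking_rpm) | df$shaking_rpm < 0)
  if (length(bad))
    stop("conditions CSV: invalid diameter/volume/rpm in row(s) ",
         paste(bad, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    culture_conditions(
      vessel_geometry(df$flask_inner_diameter_m[i], df$orbit_diameter_m[i],
                      df$label[i]),
      fill_volume_mL = df$fill_volume_mL[i], shaking_rpm = df$shaking_rpm[i])
  })
  names(out) <- df$label
  out
}

#' Annotate culture conditions with hydrodynamic quantities
#'
#' @param conditions a list of [culture_conditions()] (as returned by
#'   [read_conditions_csv()]) or a single `culture_conditions`.
#' @param medium a [medium_properties()].
#' @param band a [regime_band()].
#' @return data.frame with the condition columns (user-facing units) plus
#'   `Re`, `Ne_mod`, `P_per_V_W_m3`, `kLa_per_s`, `Pva_mW_m2_s`, `regime`.
#' @export
pva_table <- function(conditions, medium = medium_properties(),
                      band = regime_band()) {
  if (inherits(conditions, "culture_conditions")) conditions <- list(conditions)
  rows <- lapply(conditions, function(cond) {
    h <- modified_volumetric_power(cond, medium)
    data.frame(label = cond$vessel$label,
               flask_inner_diameter_m = cond$vessel$inner_diameter,
               orbit_diameter_m = cond$vessel$orbit_diameter,
               fill_volume_mL = cond$fill_volume * 1e6,
               shaking_rpm = cond$shaking_frequency * 60,
               Re = h$reynolds, Ne_mod = h$newton_mod,
               P_per_V_W_m3 = h$power_per_volume, kLa_per_s = h$kla,
               Pva_mW_m2_s = h$pva_milli)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$regime <- classify_regime(out$Pva_mW_m2_s, band)
  out
}

#' Write an annotated conditions table to CSV
#' @param df data.frame from [pva_table()] or [design_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pva_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
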