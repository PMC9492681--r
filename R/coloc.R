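#' Paired cell / stain fluorescence field
#'
#' @param cell_channel `H x W` intensity matrix of the cell marker (e.g.
#'   mKate2).
#' @param stain_channel `H x W` intensity matrix of the matrix stain (e.g.
#'   SpyCatcher-GFP, Congo Red, DiO).
#' @param channel_names character pair naming the channels.
#' @return An object of class `two_channel_field`.
#' @export
two_channel_field <- function(cell_channel, stain_channel,
                              channel_names = c("cells", "stain")) {
  if (!identical(dim(cell_channel), dim(stain_channel)))
    stop("cell and stain channels must have identical shape")
  if (min(cell_channel) < 0 || min(stain_channel) < 0)
    stop("intensities must be non-negative")
  structure(list(cell_channel = cell_channel, stain_channel = stain_channel,
                 channel_names = channel_names),
            class = "two_channel_field")
}

#' Colocalization analysis parameters
#'
#' @param threshold `"otsu"` (automatic, per channel) or `"fixed"`.
#' @param fixed_cell,fixed_stain thresholds used when `threshold =
#'   "fixed"`.
#' @param closing_radius radius (px) of the disc structuring element used
#'   to close the union mask into the material region of interest.
#' @param denominator which pixel set normalises the overlap percentage:
#'   `"cellfree"` (default; fraction of the cell-free matrix that is
#'   stained), `"stained"` or `"roi"`.
#' @return A list of class `coloc_params`.
#' @export
coloc_params <- function(threshold = c("otsu", "fixed"), fixed_cell = 0.5,
                         fixed_stain = 0.5, closing_radius = 5,
                         denominator = c("cellfree", "stained", "roi")) {
  structure(list(threshold = match.arg(threshold), fixed_cell = fixed_cell,
                 fixed_stain = fixed_stain,
                 closing_radius = closing_radius,
                 denominator = match.arg(denominator)),
            class = "coloc_params")
}

.channel_mask <- function(x, method, fixed) {
  if (method == "fixed") return(x > fixed)
  if (diff(range(x)) < 1e-10) return(matrix(FALSE, nrow(x), ncol(x)))
  x > EBImage::otsu(EBImage::Image(x / max(max(x), 1)))
}

#' Threshold a two-channel field into cell, stain and ROI masks
#'
#' Each channel is binarised independently; the material region of
#' interest (ROI) is the morphological closing of the union of the two
#' masks, and the cell-free region is the ROI minus the cell mask.  An
#' explicit `roi` (e.g. from a generator sidecar or a drawn outline)
#' bypasses the morphological construction.
#'
#' @param field a [two_channel_field()].
#' @param params a [coloc_params()].
#' @param roi optional explicit logical ROI mask.
#' @return List of logical masks `cell`, `stain`, `roi`, `cellfree`.
#' @export
make_masks <- function(field, params = coloc_params(), roi = NULL) {
  stopifnot(inherits(field, "two_channel_field"))
  cell <- .channel_mask(field$cell_channel, params$threshold, params$fixed_cell)
  stain <- .channel_mask(field$stain_channel, params$threshold,
                         params$fixed_stain)
  if (is.null(roi)) {
    u <- cell | stain
    roi <- if (params$closing_radius > 0) {
      brush <- EBImage::makeBrush(2 * params$closing_radius + 1, "disc")
      EBImage::imageData(EBImage::closing(EBImage::Image(u * 1), brush)) > 0.5
    } else u
  } else {
    stopifnot(identical(dim(roi), dim(cell)))
    roi <- roi > 0
  }
  if (!any(roi)) stop("empty ROI: no material in frame")
  list(cell = cell & roi, stain = stain & roi, roi = roi,
       cellfree = roi & !cell)
}

#' Percentage of overlapping pixels between cell-free and stained regions
#'
#' The statistic behind the matrix-composition comparison: by default the
#' percentage of cell-free ROI pixels that carry stain,
#' `100 * |stain  &  (roi & !cell)| / |roi & !cell|`.  A proteinaceous
#' matrix stains the cell-free regions heavily; a lipid stain that avoids
#' them scores near zero.
#'
#' @param cell_mask,stain_mask,roi_mask equal-shaped logical masks.
#' @param denominator see [coloc_params()].
#' @return An object of class `overlap_result`: `overlap_percent`
#'   (`NA` with `undefined = TRUE` when the denominator region is empty),
#'   pixel counts `cellfree_px`, `stained_px`, `intersection_px`,
#'   `roi_px`.
#' @export
overlap_percentage <- function(cell_mask, stain_mask, roi_mask,
                               denominator = "cellfree") {
  stopifnot(identical(dim(cell_mask), dim(stain_mask)),
            identical(dim(cell_mask), dim(roi_mask)))
  cellfree <- roi_mask & !cell_mask
  inter <- stain_mask & cellfree
  denom_px <- switch(denominator,
                     cellfree = sum(cellfree),
                     stained = sum(stain_mask & roi_mask),
                     roi = sum(roi_mask),
                     stop("unknown denominator"))
  structure(list(
    overlap_percent = if (denom_px == 0) NA_real_ else 100 * sum(inter) / denom_px,
    undefined = denom_px == 0,
    cellfree_px = sum(cellfree), stained_px = sum(stain_mask & roi_mask),
    intersection_px = sum(inter), roi_px = sum(roi_mask)),
    class = "overlap_result")
}

#' Overlap statistic for one two-channel field
#'
#' @inheritParams make_masks
#' @return An [overlap_percentage()] result.
#' @export
coloc_pipeline <- function(field, params = coloc_params(), roi = NULL) {
  m <- make_masks(field, params, roi)
  overlap_percentage(m$cell, m$stain, m$roi, params$denominator)
}

#' Per-group summary of overlap percentages
#'
#' Runs the overlap statistic over a batch of fields and summarises each
#' group with the descriptors used for box plots: mean, sample SD (n-1;
#' `NA` for singleton groups), median and the 25-75% interquartile range.
#' Groups without a single valid image are dropped with a warning.
#'
#' @param fields list of [two_channel_field()].
#' @param params a [coloc_params()].
#' @param groups character/factor vector, one entry per field (e.g.
#'   `"protein"` / `"lipid"`).
#' @param rois optional list of explicit ROI masks matching `fields`.
#' @return List with `per_image` (data.frame: `image`, `group`,
#'   `overlap_percent`) and `per_group` (data.frame: `group`, `n`, `mean`,
#'   `sd`, `median`, `q25`, `q75`).
#' @export
batch_overlap <- function(fields, params = coloc_params(), groups = NULL,
                          rois = NULL) {
  stopifnot(length(fields) >= 1)
  if (is.null(groups)) groups <- rep("all", length(fields))
  stopifnot(length(groups) == length(fields))
  vals <- vapply(seq_along(fields), function(i) {
    r <- tryCatch(
      coloc_pipeline(fields[[i]], params,
                     roi = if (is.null(rois)) NULL else rois[[i]]),
      error = function(e) NULL)
    if (is.null(r) || r$undefined) NA_real_ else r$overlap_percent
  }, numeric(1))
  per_image <- data.frame(image = seq_along(fields),
                          group = as.character(groups),
                          overlap_percent = vals)
  groups_u <- unique(per_image$group)
  rows <- lapply(groups_u, function(g) {
    v <- vals[per_image$group == g & !is.na(vals)]
    if (length(v) == 0) {
      warning("group '", g, "' has no valid images; omitted")
      return(NULL)
    }
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25, type = 7)),
               q75 = unname(stats::quantile(v, 0.75, type = 7)))
  })
  list(per_image = per_image, per_group = do.call(rbind, rows))
}
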