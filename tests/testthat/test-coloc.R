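test_that("overlap percentage counts pixels exactly in the degenerate cases", {
  roi <- matrix(TRUE, 20, 20)
  none <- matrix(FALSE, 20, 20)
  all_st <- matrix(TRUE, 20, 20)
  # stain covers the whole cell-free region -> 100%
  r <- overlap_percentage(none, all_st, roi)
  expect_equal(r$overlap_percent, 100)
  # no stain in the cell-free region -> 0%
  r0 <- overlap_percentage(none, none, roi)
  expect_equal(r0$overlap_percent, 0)
  # cells everywhere -> empty cell-free region -> undefined flag, not a number
  ru <- overlap_percentage(all_st, all_st, roi)
  expect_true(ru$undefined)
  expect_true(is.na(ru$overlap_percent))
  # planted 30% of 400 cell-free pixels
  st <- matrix(FALSE, 20, 20); st[seq_len(120)] <- TRUE
  r30 <- overlap_percentage(none, st, roi)
  expect_equal(r30$overlap_percent, 30)
  expect_identical(r30$intersection_px, 120L)
  expect_true(r30$intersection_px <= min(r30$cellfree_px, r30$stained_px))
})

test_that("mask recovery from a noiseless field is exact", {
  g <- gen_coloc_field(seed = 2, overlap_fraction = 0.3, noise_sd = 0)
  m <- make_masks(g$field, roi = g$truth$roi_mask)
  expect_identical(m$cell, g$truth$cell_mask)
  expect_identical(unname(which(m$stain)), which(g$truth$stain_mask))
  r <- overlap_percentage(m$cell, m$stain, m$roi)
  expect_equal(r$overlap_percent, g$truth$achieved_overlap_percent)
  expect_lt(abs(r$overlap_percent - 30), 0.5)
})

test_that("planted overlap is recovered within 2 points at default noise", {
  for (f in c(0.1, 0.5, 0.9)) {
    g <- gen_coloc_field(seed = 31 + round(100 * f), overlap_fraction = f)
    m <- make_masks(g$field, roi = g$truth$roi_mask)
    r <- overlap_percentage(m$cell, m$stain, m$roi)
    expect_lt(abs(r$overlap_percent - g$truth$achieved_overlap_percent), 2)
  }
})

test_that("empty fields raise an ROI error", {
  flat <- two_channel_field(matrix(0.1, 32, 32), matrix(0.1, 32, 32))
  expect_error(make_masks(flat), "empty ROI")
})

test_that("overlap is monotone in added stain and permutation symmetric", {
  g <- gen_coloc_field(seed = 9, overlap_fraction = 0.4, noise_sd = 0)
  t <- g$truth
  r1 <- overlap_percentage(t$cell_mask, t$stain_mask, t$roi_mask)
  # add stained pixels inside the cell-free region
  extra <- t$stain_mask
  free_unstained <- which(t$roi_mask & !t$cell_mask & !t$stain_mask)
  extra[free_unstained[seq_len(50)]] <- TRUE
  r2 <- overlap_percentage(t$cell_mask, extra, t$roi_mask)
  expect_gt(r2$overlap_percent, r1$overlap_percent)
  # simultaneous row/column permutation leaves the statistic unchanged
  pr <- sample(nrow(t$roi_mask)); pc <- sample(ncol(t$roi_mask))
  r3 <- overlap_percentage(t$cell_mask[pr, pc], t$stain_mask[pr, pc],
                           t$roi_mask[pr, pc])
  expect_equal(r3$overlap_percent, r1$overlap_percent)
})

test_that("group summaries match hand-computed descriptors", {
  # three fields engineered to overlap exactly 10, 20, 30 percent:
  # full-frame ROI, no cells, stain on exactly that share of pixels
  mkf <- function(pct) {
    st <- matrix(0.1, 20, 20)
    st[seq_len(4 * pct)] <- 0.9
    two_channel_field(matrix(0.1, 20, 20), st)
  }
  fields <- lapply(c(10, 20, 30), mkf)
  rois <- replicate(3, matrix(TRUE, 20, 20), simplify = FALSE)
  out <- batch_overlap(fields, coloc_params(threshold = "fixed"),
                       groups = rep("g", 3), rois = rois)
  expect_equal(out$per_image$overlap_percent, c(10, 20, 30))
  s <- out$per_group
  expect_equal(s$mean, 20)
  expect_equal(s$sd, 10)          # sample SD, n - 1
  expect_equal(s$median, 20)
  expect_equal(c(s$q25, s$q75), c(15, 25))
  # singleton group: mean = median = value, SD undefined
  one <- batch_overlap(fields[2], coloc_params(threshold = "fixed"),
                       rois = rois[2])
  expect_equal(one$per_group$mean, one$per_group$median)
  expect_true(is.na(one$per_group$sd))
})

test_that("protein-like and lipid-like groups order as planted", {
  gens <- c(lapply(1:4, function(i)
    gen_coloc_field(seed = 100 + i, overlap_fraction = 0.8)),
    lapply(1:4, function(i)
      gen_coloc_field(seed = 200 + i, overlap_fraction = 0.05)))
  out <- batch_overlap(lapply(gens, `[[`, "field"),
                       groups = rep(c("protein", "lipid"), each = 4),
                       rois = lapply(gens, function(g) g$truth$roi_mask))
  s <- out$per_group
  expect_gt(s$mean[s$group == "protein"], s$mean[s$group == "lipid"])
})
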