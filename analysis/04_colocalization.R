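#!/usr/bin/env Rscript
# Matrix-composition overlap statistic.
#
# Emulates the protein-vs-lipid staining comparison: a protein-like group
# (16 images, high planted overlap between stain and the cell-free matrix)
# against a lipid-like group (11 images, near-zero overlap), at the
# generator's default intensity noise.  Finding: the recovered group
# distributions separate cleanly, with the protein-like mean close to the
# planted 80% and the lipid-like mean near 5%.

library(budscale)

dir.create("results", showWarnings = FALSE)

gen_group <- function(n, fraction, seed0) lapply(seq_len(n), function(i)
  gen_coloc_field(seed = seed0 + i, overlap_fraction = fraction))

protein <- gen_group(16, 0.80, 100)
lipid <- gen_group(11, 0.05, 200)
gens <- c(protein, lipid)

out <- batch_overlap(lapply(gens, `[[`, "field"),
                     groups = rep(c("protein", "lipid"), c(16, 11)),
                     rois = lapply(gens, function(g) g$truth$roi_mask))
out$per_image$planted_pct <- vapply(gens, function(g)
  g$truth$achieved_overlap_percent, numeric(1))
write.csv(out$per_image, "results/04_overlap_per_image.csv", row.names = FALSE)
write.csv(out$per_group, "results/04_overlap_per_group.csv", row.names = FALSE)
print(out$per_group, digits = 4)
cat(sprintf("max |recovered - planted| per image: %.2f points\n",
            max(abs(out$per_image$overlap_percent - out$per_image$planted_pct))))
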