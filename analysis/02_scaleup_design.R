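#!/usr/bin/env Rscript
# Inverse scale-up design for 500 mL flasks.
#
# Solves the shaking frequency that places a 500 mL flask (d = 0.105 m,
# 160 mL fill) at P_V,A targets inside and outside the optimal band —
# the scale-up planning step — and cross-checks each solution by forward
# re-evaluation.  Finding: the optimal band is reached near 100-130 rpm
# at this geometry; targets below the bracket image are reported as
# non-converged rather than silently clamped.

library(budscale)

dir.create("results", showWarnings = FALSE)

vessel <- vessel_geometry(0.105, label = "500 mL")
fill <- 160e-6
band <- regime_band()
targets <- c(low = 0.3, lower_edge = band$lower,
             midpoint = (band$lower + band$upper) / 2,
             upper_edge = band$upper, high = 4.0)

rows <- lapply(names(targets), function(nm) {
  s <- solve_frequency(vessel, fill, targets[[nm]])
  data.frame(target_name = nm, target_pva_mW_m2_s = targets[[nm]],
             rpm = s$value_display, achieved_pva = s$achieved_pva_milli,
             regime = s$regime, converged = s$converged,
             iterations = s$iterations)
})
out <- do.call(rbind, rows)
write.csv(out, "results/02_design_500mL.csv", row.names = FALSE)
print(out, digits = 4)

cat(sprintf("\noptimal band at 500 mL / 160 mL fill: %.1f-%.1f rpm\n",
            out$rpm[out$target_name == "lower_edge"],
            out$rpm[out$target_name == "upper_edge"]))

# the same target reached by varying fill volume at fixed rpm
sv <- solve_volume(vessel, shaking_per_s = 2,
                   target_pva_milli = targets[["midpoint"]])
cat(sprintf("alternative at fixed 120 rpm: fill %.0f mL (regime %s)\n",
            sv$value_display, sv$regime))
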