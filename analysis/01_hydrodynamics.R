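#!/usr/bin/env Rscript
# Forward hydrodynamic model across bench conditions.
#
# Annotates a grid of shake-flask conditions spanning the three nominal
# flask sizes with Re, Ne', P/V_L, kLa and the composite predictor P_V,A,
# and classifies each against the optimal band 0.72-1.65 mW m^2/s.
# Finding: at the standard bench condition (250 mL flask, 80 mL, 250 rpm)
# the culture sits well above the optimal band (P_V,A ~ 6.6 mW m^2/s);
# P_V,A rises steeply with rpm (roughly n^4 overall) and falls with fill
# volume.

library(budscale)

dir.create("results", showWarnings = FALSE)

std <- culture_conditions(vessel_geometry(0.085, label = "250 mL standard"),
                          fill_volume_mL = 80, shaking_rpm = 250)
h <- modified_volumetric_power(std)
cat("Standard 250 mL condition (d = 0.085 m, 80 mL, 250 rpm):\n")
print(h)
cat("regime:", classify_regime(h$pva_milli), "\n\n")

presets <- flask_presets()
tabs <- lapply(seq_len(nrow(presets)), function(i) {
  v <- vessel_geometry(presets$inner_diameter_m[i],
                       label = sprintf("%g mL", presets$nominal_mL[i]))
  design_table(v, n_grid = c(60, 120, 180, 250, 320) / 60,
               volume_grid_m3 = c(25, 50, 80, 120, 160) * 1e-6)
})
tab <- do.call(rbind, tabs)
write_pva_csv(tab, "results/01_pva_conditions.csv")

cat(sprintf("wrote %d conditions; regime counts:\n", nrow(tab)))
print(table(tab$regime))
cat(sprintf("optimal-band conditions span %.0f-%.0f rpm across flasks\n",
            min(tab$shaking_per_s[tab$regime == "optimal"]) * 60,
            max(tab$shaking_per_s[tab$regime == "optimal"]) * 60))
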