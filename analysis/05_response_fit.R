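#!/usr/bin/env Rscript
# Unimodal size response and predictor comparison.
#
# Generates a condition-size table with a unimodal response planted on
# log10 P_V,A (peak 1.09 mW m^2/s, half-max band ~0.72-1.65), annotates it
# with the forward model, fits the log-Gaussian response, derives the
# optimal band, and ranks P/V_L, kLa and P_V,A by goodness of fit.
# Finding: the fitted band recovers the planted one to within the noise,
# and the composite predictor ranks first on multi-diameter data, while
# neither P/V_L nor kLa alone fits across flask sizes.

library(budscale)

dir.create("results", showWarnings = FALSE)

g <- gen_condition_table(seed = 42)   # defaults: 30 conditions x 3 replicates,
                                      # 10% noise, three flask diameters
ann <- annotate_pva(g$records)
write.csv(ann, "results/05_condition_sizes_annotated.csv", row.names = FALSE)

ft <- fit_unimodal(ann$Pva_mW_m2_s, ann$size_cm2)
print(ft)
cat(sprintf("planted: peak %.4g mW m^2/s, half-max band %.3g-%.3g\n",
            10^g$truth$peak_log10,
            10^(g$truth$peak_log10 - g$truth$width * sqrt(2 * log(2))),
            10^(g$truth$peak_log10 + g$truth$width * sqrt(2 * log(2)))))

eb <- empirical_band(ann$Pva_mW_m2_s, ann$size_cm2)
cat(sprintf("empirical (model-free) band: %.3g-%.3g mW m^2/s\n",
            eb$lower, eb$upper))

rk <- compare_parameters(ann)
print(rk)

jsonlite::write_json(list(
  fitted = list(peak_pva_mW_m2_s = 10^ft$peak_log10_pva,
                band_lower = ft$derived_band$lower,
                band_upper = ft$derived_band$upper,
                r_squared = ft$goodness),
  planted = list(peak_pva_mW_m2_s = 10^g$truth$peak_log10,
                 width_log10 = g$truth$width),
  ranking = rk), "results/05_fit.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/05_fit.json\n")
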