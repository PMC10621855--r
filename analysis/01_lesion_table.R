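#!/usr/bin/env Rscript
# Lesion sizes across wall compositions and delivered currents.
#
# Solves the six axisymmetric ventricular-wall models (homogeneous wall
# with/without epicardial fat; scar with/without fat deposits; myocardial
# channel; blocked subendocardium) at 19, 22 and 25 A and tabulates the
# 1000 V/cm lesion depth and surface width, plus the linear size-vs-current
# trends. Writes results/results.csv and results/trends.csv.

library(pfafield)

dir.create("results", showWarnings = FALSE)

cfg <- run_config(seed = 1L, output_dir = NULL)
res <- run_experiment(cfg, verbose = TRUE)
write.csv(res, "results/results.csv", row.names = FALSE)

tr <- fit_trends(res)
trends <- rbind(tr$per_model,
                data.frame(model = "pooled (excl. D)",
                           slope_depth = tr$pooled["depth"],
                           slope_width = tr$pooled["width"]))
write.csv(trends, "results/trends.csv", row.names = FALSE)

cat("\nLesion sizes (mm) by model and delivered current:\n")
print(res[, c("model", "current_A", "V_applied", "depth_mm",
              "surface_width_mm", "clamped_to_fat")], digits = 4)

cat("\nLesion-size trends (mm/A):\n")
print(trends, digits = 3, row.names = FALSE)

cat("\nFindings:\n")
cat(" - Lesions deepen and widen roughly linearly with current in every\n",
    "  wall except the scar with fat deposits, whose depth is pinned at\n",
    sprintf("  %.2f mm (the lower boundary of the dominant fat slab) at\n",
            res$depth_mm[res$model == "D"][1]),
    "  all three currents.\n")
cat(sprintf(" - The applied voltage spans %.0f-%.0f V at 22 A across wall\n",
            min(res$V_applied[res$current_A == 22]),
            max(res$V_applied[res$current_A == 22])),
    "  compositions: the wall composition barely moves the V needed for\n",
    "  a given current.\n")
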