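#!/usr/bin/env Rscript
# Potential and field along the catheter axis.
#
# Compares the axial voltage/field profiles of the homogeneous wall
# (model A) and the scar-with-fat wall (model D) at 22 A: the potential
# decays monotonically, but |E| jumps upward wherever the conductivity
# drops (fat, connective tissue), so deeper points can see higher fields
# than shallower ones. Writes results/axis_profiles.csv.

library(pfafield)

dir.create("results", showWarnings = FALSE)

profiles <- list()
for (m in c("A", "D")) {
  map <- build_model(m, geometry_spec(),
                     scar = if (m == "D") scar_spec(), seed = 1L)
  mesh <- generate_mesh(map)
  sol <- solve_at_current(mesh, tissue_properties(), 22)
  prof <- axis_profile(sol, z_max = 15)
  prof$model <- m
  profiles[[m]] <- prof
  cat(sprintf("model %s: V = %.0f V at 22 A\n", m, sol$V_applied))
}
out <- do.call(rbind, profiles)
write.csv(out, "results/axis_profiles.csv", row.names = FALSE)

a <- profiles$A
cat("\nModel A along the axis:\n")
for (z in c(1, 3, 5, 6.5, 7.5, 8.5, 10)) {
  i <- which.min(abs(a$z_mm - z))
  cat(sprintf("  z = %4.1f mm  phi = %7.1f V   |E| = %7.0f V/cm  (%s)\n",
              a$z_mm[i], a$phi_V[i], a$E_Vcm[i], a$label[i]))
}
i_fat <- which(a$label == "FAT")
i_myo <- which(a$label == "MYOCARDIUM")
cat(sprintf(
  "\nPeak |E| inside the epicardial fat band (%.0f V/cm) exceeds the field\n",
  max(a$E_Vcm[i_fat])))
cat(sprintf("1 mm shallower in myocardium (%.0f V/cm): the field\n",
            a$E_Vcm[which.min(abs(a$z_mm - (min(a$z_mm[i_fat]) - 1)))]))
cat("concentrates in the poorly conducting tissue even though it is\n")
cat("farther from the electrode.\n")
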