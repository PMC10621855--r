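#!/usr/bin/env Rscript
# Field redistribution around intramyocardial fat deposits.
#
# Solves the scar-with-fat model (D) at 22 A and classifies the boundary
# of every fat inclusion into field cold points (current entry/exit, where
# the poorly conducting fat starves the adjacent tissue of current) and
# hot points (lateral areas, where the bypassing current crowds). Writes
# results/hot_cold_points.csv and the field map as VTK.

library(pfafield)

dir.create("results", showWarnings = FALSE)

map <- build_model("D", geometry_spec(), scar_spec(), seed = 1L)
mesh <- generate_mesh(map)
sol <- solve_at_current(mesh, tissue_properties(), 22)

hc <- hotcold_points(sol)
write.csv(hc, "results/hot_cold_points.csv", row.names = FALSE)
write_vtk_solution(sol, "results/modelD_22A_field.vtk")

cat(sprintf("model D at 22 A: V = %.0f V\n\n", sol$V_applied))
cat("Hot/cold classification by inclusion (1 = dominant slab):\n")
print(table(inclusion = hc$inclusion, type = hc$type))

slab <- hc[hc$inclusion == 1, ]
cat(sprintf(
  "\nDominant slab: %d cold points (median |E| %.0f V/cm) at current\n",
  sum(slab$type == "COLD"), median(slab$E_Vcm[slab$type == "COLD"])))
cat(sprintf(
  "entry/exit faces vs %d hot points (median |E| %.0f V/cm) on the\n",
  sum(slab$type == "HOT"), median(slab$E_Vcm[slab$type == "HOT"])))
cat(sprintf("lateral rim; local reference field %.0f V/cm.\n",
            slab$E_ref_Vcm[1]))

les <- lesion_size(sol)
cat(sprintf(
  "\nThe lesion depth (%.2f mm) coincides with the slab lower boundary\n",
  les$depth))
cat(sprintf("(%.2f mm): the fat clamps lesion growth in depth while the\n",
            scar_spec()$main_fat_slab_bottom))
cat(sprintf("surface width (%.2f mm) keeps growing with current.\n",
            les$surface_width))
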