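# Legacy ASCII VTK emitters for the rasterized label grid (structured
# points) and the FEM field solution (unstructured triangle grid).

#' Export a rasterized label grid as a VTK structured-points file
#'
#' @param ras a [rasterize()] grid
#' @param path output file (.vtk, legacy ASCII)
#' @export
write_vtk_raster <- function(ras, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nr <- length(ras$r)
  nz <- length(ras$z)
  writeLines(c("# vtk DataFile Version 3.0",
               "tissue label raster", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nr, nz),
               sprintf("ORIGIN %g %g 0", ras$r[1], ras$z[1]),
               sprintf("SPACING %g %g 1", ras$h, ras$h),
               sprintf("POINT_DATA %d", nr * nz),
               "SCALARS tissue_label int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(ras$lab), collapse = " "), con)
  invisible(path)
}

#' Export a field solution as a VTK unstructured-grid file
#'
#' Writes the triangulation with nodal potential (V) and per-element field
#' magnitude (V/cm), conductivity (S/m), current density (A/m^2) and
#' tissue label.
#'
#' @param sol a `field_solution`
#' @param path output file (.vtk, legacy ASCII)
#' @export
write_vtk_solution <- function(sol, path) {
  mesh <- sol$mesh
  con <- file(path, "w")
  on.exit(close(con))
  n <- mesh$n_nodes
  ne <- mesh$n_elements
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric PFA field solution", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%g %g 0", mesh$r_mm, mesh$z_mm), con)
  writeLines(sprintf("CELLS %d %d", ne, 4 * ne), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L,
                     mesh$tri[, 2] - 1L, mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("5", ne), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS phi float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", sol$phi), con)
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS E_mag_Vcm float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", sol$E_mag / 100), con)
  writeLines(c("SCALARS sigma float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", sol$sigma_eff), con)
  writeLines(c("SCALARS J_mag float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", sol$J_mag), con)
  writeLines(c("SCALARS tissue_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", match(mesh$label, tissue_labels())), con)
  invisible(path)
}
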