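test_that("the mesh conforms to planar interfaces and electrode sizing", {
  mesh <- get_mesh("A")
  spec <- get_map("A")$spec

  # no element straddles the fat/myocardium or endocardial interface
  for (zi in c(0, spec$wall_thickness,
               spec$wall_thickness + spec$epicardial_fat_thickness)) {
    zt <- matrix(mesh$z_mm[mesh$tri], ncol = 3)
    lo <- apply(zt, 1, min)
    hi <- apply(zt, 1, max)
    expect_false(any(lo < zi - 1e-9 & hi > zi + 1e-9))
  }

  # grid spacing at the electrode surface respects h_fine
  rel <- spec$electrode_diameter / 2
  dr <- diff(mesh$rl)
  expect_true(all(dr[mesh$rl[-1] <= rel + 1e-9] <= mesh$h_fine + 1e-9))
  zin <- mesh$zl >= spec$insertion_depth - spec$electrode_length &
    mesh$zl <= spec$insertion_depth
  expect_true(all(diff(mesh$zl)[zin[-1]] <= mesh$h_fine + 1e-9))

  # every element carries exactly one defined label
  expect_true(all(mesh$label %in% tissue_labels()))
  expect_false(any(mesh$label %in% c("ELECTRODE", "INSULATED_SHAFT")))
})

test_that("meshing a seeded heterogeneous model is deterministic", {
  prof <- list(h_fine = 0.12, h_coarse = 3, h_lesion = 0.4)
  m1 <- do.call(generate_mesh, c(list(build_model("D", scar = scar_spec(),
                                                  seed = 5)), prof))
  m2 <- do.call(generate_mesh, c(list(build_model("D", scar = scar_spec(),
                                                  seed = 5)), prof))
  expect_identical(m1$rl, m2$rl)
  expect_identical(m1$zl, m2$zl)
  expect_identical(m1$tri, m2$tri)
  expect_identical(m1$label, m2$label)
})

test_that("boundary tags cover electrode and grounded outer boundaries", {
  mesh <- get_mesh("A")
  map <- get_map("A")
  r <- mesh$r_mm[mesh$idx_ground]
  z <- mesh$z_mm[mesh$idx_ground]
  expect_true(all(r > map$rmax - 1e-9 | z < map$zmin + 1e-9 |
                    z > map$zmax - 1e-9))
  rel <- map$spec$electrode_diameter / 2
  re <- mesh$r_mm[mesh$idx_electrode]
  ze <- mesh$z_mm[mesh$idx_electrode]
  expect_true(all(abs(re - rel) < 1e-9 |
                    abs(ze - map$spec$insertion_depth) < 1e-9))
  expect_gt(length(mesh$idx_electrode), 20)
})
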