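test_that("layered wall models place tissues at the documented depths", {
  A <- get_map("A")
  expect_equal(label_points(A, c(5, 5, 5), c(3, 8, 10)),
               c("MYOCARDIUM", "FAT", "CONNECTIVE"))
  B <- get_map("B")
  expect_equal(label_points(B, 5, 8), "CONNECTIVE")
  # electrode indents the wall; blood surrounds the shaft
  expect_equal(label_points(A, c(0.5, 0.5, 3, 0.5), c(0.2, 0.7, -5, -10)),
               c("ELECTRODE", "MYOCARDIUM", "BLOOD", "INSULATED_SHAFT"))
})

test_that("scar models follow their specification", {
  sc <- scar_spec()
  C <- build_model("C", scar = sc)
  # viable rim, fibrotic body, myocardium below the scar
  expect_equal(label_points(C, c(2, 2, 2), c(0.7, 3, 6.5)),
               c("MYOCARDIUM", "FIBROSIS", "MYOCARDIUM"))
  E <- build_model("E", scar = sc)
  expect_equal(label_points(E, c(0.2, 2), c(3, 3)),
               c("MYOCARDIUM", "FIBROSIS"))
  F_ <- build_model("F", scar = sc)
  expect_equal(label_points(F_, 2, 0.7), "FIBROSIS")
  D <- get_map("D")
  # dominant slab between its documented bounds, fibrosis right below
  expect_equal(label_points(D, c(1, 1), c(3.5, 4.8)),
               c("FAT", "FIBROSIS"))
  expect_error(build_model("D"), "scar")
  expect_error(build_model("Q", geometry_spec()), "unknown model_id")
})

test_that("seeded blob placement is reproducible and stays in the scar", {
  d1 <- build_model("D", scar = scar_spec(), seed = 7)
  d2 <- build_model("D", scar = scar_spec(), seed = 7)
  expect_identical(d1$regions, d2$regions)
  d3 <- build_model("D", scar = scar_spec(), seed = 8)
  expect_false(identical(d1$regions, d3$regions))

  sc <- scar_spec()
  blobs <- Filter(function(r) r$shape == "ellipse", d1$regions)
  expect_length(blobs, sc$fat_blob_count)
  for (b in blobs) {
    p <- b$ell
    expect_true(p[1] + p[3] <= sc$scar_width / 2)
    expect_true(p[2] - p[4] >= sc$rim_thickness)
    expect_true(p[2] + p[4] <= sc$scar_depth_extent)
    # clear of the dominant slab: lateral to it or in the pocket above it
    expect_true(p[1] - p[3] >= sc$main_fat_slab_radius ||
                  p[2] + p[4] <= sc$main_fat_slab_top)
  }
})

test_that("rasterization partitions the domain and conserves areas", {
  A <- get_map("A")
  ras <- rasterize(A, 0.1)
  expect_false(anyNA(ras$lab))
  frac_fat <- mean(ras$lab == match("FAT", ras$levels))
  domain_area <- A$rmax * (A$zmax - A$zmin)
  expect_rel(frac_fat, 2 * A$rmax / domain_area, 0.01)

  ras2 <- rasterize(A, 0.05)
  # tissue areas; the catheter cross-section is a sub-millimetre sliver
  # whose voxelized area quantizes at +-h/2 and is checked more loosely
  for (lv in c("MYOCARDIUM", "FAT", "CONNECTIVE", "BLOOD")) {
    i <- match(lv, ras$levels)
    expect_rel(sum(ras$lab == i) * 0.1^2, sum(ras2$lab == i) * 0.05^2,
               0.02)
  }
  for (lv in c("ELECTRODE", "INSULATED_SHAFT")) {
    i <- match(lv, ras$levels)
    expect_rel(sum(ras$lab == i) * 0.1^2, sum(ras2$lab == i) * 0.05^2,
               0.06)
  }
})

test_that("model E keeps a connected myocardium path under the electrode", {
  E <- get_map("E")
  ras <- rasterize(E, 0.1, rlim = c(0, 12), zlim = c(0, 7))
  myo <- ras$lab == match("MYOCARDIUM", ras$levels)
  comp <- EBImage::bwlabel(myo)
  # component at the surface on the axis must reach below the scar
  top <- comp[1, which(myo[1, ])[1]]
  deep_j <- which.min(abs(ras$z - 6.5))
  expect_true(top %in% comp[, deep_j])
})

test_that("tissue maps round-trip through the text config", {
  d1 <- build_model("D", scar = scar_spec(), seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_tissue_config(d1, f)
  d2 <- read_tissue_config(f)
  expect_identical(d1$regions, d2$regions)
  expect_identical(d1$model_id, d2$model_id)

  A <- get_map("A")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_tissue_config(A, f2)
  expect_identical(read_tissue_config(f2)$regions, A$regions)
})

test_that("geometry invariants are enforced", {
  expect_error(geometry_spec(insertion_depth = 4), "insertion_depth")
  expect_error(geometry_spec(wall_thickness = -1), "> 0")
  expect_error(scar_spec(main_fat_slab_top = 5, main_fat_slab_bottom = 4))
})
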