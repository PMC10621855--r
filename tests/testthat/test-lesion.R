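test_that("a radial analytic field yields the closed-form lesion extent", {
  # |E| = c / R^2 with the 1000 V/cm level surface at R = 3 mm
  h <- 0.02
  r <- seq(h / 2, 6, by = h)
  z <- seq(h / 2, 6, by = h)
  Rm <- outer(r, z, function(r, z) sqrt(r^2 + z^2))
  E <- 1e5 * (3 / Rm)^2
  lab <- matrix(match("MYOCARDIUM", tissue_labels()),
                length(r), length(z))
  seed <- Rm < 0.5
  m <- pfafield:::lesion_metrics_core(E, lab, r, z, h, 1e5,
                                      seed_mask = seed)
  expect_rel(m$depth, 3, 0.01)
  expect_rel(m$surface_width, 6, 0.01)
  expect_false(m$clamped_to_fat)
})

test_that("thresholds above the field maximum give an empty lesion", {
  sol <- get_run("A", 22)
  les <- lesion_size(sol, threshold = 1e6)
  expect_identical(les$depth, 0)
  expect_identical(les$surface_width, 0)
  expect_length(extract_isoline(sol, threshold = 1e6), 0)
})

test_that("the wall model produces one dominant closed lethal isoline", {
  iso <- extract_isoline(get_run("A", 22))
  expect_gt(length(iso), 0)
  main <- iso[[which.max(vapply(iso, nrow, integer(1)))]]
  # closed curve around the electrode: starts and ends on the axis/surface
  expect_gt(max(main$z), 3)
  expect_gt(max(main$r), 4)
})

test_that("lesion depth and width grow with current except when fat clamps", {
  for (m in c("A", "B", "C", "E", "F")) {
    d <- vapply(c(19, 22, 25), function(I) get_lesion(m, I)$depth,
                numeric(1))
    w <- vapply(c(19, 22, 25), function(I) get_lesion(m, I)$surface_width,
                numeric(1))
    expect_true(all(diff(d) >= 0), info = m)
    expect_true(all(diff(w) >= 0), info = m)
  }
  dD <- vapply(c(19, 22, 25), function(I) get_lesion("D", I)$depth,
               numeric(1))
  expect_lt(max(dD) - min(dD), 0.025 + 1e-9)
})

test_that("isoline resampling refinement leaves the metrics stable", {
  sol <- get_run("A", 22)
  l1 <- lesion_size(sol, h = 0.025)
  l2 <- lesion_size(sol, h = 0.0125)
  expect_rel(l2$depth, l1$depth, 0.01)
  expect_rel(l2$surface_width, l1$surface_width, 0.01)
})

test_that("the axis profile decays monotonically with field jumps at sigma drops", {
  sol <- get_run("A", 22)
  prof <- axis_profile(sol)
  expect_true(all(diff(prof$phi_V) <= 1e-6))
  expect_equal(prof$phi_V[1], sol$V_applied)
  # |E| peaks inside the epicardial fat relative to shallower myocardium
  E_fat <- prof$E_Vcm[which.min(abs(prof$z_mm - 7.5))]
  E_myo <- prof$E_Vcm[which.min(abs(prof$z_mm - 6.5))]
  expect_gt(E_fat, E_myo)
})

test_that("tangential E and normal J are continuous across the fat interface", {
  props <- tissue_properties()
  sol <- get_interface_run()
  w <- map_w <- get_map("A")$spec$wall_thickness
  for (r in c(2, 3, 4, 5, 6)) {
    up <- field_at_points(sol, r, w - 1e-3)   # myocardium-side trace
    dn <- field_at_points(sol, r, w + 1e-3)   # fat-side trace
    sm <- sigma_of_E("MYOCARDIUM", up$E_mag, props)
    expect_rel(0.08 * dn$Ez, sm * up$Ez, 0.05)
    expect_rel(dn$Er, up$Er, 0.05)
    # the field magnitude is higher on the poorly conducting side
    expect_gt(dn$E_mag, up$E_mag)
  }
})

test_that("cold poles and a hot equator form around an insulating sphere", {
  ip <- inclusion_problem()
  hc <- hotcold_points(ip$sol, E_ref = ip$E0, offset = 0.1)
  cold <- hc[hc$type == "COLD", ]
  hot <- hc[hc$type == "HOT", ]
  expect_gt(nrow(cold), 0)
  expect_gt(nrow(hot), 0)
  # current is axial: entry/exit poles lie on the axis, hot band lateral
  expect_true(all(abs(cold$z) > cold$r))
  expect_true(all(hot$r > abs(hot$z)))
})

test_that("fat deposits in the scar model show entry/exit cold and lateral hot points", {
  sol <- get_run("D", 22)
  hc <- hotcold_points(sol)
  slab <- hc[hc$inclusion == 1, ]  # dominant slab is the first inclusion
  expect_gt(sum(slab$type == "COLD"), 0)
  expect_gt(sum(slab$type == "HOT"), 0)
  expect_gt(sum(hc$type == "HOT" & hc$inclusion > 1), 0)
})

test_that("a homogeneous wall has no fat inclusions to classify", {
  hc <- hotcold_points(get_run("A", 22))
  expect_identical(nrow(hc), 0L)
})
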