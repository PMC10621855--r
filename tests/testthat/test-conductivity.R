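props <- tissue_properties()

test_that("sigmoid conductivity reproduces its limits and center value", {
  # lower asymptote: membranes intact
  expect_equal(sigma_of_E("MYOCARDIUM", 0, props), 0.4, tolerance = 1e-8)
  # center field: sigma0 + (sigma1 - sigma0) / (1 + prefactor)
  expect_equal(sigma_of_E("MYOCARDIUM", 58000, props), 0.4 + 0.2 / 11,
               tolerance = 1e-12)
  # upper asymptote: fully electroporated
  expect_lt(abs(sigma_of_E("MYOCARDIUM", 3e5, props) - 0.6), 1e-3)
  # field-independent tissues return their constant at any field
  for (E in c(0, 5e4, 1e6)) {
    expect_identical(sigma_of_E("FIBROSIS", E, props), 0.85)
    expect_identical(sigma_of_E("FAT", E, props), 0.08)
    expect_identical(sigma_of_E("CONNECTIVE", E, props), 0.115)
    expect_identical(sigma_of_E("BLOOD", E, props), 0.6)
  }
  expect_error(sigma_of_E("MYOCARDIUM", -1, props), "non-negative")
})

test_that("sigma(E) is monotone nondecreasing and bounded per tissue", {
  E <- seq(0, 2e5, length.out = 400)
  for (lab in props$table$label) {
    s <- sigma_of_E(rep(lab, length(E)), E, props)
    i <- match(lab, props$table$label)
    expect_true(all(diff(s) >= 0))
    expect_true(all(s >= props$table$sigma0[i] - 1e-12))
    expect_true(all(s <= props$table$sigma1[i] + 1e-12))
  }
})

test_that("the half-rise field matches the closed form", {
  mid <- (0.4 + 0.6) / 2
  root <- uniroot(function(E) sigma_of_E("MYOCARDIUM", E, props) - mid,
                  c(5e4, 9e4), tol = 1e-6)$root
  expect_lt(abs(root - (props$E_center + props$E_slope * log(10))), 0.1)
})

test_that("the published alternative fat conductivity is selectable", {
  alt <- tissue_properties(fat_sigma = 0.015)
  expect_identical(sigma_of_E("FAT", 1e5, alt), 0.015)
})

test_that("tissue properties round-trip through the text config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_tissue_properties(props, f)
  p2 <- read_tissue_properties(f)
  expect_equal(p2$table, props$table)
  expect_equal(p2$E_center, props$E_center)
})
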